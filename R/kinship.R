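#' Autotetraploid numerator relationship matrix under double reduction
#'
#' Builds the additive relationship matrix `A` and inbreeding
#' coefficients `F` for a tetraploid pedigree, given the double-reduction
#' rate `alpha` (the probability that the two alleles of a gamete are
#' copies of a single parental allele).  The construction is the exact
#' recursion over pedigree kinships: with kinship
#' `theta_ij = P(random allele of i IBD to random allele of j)`,
#' self-kinship `phi_i = 1/4 + 3/4 F_i`, and within-gamete IBD
#' `gamma_p = alpha + (1 - alpha) F_p` for a gamete from parent `p`
#' (`gamma = alpha` for an unknown parent), the offspring `i` of
#' `s x d` has
#' `F_i = gamma_s/6 + gamma_d/6 + 2/3 kappa_sd` (with `kappa_sd` the
#' parental kinship, `phi_s` for selfing, 0 if a parent is unknown) and
#' `theta_ij = (theta_sj + theta_dj)/2` for any earlier `j`.  Reported
#' on the founder-at-1 scale: `A_ij = 4 theta_ij` off the diagonal and
#' `A_ii = 1 + 3 F_i`, so founders have `A_ii = 1` and unrelated
#' non-inbred parents give parent-offspring and full-sib relationships
#' of 0.5 at any `alpha`.
#'
#' Unknown parents are treated as unrelated, non-inbred base
#' individuals in which double reduction still occurs (`gamma = alpha`).
#'
#' @param ped a [pedigree] (topologically ordered by construction).
#' @param alpha double-reduction rate in \[0, 1\].
#' @return An object of class `tetra_kinship`: list with the dense
#'   symmetric matrix `A` (dimnames = line ids), inbreeding vector `F`,
#'   average diagonal `d_A`, and `alpha`.
#' @examples
#' ped <- pedigree(c("A", "B", "X"), c(NA, NA, "A"), c(NA, NA, "B"))
#' k <- tetra_amatrix(ped, alpha = 0.1)
#' k$A["X", "X"]   # 1 + alpha
#' @export
tetra_amatrix <- function(ped, alpha) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  n <- nrow(ped)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  if (any(p1 > seq_len(n) | p2 > seq_len(n), na.rm = TRUE))
    stop("pedigree is not topologically ordered")

  # theta holds kinships; its diagonal holds self-kinship phi = 1/4+3/4F
  theta <- matrix(0, n, n)
  Fv <- numeric(n)
  for (i in seq_len(n)) {
    s <- p1[i]; d <- p2[i]
    if (is.na(s) && is.na(d)) {          # founder
      Fv[i] <- 0
      theta[i, i] <- 0.25
      next
    }
    gs <- if (is.na(s)) alpha else alpha + (1 - alpha) * Fv[s]
    gd <- if (is.na(d)) alpha else alpha + (1 - alpha) * Fv[d]
    kap <- if (is.na(s) || is.na(d)) 0 else theta[s, d]   # phi_s if s==d
    Fv[i] <- gs / 6 + gd / 6 + (2 / 3) * kap
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (is.na(s)) 0 else theta[s, j]
      rd <- if (is.na(d)) 0 else theta[d, j]
      theta[i, j] <- (rs + rd) / 2
      theta[j, i] <- theta[i, j]
    }
    theta[i, i] <- 0.25 + 0.75 * Fv[i]
  }
  A <- 4 * theta
  dimnames(A) <- list(ped$id, ped$id)
  names(Fv) <- ped$id
  structure(list(A = A, F = Fv, d_A = mean(diag(A)), alpha = alpha),
            class = "tetra_kinship")
}

#' Relationship matrices over a grid of double-reduction rates
#'
#' @param ped a [pedigree].
#' @param alphas numeric vector of double-reduction rates; default is
#'   the standard profiling grid `0.05, 0.1, 0.2, ..., 0.9`.
#' @return Named list of [tetra_amatrix()] results (names = alphas),
#'   identical row/column order.
#' @export
amatrix_grid <- function(ped, alphas = c(0.05, seq(0.1, 0.9, by = 0.1))) {
  if (!length(alphas)) stop("empty alpha grid")
  out <- lapply(alphas, function(a) tetra_amatrix(ped, a))
  names(out) <- format(alphas, trim = TRUE)
  out
}

#' Average diagonal of a relationship matrix
#'
#' `d(A)` scales the additive variance in plot-level heritability; it
#' equals the mean of `1 + 3 F_i` over the pedigree.
#'
#' @param k a `tetra_kinship`.
#' @return Scalar mean diagonal.
#' @export
mean_diagonal <- function(k) {
  stopifnot(inherits(k, "tetra_kinship"))
  mean(diag(k$A))
}

#' @export
print.tetra_kinship <- function(x, ...) {
  cat(sprintf(
    "Tetraploid A matrix: %d lines, double-reduction rate %.3g\n",
    nrow(x$A), x$alpha))
  cat(sprintf("  mean diagonal d(A) = %.4f, mean F = %.4f, max F = %.4f\n",
              x$d_A, mean(x$F), max(x$F)))
  invisible(x)
}

#' Write a relationship matrix as sparse text
#'
#' Writes the lower triangle (including diagonal) of `A` as
#' `row_id,col_id,value` (zeros omitted) and a per-line table
#' `id,F,A_ii`, as two CSV files.
#'
#' @param k a `tetra_kinship`.
#' @param path base path; `<path>.amat.csv` and `<path>.ind.csv`
#'   are written.
#' @return Invisibly, the two file paths.
#' @export
write_kinship <- function(k, path) {
  stopifnot(inherits(k, "tetra_kinship"))
  A <- k$A
  idx <- which(lower.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
  tri <- data.frame(row_id = rownames(A)[idx[, 1]],
                    col_id = colnames(A)[idx[, 2]],
                    value = A[idx], stringsAsFactors = FALSE)
  ind <- data.frame(id = rownames(A), F = k$F, A_ii = diag(A),
                    stringsAsFactors = FALSE)
  f1 <- paste0(path, ".amat.csv"); f2 <- paste0(path, ".ind.csv")
  utils::write.csv(tri, f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(ind, f2, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}

#' Read a relationship matrix written by [write_kinship()]
#'
#' @param path base path used when writing.
#' @param alpha the double-reduction rate to record on the object
#'   (not stored in the files).
#' @return A `tetra_kinship`.
#' @export
read_kinship <- function(path, alpha = NA_real_) {
  tri <- utils::read.csv(paste0(path, ".amat.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  ind <- utils::read.csv(paste0(path, ".ind.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric", "numeric"))
  n <- nrow(ind)
  A <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  i <- match(tri$row_id, ind$id); j <- match(tri$col_id, ind$id)
  A[cbind(i, j)] <- tri$value
  A[cbind(j, i)] <- tri$value
  Fv <- ind$F; names(Fv) <- ind$id
  structure(list(A = A, F = Fv, d_A = mean(diag(A)), alpha = alpha),
            class = "tetra_kinship")
}
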