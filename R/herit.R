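#' Plot-level heritabilities from a fitted model
#'
#' Narrow-sense heritability of a single-plot measurement is
#' `h2 = d(A) * s2_a / (d(A) * s2_a + s2_g + s2_i + s2_s + s2_e)` and
#' broad-sense `H2 = (d(A) * s2_a + s2_g + s2_s) / (same denominator)`,
#' where `d(A)` is the average diagonal of the additive relationship
#' matrix and the `s2` are the per-trait variance components of the
#' additive, line, genotype-by-trial-by-year, SCA and residual terms.
#' For the baseline model (no SCA) the `s2_s` terms are omitted.
#'
#' @param fit a fitted [tetra_lmm()].
#' @param d_A average diagonal of `A`; defaults to the fit's.
#' @return Object of class `heritability`: data.frame with one row per
#'   trait (`h2`, `H2`) plus attributes `d_A` and `model`.
#' @export
heritability <- function(fit, d_A = fit$d_A) {
  stopifnot(inherits(fit, "tetra_lmm"))
  comp <- vapply(fit$vc, diag, numeric(length(fit$traits)))
  comp <- matrix(comp, nrow = length(fit$traits),
                 dimnames = list(fit$traits, names(fit$vc)))
  if (any(comp < 0)) stop("negative variance component")
  s2s <- if (fit$sca) comp[, "sca"] else 0
  den <- d_A * comp[, "additive"] + comp[, "line"] + comp[, "gxty"] +
    s2s + comp[, "residual"]
  if (any(den <= 0)) stop("zero phenotypic variance")
  h2 <- d_A * comp[, "additive"] / den
  H2 <- (d_A * comp[, "additive"] + comp[, "line"] + s2s) / den
  out <- data.frame(trait = fit$traits, h2 = h2, H2 = H2,
                    row.names = NULL)
  attr(out, "d_A") <- d_A
  attr(out, "model") <- if (fit$sca) "M2" else "M1"
  class(out) <- c("heritability", "data.frame")
  out
}

#' @export
print.heritability <- function(x, ...) {
  cat("Plot-level heritability (", attr(x, "model"),
      ", d(A) = ", sprintf("%.4f", attr(x, "d_A")), ")\n", sep = "")
  df <- as.data.frame(x)
  df$h2 <- round(df$h2, 3); df$H2 <- round(df$H2, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Heritability of clone means
#'
#' Extension of the plot-level formulas to the mean of a clone's plots:
#' the denominator replaces `s2_i` by `s2_i / t` and `s2_e` by
#' `s2_e / n`, with `t` the (harmonic mean) number of trial-year cells
#' and `n` the (harmonic mean) number of plots per clone.
#'
#' @param fit a fitted [tetra_lmm()].
#' @param n_plots,n_cells (harmonic mean) plots and trial-year cells
#'   per clone, recycled per trait.
#' @param d_A average diagonal of `A`.
#' @return data.frame with per-trait `h2_mean` and `H2_mean`.
#' @export
clone_mean_heritability <- function(fit, n_plots, n_cells,
                                    d_A = fit$d_A) {
  stopifnot(inherits(fit, "tetra_lmm"))
  nt <- length(fit$traits)
  n_plots <- rep_len(n_plots, nt); n_cells <- rep_len(n_cells, nt)
  comp <- matrix(vapply(fit$vc, diag, numeric(nt)), nrow = nt,
                 dimnames = list(fit$traits, names(fit$vc)))
  s2s <- if (fit$sca) comp[, "sca"] else 0
  gen <- d_A * comp[, "additive"] + comp[, "line"] + s2s
  den <- gen + comp[, "gxty"] / n_cells + comp[, "residual"] / n_plots
  data.frame(trait = fit$traits,
             h2_mean = d_A * comp[, "additive"] / den,
             H2_mean = gen / den, row.names = NULL)
}

#' Share of phenotypic variance per model term
#'
#' @param fit a fitted [tetra_lmm()].
#' @param d_A average diagonal of `A`.
#' @return Matrix terms x traits of shares summing to 1 per trait; the
#'   additive component is weighted by `d_A`.
#' @export
variance_proportions <- function(fit, d_A = fit$d_A) {
  stopifnot(inherits(fit, "tetra_lmm"))
  nt <- length(fit$traits)
  comp <- matrix(vapply(fit$vc, diag, numeric(nt)), nrow = nt,
                 dimnames = list(fit$traits, names(fit$vc)))
  if (any(comp < 0)) stop("negative variance component")
  comp[, "additive"] <- d_A * comp[, "additive"]
  tot <- rowSums(comp)
  if (any(tot <= 0)) stop("zero phenotypic variance")
  t(comp / tot)
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares the baseline model against the model extended with the SCA
#' term on the same data, traits, fixed effects and double-reduction
#' rate.  The statistic is the drop in REML deviance (clamped at zero);
#' the degrees of freedom are the extra free (co)variance parameters of
#' the SCA block (1 univariate, 3 bivariate) and the p-value is the
#' plain upper-tail chi-square probability.  With a true variance on
#' the boundary this reference distribution is conservative; no mixture
#' correction is applied.  If the full model's recorded deviance sits
#' above the reduced model's (a numerical nesting violation, possible
#' when the optimum lies on a covariance-boundary ridge), the full
#' model is re-solved warm-started from the reduced solution before
#' the statistic is formed.
#'
#' @param fit_reduced,fit_full fitted [tetra_lmm()] objects, the first
#'   nested in the second (no-SCA vs SCA).
#' @return Object of class `tetra_lrt`: list with `stat`, `df`, `p`.
#' @export
lrt <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "tetra_lmm"),
            inherits(fit_full, "tetra_lmm"))
  if (fit_reduced$sca || !fit_full$sca)
    stop("fits are not nested (expected no-SCA reduced vs SCA full)")
  if (!identical(fit_reduced$traits, fit_full$traits) ||
      fit_reduced$alpha != fit_full$alpha ||
      fit_reduced$n_obs != fit_full$n_obs)
    stop("fits are not on the same data/traits/alpha")
  if (!fit_reduced$converged || !fit_full$converged)
    stop("both fits must have converged")
  dev_full <- fit_full$minus2logL
  if (dev_full > fit_reduced$minus2logL + 1e-8) {
    # nesting guarantees dev(full) <= dev(reduced); a violation means
    # the full fit stopped short (typically on a covariance-boundary
    # ridge), so re-solve it warm-started from the reduced solution
    st <- fit_reduced$vc
    nt <- length(fit_full$traits)
    st$sca <- diag(1e-8 * vapply(fit_full$model$var_y, max, 0, 0),
                   nt)
    refit <- tryCatch(reml_fit(fit_full$model, start = st),
                      error = function(e) NULL)
    if (!is.null(refit)) dev_full <- min(dev_full, refit$dev)
  }
  stat <- max(0, fit_reduced$minus2logL - dev_full)
  df <- n_par_block(length(fit_full$traits))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(stat = stat, df = df, p = p), class = "tetra_lrt")
}

#' @export
print.tetra_lrt <- function(x, ...) {
  cat(sprintf(
    "LRT baseline vs SCA model: chi2 = %.4f, df = %d, p = %.4g\n",
    x$stat, x$df, x$p))
  invisible(x)
}
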