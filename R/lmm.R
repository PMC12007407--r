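#' Fit the pedigree mixed model by AI-REML
#'
#' Fits, for one or two traits jointly, the multi-random-effect mixed
#' model
#' \deqn{y = Xb + Z_1 a + Z_2 g + Z_3 i + (Z_4 s) + e}
#' where `b` holds the trial, year and trial-by-year fixed effects,
#' `a` is the additive genetic effect with covariance `A (x) Sigma_a`
#' (`A` the tetraploid relationship matrix at double-reduction rate
#' `alpha`), `g` a line (clone) effect, `i` the
#' genotype-by-trial-by-year interaction, `s` (optional, the "M2"
#' model) the specific combining ability keyed by the unordered parent
#' pair, and `e` the residual.  In the bivariate case every term
#' carries an unstructured 2 x 2 cross-trait covariance block and a
#' plot contributes only its observed traits.  Variance components are
#' estimated by restricted maximum likelihood using average-information
#' updates on a log-Cholesky parameterization; fixed effects by
#' generalized least squares and random effects by BLUP at the REML
#' estimates.
#'
#' @param pheno plot-level data.frame with columns `line_id`, `trial`,
#'   `year` and the trait columns; missing trait values are allowed.
#' @param ped a [pedigree] covering every phenotyped line.
#' @param traits character vector (length 1 or 2) of trait column names.
#' @param alpha double-reduction rate used to build `A` (ignored if
#'   `kinship` is given).
#' @param sca include the specific-combining-ability term (`FALSE` =
#'   baseline model "M1", `TRUE` = "M2").
#' @param fixed one-sided formula for the fixed effects, evaluated on
#'   the plot table; default `~ trial * year`.
#' @param kinship optional precomputed [tetra_amatrix()] result for
#'   `ped` (used by the profiling and cross-validation code to share
#'   work across fits).
#' @param start optional named list of starting covariance blocks
#'   (`additive`, `line`, `gxty`, `sca`, `residual`); default splits
#'   each trait's phenotypic variance equally across terms with zero
#'   cross-trait covariance.
#' @param control a [lmm_control()].
#' @return An object of class `tetra_lmm` with components `vc` (named
#'   list of covariance blocks), `vc_se` (asymptotic standard errors),
#'   `minus2logL`, `blue` (fixed-effect solutions), `blup` (per-term
#'   random-effect solutions; `blup$additive` covers every pedigree
#'   member), `converged`, `iterations`, `boundary`, `d_A`, `alpha`,
#'   `traits`, and bookkeeping used by [predict.tetra_lmm()] and the
#'   cross-validation functions.
#' @examples
#' \donttest{
#' sim <- simulate_program(sim_config(n_cycles = 4, crosses_per_cycle = 6,
#'                                    progeny_per_cross = 4), seed = 1)
#' fit <- tetra_lmm(sim$pheno, sim$pedigree, "trait1", alpha = 0.05)
#' summary(fit)
#' }
#' @export
tetra_lmm <- function(pheno, ped, traits, alpha = 0.05, sca = FALSE,
                      fixed = ~ trial * year, kinship = NULL,
                      start = NULL, control = lmm_control()) {
  stopifnot(inherits(ped, "pedigree"))
  need <- c("line_id", "trial", "year")
  if (any(!need %in% names(pheno)))
    stop("pheno must have columns line_id, trial, year")
  if (any(!traits %in% names(pheno)))
    stop("trait column(s) not in pheno: ",
         paste(setdiff(traits, names(pheno)), collapse = ", "))

  # drop plots with no observed trait; drop empty traits
  obs_any <- rowSums(!is.na(pheno[, traits, drop = FALSE])) > 0L
  if (!all(obs_any)) {
    message("dropping ", sum(!obs_any), " plot(s) with no observed trait")
    pheno <- pheno[obs_any, , drop = FALSE]
  }
  empty <- vapply(traits, function(t) all(is.na(pheno[[t]])), TRUE)
  if (any(empty)) {
    warning("trait(s) with no data dropped from the model: ",
            paste(traits[empty], collapse = ", "))
    traits <- traits[!empty]
    if (!length(traits)) stop("no trait has data")
  }

  if (is.null(kinship)) kinship <- tetra_amatrix(ped, alpha)
  else stopifnot(inherits(kinship, "tetra_kinship"),
                 identical(rownames(kinship$A), ped$id))

  model <- assemble_model(pheno, ped, traits, kinship, sca = sca,
                          fixed = fixed)
  fit <- reml_fit(model, start = start, control = control)
  blup <- reml_blups(model, fit$Sigmas, fit$ev$Py)
  blue <- fit$ev$b
  names(blue) <- colnames(model$X)
  cM <- fit$ev$cM
  bcov <- chol2inv(cM)
  dimnames(bcov) <- list(names(blue), names(blue))

  vc <- lapply(fit$Sigmas, function(S) {
    dimnames(S) <- list(traits, traits); S
  })
  vc_se <- lapply(fit$vc_se, function(S) {
    dimnames(S) <- list(traits, traits); S
  })

  structure(list(
    vc = vc, vc_se = vc_se, minus2logL = fit$dev, blue = blue,
    blue_cov = bcov, blup = blup, converged = fit$converged,
    iterations = fit$iterations, trace = fit$trace,
    boundary = fit$boundary, d_A = kinship$d_A, alpha = kinship$alpha,
    traits = traits, sca = sca, fixed = fixed,
    n_obs = model$n, n_plots = nrow(pheno), Py = fit$ev$Py,
    model = model, call = match.call()),
    class = "tetra_lmm")
}

#' @export
print.tetra_lmm <- function(x, ...) {
  cat("Tetraploid pedigree mixed model (",
      if (x$sca) "with SCA" else "no SCA", ")\n", sep = "")
  cat(sprintf("  traits: %s | alpha = %.3g | d(A) = %.4f\n",
              paste(x$traits, collapse = ", "), x$alpha, x$d_A))
  cat(sprintf("  %d observations on %d plots; -2 logL = %.4f (%s, %d it.)\n",
              x$n_obs, x$n_plots, x$minus2logL,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  variance components (diagonal):\n")
  for (nm in names(x$vc))
    cat(sprintf("    %-9s %s\n", nm,
                paste(sprintf("%.4g", diag(x$vc[[nm]])), collapse = "  ")))
  invisible(x)
}

#' @export
summary.tetra_lmm <- function(object, ...) {
  nt <- length(object$traits)
  rows <- list()
  for (nm in names(object$vc)) {
    S <- object$vc[[nm]]; E <- object$vc_se[[nm]]
    for (i in seq_len(nt)) for (j in i:nt) {
      lab <- if (i == j) paste0("var(", nm, ":", object$traits[i], ")")
             else paste0("cov(", nm, ":", object$traits[i], ",",
                         object$traits[j], ")")
      rows[[lab]] <- c(estimate = S[j, i], se = E[j, i])
    }
  }
  vt <- do.call(rbind, rows)
  h2 <- tryCatch(heritability(object), error = function(e) NULL)
  out <- list(vc_table = vt, minus2logL = object$minus2logL,
              heritability = h2, converged = object$converged,
              boundary = object$boundary, traits = object$traits,
              alpha = object$alpha, d_A = object$d_A, sca = object$sca)
  class(out) <- "summary.tetra_lmm"
  out
}

#' @export
print.summary.tetra_lmm <- function(x, ...) {
  cat("REML variance components (alpha =", format(x$alpha), ")\n")
  print(round(x$vc_table, 5))
  cat(sprintf("-2 logL = %.4f  d(A) = %.4f\n", x$minus2logL, x$d_A))
  if (!is.null(x$heritability)) print(x$heritability)
  if (any(x$boundary))
    cat("note: component(s) at the variance floor:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.tetra_lmm <- function(object, ...) object$blue

#' @export
vcov.tetra_lmm <- function(object, ...) object$blue_cov

#' @export
logLik.tetra_lmm <- function(object, ...) {
  npar <- length(object$vc) * n_par_block(length(object$traits))
  structure(-object$minus2logL / 2, df = npar,
            nobs = object$n_obs, class = "logLik")
}

#' Predicted breeding values
#'
#' Extracts the BLUP of the additive genetic effect for the requested
#' lines (per trait), including unphenotyped pedigree members, whose
#' values are propagated through the relationship matrix.
#'
#' @param object a fitted [tetra_lmm()].
#' @param ids line ids; default all pedigree members.
#' @param ... unused.
#' @return Numeric matrix ids x traits.
#' @export
predict.tetra_lmm <- function(object, ids = NULL, ...) {
  a <- object$blup$additive
  if (is.null(ids)) return(a)
  miss <- setdiff(ids, rownames(a))
  if (length(miss))
    stop("id(s) not in pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  a[ids, , drop = FALSE]
}

#' @export
fitted.tetra_lmm <- function(object, ...) {
  m <- object$model
  yhat <- drop(m$X %*% object$blue)
  for (nm in names(m$terms)) {
    if (nm == "residual") next
    if (nm == "additive") {
      a <- object$blup$additive
      for (t in seq_len(m$nt)) {
        b <- m$bidx[[t]]
        yhat[b] <- yhat[b] + a[m$terms$additive$ind[b], t]
      }
    } else {
      u <- object$blup[[nm]]
      trm <- m$terms[[nm]]
      for (t in seq_len(m$nt)) {
        b <- m$bidx[[t]]
        yhat[b] <- yhat[b] + u[trm$lev[b], t]
      }
    }
  }
  yhat
}

#' @export
residuals.tetra_lmm <- function(object, ...) {
  object$model$y - fitted(object)
}
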