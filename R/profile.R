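#' Profile the restricted likelihood over double-reduction rates
#'
#' Rebuilds the relationship matrix and refits the mixed model at each
#' rate on a grid, recording the REML deviance (-2 logL); the estimated
#' double-reduction rate is the grid argmin.  The fixed-effect
#' structure is held constant across the grid so that the restricted
#' likelihoods are commensurable.  Fits are warm-started from the
#' previous grid point; by default the argmin is re-fitted from default
#' starting values and the two deviances are required to agree within
#' `audit_tol`.
#'
#' @inheritParams tetra_lmm
#' @param grid increasing vector of rates in \[0, 1\]; default
#'   `0.05, 0.1, 0.2, ..., 0.9`.
#' @param models which models to profile: `"M1"` (no SCA), `"M2"`, or
#'   both.
#' @param flat_tol deviances within this tolerance of the minimum are
#'   treated as flat when locating the flat region at small rates.
#' @param audit logical: re-fit the argmin point cold.
#' @param audit_tol allowed deviance discrepancy in the audit.
#' @return Object of class `dr_profile`: list with `grid`, `deviance`
#'   (matrix grid x models), `best_alpha` (per model, ties broken
#'   toward the smallest rate), and `flat_below` (per model, the
#'   largest rate up to which the deviance stays within `flat_tol` of
#'   the first grid point, `NA` if none).
#' @export
profile_dr <- function(pheno, ped, traits,
                       grid = c(0.05, seq(0.1, 0.9, by = 0.1)),
                       models = "M1", fixed = ~ trial * year,
                       control = lmm_control(), flat_tol = 1e-4,
                       audit = TRUE, audit_tol = 1e-4) {
  if (!length(grid)) stop("empty alpha grid")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  models <- match.arg(models, c("M1", "M2"), several.ok = TRUE)
  dev <- matrix(NA_real_, length(grid), length(models),
                dimnames = list(format(grid, trim = TRUE), models))
  fits <- vector("list", length(models)); names(fits) <- models
  for (m in models) {
    sca <- m == "M2"
    start <- NULL
    for (i in seq_along(grid)) {
      kin <- tetra_amatrix(ped, grid[i])
      f <- tryCatch(
        tetra_lmm(pheno, ped, traits, sca = sca, fixed = fixed,
                  kinship = kin, start = start, control = control),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        warning("model ", m, ", alpha = ", grid[i],
                ": fit did not converge; excluded from profile")
        next
      }
      dev[i, m] <- f$minus2logL
      start <- f$vc
      fits[[m]] <- f
    }
    if (all(is.na(dev[, m]))) stop("no grid point converged for ", m)
    if (audit) {
      i0 <- which.min(round(dev[, m] / audit_tol))
      kin <- tetra_amatrix(ped, grid[i0])
      f0 <- tetra_lmm(pheno, ped, traits, sca = sca, fixed = fixed,
                      kinship = kin, control = control)
      if (is.finite(f0$minus2logL) &&
          abs(f0$minus2logL - dev[i0, m]) > audit_tol)
        warning(sprintf(
          "cold-start audit at alpha = %g differs by %.3g in -2logL",
          grid[i0], abs(f0$minus2logL - dev[i0, m])))
    }
  }
  best <- apply(dev, 2, function(d) {
    ok <- which(!is.na(d))
    # ties (within numerical noise) broken toward the smallest rate
    ok[which(d[ok] <= min(d[ok]) + 1e-9)[1L]]
  })
  best_alpha <- grid[best]; names(best_alpha) <- models
  flat_below <- vapply(models, function(m) {
    d <- dev[, m]
    ok <- which(!is.na(d))
    run <- ok[cumsum(abs(d[ok] - d[ok[1L]]) > flat_tol) == 0]
    if (length(run) > 1L) grid[run[length(run)]] else NA_real_
  }, 0)
  structure(list(grid = grid, deviance = dev, best_alpha = best_alpha,
                 flat_below = flat_below, models = models,
                 traits = traits),
            class = "dr_profile")
}

#' @export
print.dr_profile <- function(x, ...) {
  cat("Double-reduction rate profile (traits:",
      paste(x$traits, collapse = ", "), ")\n")
  print(round(x$deviance, 4))
  for (m in x$models)
    cat(sprintf("  %s: alpha-hat = %s%s\n", m, format(x$best_alpha[m]),
                if (is.finite(x$flat_below[m]))
                  paste0(" (deviance flat up to ",
                         format(x$flat_below[m]), ")") else ""))
  invisible(x)
}

#' Tabulate or plot a likelihood profile
#'
#' @param p a [profile_dr()] result.
#' @param file optional TSV path to write the table to.
#' @return data.frame with `model`, `alpha`, `minus2logL` and `delta`
#'   (deviance above the per-model minimum).
#' @export
profile_report <- function(p, file = NULL) {
  stopifnot(inherits(p, "dr_profile"))
  out <- do.call(rbind, lapply(p$models, function(m) {
    d <- p$deviance[, m]
    data.frame(model = m, alpha = p$grid, minus2logL = d,
               delta = d - min(d, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}

#' @export
plot.dr_profile <- function(x, ...) {
  d <- x$deviance
  graphics::matplot(x$grid, d, type = "b", pch = 19, lty = 1,
                    xlab = "double-reduction rate",
                    ylab = "-2 logL (REML)", ...)
  graphics::legend("topleft", legend = colnames(d), bty = "n",
                   col = seq_len(ncol(d)), lty = 1, pch = 19)
  graphics::abline(v = x$best_alpha, lty = 3,
                   col = seq_len(ncol(d)))
  invisible(x)
}
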