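#' Build cross-validation folds over clones
#'
#' Two schemes: `"five_fold"` partitions the phenotyped clones into
#' five random non-overlapping subsets (all plots of a clone stay in
#' one fold; the partition depends only on the seed and the clone set,
#' not on row order), and `"lbco"` (leave one breeding cycle out)
#' makes one fold per crossing year.  For LBCO the masked set of a
#' cycle additionally includes every phenotyped clone sharing at least
#' one known parent with a member of the cycle, so all full and half
#' sibs of the cycle's lines are masked together with them; those sibs
#' still have their own predictions scored in their own fold.
#'
#' @param pheno plot-level phenotype data.frame (`line_id` column).
#' @param ped a [pedigree] with crossing years (needed for `"lbco"`).
#' @param scheme `"five_fold"` or `"lbco"`.
#' @param k number of folds for `"five_fold"`.
#' @param seed RNG seed for the random partition.
#' @return Object of class `cv_scheme`: list with `kind`, `folds`
#'   (clone ids scored per fold), `mask` (clone ids whose phenotypes
#'   are masked per fold), and `seed`.
#' @export
make_folds <- function(pheno, ped, scheme = c("five_fold", "lbco"),
                       k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ped, "pedigree"))
  clones <- sort(unique(as.character(pheno$line_id)))
  miss <- setdiff(clones, ped$id)
  if (length(miss)) stop("phenotyped clone(s) not in pedigree")
  if (scheme == "five_fold") {
    if (length(clones) < k)
      stop("fewer than ", k, " phenotyped clones")
    set.seed(seed)
    grp <- sample(rep_len(seq_len(k), length(clones)))
    folds <- split(clones, grp)
    names(folds) <- paste0("fold", seq_len(k))
    mask <- folds
  } else {
    yr <- ped$crossing_year[match(clones, ped$id)]
    if (all(is.na(yr))) stop("no crossing years for phenotyped clones")
    if (any(is.na(yr)))
      warning(sum(is.na(yr)), " phenotyped clone(s) without a crossing",
              " year are never scored")
    folds <- split(clones[!is.na(yr)], yr[!is.na(yr)])
    names(folds) <- paste0("cycle", names(folds))
    par1 <- ped$parent1[match(clones, ped$id)]
    par2 <- ped$parent2[match(clones, ped$id)]
    mask <- lapply(folds, function(f) {
      fp <- stats::na.omit(c(par1[match(f, clones)],
                             par2[match(f, clones)]))
      sib <- clones[(!is.na(par1) & par1 %in% fp) |
                    (!is.na(par2) & par2 %in% fp)]
      union(f, sib)
    })
  }
  structure(list(kind = scheme, folds = folds, mask = mask,
                 seed = seed), class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat("Cross-validation scheme:", x$kind, "with", length(x$folds),
      "folds\n")
  cat("  fold sizes:", paste(lengths(x$folds), collapse = ", "), "\n")
  if (!identical(x$folds, x$mask))
    cat("  masked-set sizes:", paste(lengths(x$mask), collapse = ", "),
        "\n")
  invisible(x)
}

#' Fixed-effect-corrected clone means
#'
#' Subtracts the full-data GLS fixed-effect estimates from every
#' observation and averages the corrected records per clone and trait.
#' These means are the phenotypic reference against which predicted
#' breeding values are correlated in cross-validation.
#'
#' @param fit a [tetra_lmm()] fitted on the full data.
#' @return Matrix clones x traits (`NA` where a clone has no observed
#'   plot for a trait).
#' @export
corrected_clone_means <- function(fit) {
  stopifnot(inherits(fit, "tetra_lmm"))
  m <- fit$model
  yc <- m$y - drop(m$X %*% fit$blue)
  clone <- m$ped$id[m$terms$additive$ind]
  out <- matrix(NA_real_, length(unique(clone)), m$nt,
                dimnames = list(sort(unique(clone)), m$traits))
  for (t in seq_len(m$nt)) {
    b <- m$bidx[[t]]
    mu <- tapply(yc[b], clone[b], mean)
    out[names(mu), t] <- mu
  }
  out
}

#' Run a cross-validation of the prediction model
#'
#' Variance components are fixed at the full-data REML estimates and
#' only the mixed-model equations are re-solved per fold (set
#' `refit = TRUE` to re-estimate them per fold).  For each fold, the
#' phenotypes of the masked clones are removed, breeding values are
#' re-predicted from the remaining records, and the fold's scored
#' clones contribute their reduced-data prediction.  Reported per
#' trait, pooled over all scored clones jointly: predictive ability
#' `PA = cor(corrected clone mean, reduced-data breeding value)`,
#' accuracy ratio `RC = cor(full-data, reduced-data breeding values)`,
#' and the reconstructed theoretical maximum of PA, the square root of
#' the heritability of the corrected clone mean
#' (`var(mean) = d(A) s2_a + s2_g + s2_s + s2_i/t + s2_e/n` with
#' harmonic-mean plots `n` and trial-year cells `t` per clone).
#'
#' @param fit a [tetra_lmm()] fitted on the full data.
#' @param scheme a [make_folds()] result.
#' @param refit re-estimate variance components within each fold.
#' @param control a [lmm_control()] (used when `refit = TRUE`).
#' @return Object of class `tetra_cv`: list with `pa`, `rc`,
#'   `theoretical_max` (per trait), `per_fold` data.frame, `n_masked`,
#'   `abv` (matrix of reduced-data breeding values for scored clones),
#'   and the scheme kind.
#' @export
run_cv <- function(fit, scheme, refit = FALSE,
                   control = lmm_control()) {
  stopifnot(inherits(fit, "tetra_lmm"), inherits(scheme, "cv_scheme"))
  m <- fit$model
  ybar <- corrected_clone_means(fit)
  clones <- rownames(ybar)
  aF <- predict(fit, clones)
  aR <- matrix(NA_real_, length(clones), m$nt,
               dimnames = list(clones, m$traits))
  obs_clone <- as.character(m$ped$id[m$terms$additive$ind])

  per_fold <- list()
  for (f in seq_along(scheme$folds)) {
    masked <- scheme$mask[[f]]
    scored <- intersect(scheme$folds[[f]], clones)
    if (!length(intersect(masked, clones))) {
      warning("fold ", names(scheme$folds)[f],
              ": no masked phenotyped clone; skipped")
      next
    }
    keep_obs <- !(obs_clone %in% masked)
    sub <- subset_model(m, keep_obs)
    if (refit) {
      ft <- reml_fit(sub, start = fit$vc, control = control)
      Sig <- ft$Sigmas; Py <- ft$ev$Py
    } else {
      ev <- reml_eval(sub, fit$vc, need_P = FALSE)
      if (!ev$ok) stop("fold solve failed")
      Sig <- fit$vc; Py <- ev$Py
    }
    bl <- reml_blups(sub, Sig, Py)
    aR[scored, ] <- bl$additive[scored, , drop = FALSE]
    for (t in seq_len(m$nt)) {
      sc <- scored[!is.na(ybar[scored, t])]
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        fold = names(scheme$folds)[f], trait = m$traits[t],
        n_masked = length(intersect(masked, clones)),
        n_scored = length(sc),
        pa = if (length(sc) > 2L)
          stats::cor(ybar[sc, t], bl$additive[sc, t]) else NA_real_)
    }
  }
  per_fold <- do.call(rbind, per_fold)

  pa <- rc <- tmax <- rep(NA_real_, m$nt)
  for (t in seq_len(m$nt)) {
    sc <- clones[!is.na(aR[, t]) & !is.na(ybar[, t])]
    if (length(sc) < 3L) next
    pa[t] <- stats::cor(ybar[sc, t], aR[sc, t])
    rc[t] <- stats::cor(aF[sc, t], aR[sc, t])
    # harmonic-mean replication of the scored clones for this trait
    b <- m$bidx[[t]]
    cl <- obs_clone[b]
    np <- tapply(m$obs_plot[b], cl, function(z) length(unique(z)))[sc]
    ncell <- tapply(m$terms$gxty$lev[b], cl,
                    function(z) length(unique(z)))[sc]
    hm <- function(v) length(v) / sum(1 / v)
    cm <- clone_mean_heritability(fit, hm(as.numeric(np)),
                                  hm(as.numeric(ncell)))
    tmax[t] <- sqrt(cm$h2_mean[t])
  }
  names(pa) <- names(rc) <- names(tmax) <- m$traits
  structure(list(kind = scheme$kind, pa = pa, rc = rc,
                 theoretical_max = tmax, per_fold = per_fold,
                 abv = aR, ybar = ybar,
                 n_masked = lengths(scheme$mask), seed = scheme$seed),
            class = "tetra_cv")
}

#' @export
print.tetra_cv <- function(x, ...) {
  cat("Cross-validation (", x$kind, ", ", length(x$n_masked),
      " folds)\n", sep = "")
  tab <- rbind(`predictive ability` = x$pa,
               `accuracy ratio` = x$rc,
               `theoretical max` = x$theoretical_max)
  print(round(tab, 3))
  invisible(x)
}

# restrict an assembled model to a subset of observations (logical over
# the stacked observation vector), keeping kinship and pedigree intact
subset_model <- function(m, keep) {
  y <- m$y[keep]
  X <- m$X[keep, , drop = FALSE]
  qx <- qr(X)
  kc <- sort(qx$pivot[seq_len(qx$rank)])
  X <- X[, kc, drop = FALSE]
  obs_trait <- m$obs_trait[keep]
  obs_plot <- m$obs_plot[keep]
  n <- length(y)
  bidx <- lapply(seq_len(m$nt), function(t) which(obs_trait == t))
  remap_iid <- function(trm) {
    lev <- trm$lev[keep]
    f <- factor(lev)
    li <- as.integer(f)
    by <- split(seq_len(n), li)
    ii <- unlist(lapply(by, function(s) rep(s, each = length(s))),
                 use.names = FALSE)
    jj <- unlist(lapply(by, function(s) rep.int(s, length(s))),
                 use.names = FALSE)
    list(name = trm$name, lev = li, nlev = nlevels(f),
         labels = trm$labels[as.integer(levels(f))],
         lin = (jj - 1) * n + ii,
         tt = (obs_trait[ii] - 1L) * m$nt + obs_trait[jj])
  }
  terms <- list(additive = list(
    name = "additive", ind = m$terms$additive$ind[keep],
    MA = m$terms$additive$MA[keep, keep, drop = FALSE]))
  for (nm in names(m$terms)[-1]) terms[[nm]] <- remap_iid(m$terms[[nm]])
  out <- m
  out$y <- y; out$X <- X; out$n <- n; out$p <- ncol(X)
  out$obs_plot <- obs_plot; out$obs_trait <- obs_trait
  out$bidx <- bidx; out$terms <- terms
  out$var_y <- vapply(seq_len(m$nt), function(t)
    stats::var(y[bidx[[t]]]), 0)
  out
}
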