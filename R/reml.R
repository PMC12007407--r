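# Direct average-information REML on the observed-data covariance.
#
# The model is y = Xb + Z1 a + Z2 g + Z3 i (+ Z4 s) + e with
# a ~ N(0, A (x) Sa), the other random terms iid over their levels with
# t x t cross-trait blocks, and a residual block per plot (a plot
# contributes only its observed traits).  Observations are stacked
# trait-major, so V = sum_j Sigma_j[t1,t2] * K_j[lev1,lev2] + R has
# simple trait-block structure; all heavy operations are dense BLAS-3.
# Each covariance block is parameterized by its log-Cholesky factor
# (diagonal on log scale), which keeps every block positive
# semidefinite; updates are Newton steps using the average-information
# matrix mapped into that parameterization, under adaptive
# Levenberg-Marquardt damping (a rejected step bends the next attempt
# toward a short gradient step).

#' Convergence and numerical options for [tetra_lmm()]
#'
#' @param max_iter maximum AI iterations.
#' @param tol_dev convergence tolerance on the change in -2 logL.
#' @param tol_par convergence tolerance on the largest parameter change.
#' @param tol_rel relative deviance-change tolerance: a change below
#'   `tol_rel * (1 + |deviance|)` also counts as stalled.
#' @param tol_pred a stalled iteration (no deviance movement) also
#'   counts as converged when the predicted remaining improvement of
#'   the undamped AI step falls below this.
#' @param floor_factor variance floor as a fraction of the phenotypic
#'   variance of each trait; variances are clamped here rather than
#'   allowed to reach zero.
#' @param max_halvings maximum step halvings per iteration.
#' @param verbose print the deviance trajectory.
#' @return list of class `lmm_control`.
#' @export
lmm_control <- function(max_iter = 200L, tol_dev = 1e-8, tol_par = 1e-8,
                        tol_rel = 1e-9, tol_pred = 1e-3,
                        floor_factor = 1e-10, max_halvings = 15L,
                        verbose = FALSE) {
  structure(list(max_iter = max_iter, tol_dev = tol_dev,
                 tol_par = tol_par, tol_rel = tol_rel,
                 tol_pred = tol_pred, floor_factor = floor_factor,
                 max_halvings = max_halvings, verbose = verbose),
            class = "lmm_control")
}

# ---- model assembly ---------------------------------------------------

assemble_model <- function(pheno, ped, traits, kin, sca = FALSE,
                           fixed = ~ trial * year) {
  miss <- setdiff(unique(pheno$line_id), ped$id)
  if (length(miss))
    stop("phenotyped line(s) not in pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  nt <- length(traits)
  stopifnot(nt %in% 1:2, all(traits %in% names(pheno)))

  plots <- pheno
  plots$trial <- factor(plots$trial)
  plots$year <- factor(plots$year)
  # drop fixed-effect terms involving single-level factors (degenerate
  # designs, e.g. one trial only); intercept-only if nothing is left
  tl <- attr(stats::terms(fixed), "term.labels")
  single <- names(plots)[vapply(plots, function(v)
    is.factor(v) && nlevels(v) < 2L, TRUE)]
  if (length(single)) {
    bad <- vapply(tl, function(lab)
      any(all.vars(stats::as.formula(paste("~", lab))) %in% single), TRUE)
    tl <- tl[!bad]
    fixed <- if (length(tl))
      stats::reformulate(tl) else ~ 1
  }
  Fmat <- stats::model.matrix(fixed, data = plots)

  obs_plot <- integer(0); obs_trait <- integer(0); y <- numeric(0)
  for (t in seq_len(nt)) {
    r <- which(!is.na(pheno[[traits[t]]]))
    obs_plot <- c(obs_plot, r)
    obs_trait <- c(obs_trait, rep.int(t, length(r)))
    y <- c(y, pheno[[traits[t]]][r])
  }
  n <- length(y)
  if (!n) stop("no non-missing phenotype records")
  bidx <- lapply(seq_len(nt), function(t) which(obs_trait == t))

  # trait-block-diagonal fixed design, aliased columns dropped per block
  Xb <- vector("list", nt)
  for (t in seq_len(nt)) {
    Xt <- Fmat[obs_plot[bidx[[t]]], , drop = FALSE]
    qx <- qr(Xt)
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    if (length(keep) < ncol(Xt))
      message("trait ", traits[t], ": dropped ", ncol(Xt) - length(keep),
              " aliased fixed-effect column(s)")
    Xt <- Xt[, keep, drop = FALSE]
    colnames(Xt) <- paste(traits[t], colnames(Xt), sep = ":")
    Xb[[t]] <- Xt
  }
  p <- sum(vapply(Xb, ncol, 0L))
  X <- matrix(0, n, p)
  cn <- character(0); at <- 0L
  for (t in seq_len(nt)) {
    X[bidx[[t]], at + seq_len(ncol(Xb[[t]]))] <- Xb[[t]]
    cn <- c(cn, colnames(Xb[[t]])); at <- at + ncol(Xb[[t]])
  }
  colnames(X) <- cn

  iid_term <- function(lev_all, name) {
    lev <- lev_all[obs_plot]
    f <- factor(lev)
    li <- as.integer(f)
    by <- split(seq_len(n), li)
    ii <- unlist(lapply(by, function(s) rep(s, each = length(s))),
                 use.names = FALSE)
    jj <- unlist(lapply(by, function(s) rep.int(s, length(s))),
                 use.names = FALSE)
    list(name = name, lev = li, nlev = nlevels(f), labels = levels(f),
         lin = (jj - 1) * n + ii,
         tt = (obs_trait[ii] - 1L) * nt + obs_trait[jj])
  }

  ind <- match(pheno$line_id, ped$id)[obs_plot]
  terms <- list(
    additive = list(name = "additive", ind = ind,
                    MA = kin$A[ind, ind, drop = FALSE]),
    line = iid_term(pheno$line_id, "line"),
    gxty = iid_term(paste(pheno$line_id, pheno$trial, pheno$year,
                          sep = "\r"), "gxty"))
  if (sca)
    terms$sca <- iid_term(sca_key(ped, pheno$line_id), "sca")
  # residual: one level per plot row
  terms$residual <- iid_term(seq_len(nrow(pheno)), "residual")

  if (!anyDuplicated(paste(pheno$line_id, pheno$trial, pheno$year)))
    warning("no clone is replicated within any trial-year cell: ",
            "G x T x Y and residual variances are jointly unidentifiable")

  var_y <- vapply(seq_len(nt), function(t) stats::var(y[bidx[[t]]]), 0)
  # degenerate (constant) phenotypes still need a positive scale
  var_y <- pmax(var_y, 1e-6 * (1 + mean(y^2)) * 1e-6)
  list(y = y, X = X, n = n, p = p, nt = nt, traits = traits,
       obs_plot = obs_plot, obs_trait = obs_trait, bidx = bidx,
       terms = terms, kin = kin, ped = ped, sca = sca, fixed = fixed,
       var_y = var_y)
}

# ---- covariance-block parameterization --------------------------------

# pack a PSD block as log-Cholesky parameters
chol_pack <- function(S) {
  if (nrow(S) == 1L) return(0.5 * log(max(S[1, 1], 1e-300)))
  L <- t(chol(S + diag(1e-12 * max(diag(S), 1e-300), 2)))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

chol_unpack <- function(phi, nt) {
  if (nt == 1L) return(matrix(exp(2 * phi), 1, 1))
  L <- matrix(c(exp(phi[1]), phi[2], 0, exp(phi[3])), 2, 2)
  L %*% t(L)
}

# Jacobian d(Sigma elements)/d(phi); element order (S11, S21, S22)
chol_jac <- function(phi, nt) {
  if (nt == 1L) return(matrix(2 * exp(2 * phi), 1, 1))
  l11 <- exp(phi[1]); c21 <- phi[2]; l22 <- exp(phi[3])
  matrix(c(2 * l11^2, l11 * c21, 0,
           0,         l11,       2 * c21,
           0,         0,         2 * l22^2),
         3, 3, byrow = FALSE)  # rows = elements, cols = phi
}

n_par_block <- function(nt) if (nt == 1L) 1L else 3L

# elementary symmetric derivative matrices for the block elements
elem_mats <- function(nt) {
  if (nt == 1L) return(list(matrix(1, 1, 1)))
  list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 1, 0), 2),
       matrix(c(0, 0, 0, 1), 2))
}

# ---- likelihood evaluation --------------------------------------------

build_V <- function(model, Sigmas) {
  n <- model$n; nt <- model$nt
  tm <- model$terms
  V <- matrix(0, n, n)
  Sa <- Sigmas$additive
  for (t1 in seq_len(nt)) for (t2 in seq_len(nt)) {
    b1 <- model$bidx[[t1]]; b2 <- model$bidx[[t2]]
    V[b1, b2] <- Sa[t1, t2] * tm$additive$MA[b1, b2]
  }
  for (nm in names(tm)) {
    if (nm == "additive") next
    sv <- as.vector(Sigmas[[nm]])
    trm <- tm[[nm]]
    V[trm$lin] <- V[trm$lin] + sv[trm$tt]
  }
  V
}

# Core REML evaluation at fixed covariance blocks.  Returns the pieces
# the AI update and the BLUP solves need.
reml_eval <- function(model, Sigmas, need_P = TRUE) {
  y <- model$y; X <- model$X; n <- model$n; p <- model$p
  V <- build_V(model, Sigmas)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ok = FALSE))
  logdetV <- 2 * sum(log(diag(R)))
  Vi <- chol2inv(R)
  XtVi <- crossprod(X, Vi)          # p x n
  M <- XtVi %*% X
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(list(ok = FALSE))
  logdetM <- 2 * sum(log(diag(cM)))
  XtViy <- drop(XtVi %*% y)
  b <- backsolve(cM, backsolve(cM, XtViy, transpose = TRUE))
  r <- y - drop(X %*% b)
  Py <- drop(Vi %*% r) -
    crossprod(XtVi, backsolve(cM, backsolve(cM, drop(XtVi %*% r),
                                            transpose = TRUE)))
  Py <- drop(Py)
  yPy <- sum(y * Py)
  dev <- (n - p) * log(2 * pi) + logdetV + logdetM + yPy
  out <- list(ok = TRUE, dev = dev, b = b, Py = Py, cM = cM,
              XtVi = XtVi)
  if (need_P) {
    P <- Vi - crossprod(XtVi, backsolve(cM, backsolve(cM, XtVi,
                                                      transpose = TRUE)))
    out$P <- P
  }
  out
}

# gradient (w.r.t. covariance elements) and AI matrix at an evaluation
reml_grad_ai <- function(model, Sigmas, ev) {
  n <- model$n; nt <- model$nt
  P <- ev$P; Py <- ev$Py
  tm <- model$terms
  E <- elem_mats(nt)
  npb <- n_par_block(nt)

  # per-term sufficient pieces
  # additive: Vt[, t2] = MA[, b2] %*% Py[b2]; sA[t1,t2] = sum(P*MA) blockwise
  MA <- tm$additive$MA
  Vt <- matrix(0, n, nt)
  sA <- matrix(0, nt, nt)
  PM <- P * MA
  for (t2 in seq_len(nt)) {
    b2 <- model$bidx[[t2]]
    Vt[, t2] <- MA[, b2, drop = FALSE] %*% Py[b2]
    for (t1 in seq_len(nt))
      sA[t1, t2] <- sum(PM[model$bidx[[t1]], b2])
  }
  rm(PM)

  K <- length(tm) * npb
  W <- matrix(0, n, K)
  trv <- numeric(K)
  k <- 0L
  for (nm in names(tm)) {
    trm <- tm[[nm]]
    if (nm == "additive") {
      for (e in seq_len(npb)) {
        k <- k + 1L
        Ee <- E[[e]]
        w <- numeric(n)
        for (t1 in seq_len(nt)) {
          b1 <- model$bidx[[t1]]
          acc <- 0
          for (t2 in seq_len(nt))
            if (Ee[t1, t2] != 0) acc <- acc + Ee[t1, t2] * Vt[b1, t2]
          w[b1] <- acc
        }
        W[, k] <- w
        trv[k] <- sum(Ee * sA)
      }
    } else {
      # aggregate Py by (level, trait)
      S <- matrix(0, trm$nlev, nt)
      grp <- trm$lev + (model$obs_trait - 1L) * trm$nlev
      ag <- rowsum(Py, grp)
      gi <- as.integer(rownames(ag))
      S[cbind((gi - 1L) %% trm$nlev + 1L,
              (gi - 1L) %/% trm$nlev + 1L)] <- ag
      sp <- rowsum(P[trm$lin], trm$tt)
      spm <- matrix(0, nt, nt)
      spm[as.integer(rownames(sp))] <- sp
      for (e in seq_len(npb)) {
        k <- k + 1L
        Ee <- E[[e]]
        w <- numeric(n)
        for (t1 in seq_len(nt)) {
          sel <- model$obs_trait == t1
          acc <- 0
          for (t2 in seq_len(nt))
            if (Ee[t1, t2] != 0)
              acc <- acc + Ee[t1, t2] * S[trm$lev[sel], t2]
          w[sel] <- acc
        }
        W[, k] <- w
        trv[k] <- sum(Ee * spm)
      }
    }
  }
  PW <- P %*% W
  AI <- 0.5 * crossprod(W, PW)
  grad <- -0.5 * (trv - drop(crossprod(W, Py)))  # d logL / d Sigma elements
  list(grad = grad, AI = AI)
}

# ---- the AI-REML driver -----------------------------------------------

reml_fit <- function(model, start = NULL, control = lmm_control()) {
  nt <- model$nt
  nterm <- length(model$terms)
  npb <- n_par_block(nt)
  term_names <- names(model$terms)

  floor_var <- control$floor_factor * model$var_y
  phi_floor <- 0.5 * log(floor_var)   # lower bound for log-diagonals
  diag_idx <- if (nt == 1L) 1L else c(1L, 3L)  # phi positions of log-diag
  diag_trait <- if (nt == 1L) 1L else c(1L, 2L)

  if (is.null(start)) {
    start <- lapply(term_names, function(nm)
      diag(model$var_y / nterm, nt))
    names(start) <- term_names
  }
  phi <- unlist(lapply(term_names, function(nm) chol_pack(start[[nm]])))

  clamp <- function(phi) {
    for (j in seq_len(nterm)) {
      off <- (j - 1L) * npb
      for (q in seq_along(diag_idx)) {
        lo <- phi_floor[diag_trait[q]]
        if (phi[off + diag_idx[q]] < lo) phi[off + diag_idx[q]] <- lo
      }
    }
    phi
  }
  phi <- clamp(phi)
  unpackS <- function(phi) {
    S <- lapply(seq_len(nterm), function(j)
      chol_unpack(phi[(j - 1L) * npb + seq_len(npb)], nt))
    names(S) <- term_names
    S
  }

  grad_phi <- function(phi, g_sigma) {
    # gradient in log-Cholesky space with active floor directions
    # projected out
    J <- matrix(0, nterm * npb, nterm * npb)
    for (j in seq_len(nterm)) {
      ix <- (j - 1L) * npb + seq_len(npb)
      J[ix, ix] <- chol_jac(phi[ix], nt)
    }
    g <- drop(crossprod(J, g_sigma))
    act <- logical(length(phi))
    for (j in seq_len(nterm)) {
      off <- (j - 1L) * npb
      for (q in seq_along(diag_idx)) {
        ii <- off + diag_idx[q]
        if (phi[ii] <= phi_floor[diag_trait[q]] + 1e-9 && g[ii] < 0)
          act[ii] <- TRUE
      }
    }
    list(g = g, J = J, act = act)
  }

  snap_phi <- function(phi) {
    # candidate with near-floor log-Cholesky diagonals set exactly to
    # the floor; jumps the geometric tail of a vanishing variance (or a
    # correlation heading to +-1 through a vanishing conditional
    # variance) straight to its boundary limit
    changed <- FALSE
    for (j in seq_len(nterm)) {
      off <- (j - 1L) * npb
      for (q in seq_along(diag_idx)) {
        ii <- off + diag_idx[q]
        lo <- phi_floor[diag_trait[q]]
        if (phi[ii] > lo + 1e-9 &&
            exp(2 * phi[ii]) < 1e-6 * model$var_y[diag_trait[q]]) {
          phi[ii] <- lo
          # a floored leading diagonal makes the cross term vanish too
          if (nt == 2L && diag_idx[q] == 1L) phi[off + 2L] <- 0
          changed <- TRUE
        }
      }
    }
    if (!changed) return(NULL)
    clamp(phi)
  }

  run_ai <- function(phi) {
    ev <- reml_eval(model, unpackS(phi))
    if (!ev$ok)
      return(list(phi = phi, ev = NULL, converged = FALSE, iter = 0L,
                  trace = numeric(0)))
    trace <- ev$dev
    converged <- FALSE
    iter <- 0L
    stall <- 0L   # successive steps with no deviance movement
    lam <- 0      # Levenberg-Marquardt damping, persistent across iters
    while (iter < control$max_iter) {
      iter <- iter + 1L
      ga <- reml_grad_ai(model, unpackS(phi), ev)
      gp <- grad_phi(phi, ga$grad)
      g <- gp$g; act <- gp$act; J <- gp$J
      H <- crossprod(J, ga$AI %*% J)
      g[act] <- 0
      H[act, ] <- 0; H[, act] <- 0; diag(H)[act] <- 1
      hscale <- max(diag(H), 1e-12)

      dev_old <- ev$dev
      ev_new <- NULL
      pred_drop <- Inf
      # adaptive damping: a rejected step raises lam (toward a short
      # gradient step), an accepted one lowers it (toward pure AI)
      for (round in 1:12) {
        Hl <- H + diag(lam, nrow(H))
        step <- tryCatch(solve(Hl, g), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) {
          step <- pmin(pmax(step, -10), 10)
          pred_drop <- sum(step * g)   # predicted drop in -2logL
          if (pred_drop < control$tol_dev && lam <= 1e-8 * hscale) break
          cand <- clamp(phi + step)
          evc <- reml_eval(model, unpackS(cand))
          if (evc$ok && evc$dev < dev_old - 1e-12) {
            phi_new <- cand; ev_new <- evc
            lam <- if (lam > 1e-10 * hscale) lam / 5 else 0
            break
          }
        }
        lam <- max(lam * 10, 1e-7 * hscale)
      }
      if (is.null(ev_new)) {
        ps <- snap_phi(phi)
        if (!is.null(ps)) {
          evs <- reml_eval(model, unpackS(ps))
          if (evs$ok && evs$dev <= dev_old + 1e-8) {
            phi <- ps; ev <- evs
            next
          }
        }
        # no step improved even under heavy damping: stationary to
        # numerical precision (the gradient audit below arbitrates)
        converged <- is.finite(pred_drop) && pred_drop < control$tol_pred
        break
      }
      dpar <- max(abs(phi_new - phi))
      phi <- phi_new; ev <- ev_new
      trace <- c(trace, ev$dev)
      if (control$verbose)
        cat(sprintf("  it %3d  -2logL %.6f  (lam %.2g)\n", iter,
                    ev$dev, lam))
      if (iter %% 10L == 0L) {
        ps <- snap_phi(phi)
        if (!is.null(ps)) {
          evs <- reml_eval(model, unpackS(ps))
          if (evs$ok && evs$dev <= ev$dev + 1e-8) { phi <- ps; ev <- evs }
        }
      }
      tol_eff <- max(control$tol_dev,
                     control$tol_rel * (1 + abs(ev$dev)))
      if (dev_old - ev$dev < tol_eff) {
        stall <- stall + 1L
        # dpar may stay large along directions the likelihood is flat
        # in (e.g. the cross-trait parameter of a floored block)
        if (dpar < control$tol_par ||
            (pred_drop < control$tol_pred && lam <= 1e-8 * hscale) ||
            stall >= 4L) {
          converged <- TRUE
          break
        }
      } else stall <- 0L
    }
    # stationarity audit: a "converged" claim must have a small
    # projected gradient, otherwise the run stopped on a ridge
    if (converged) {
      ga <- reml_grad_ai(model, unpackS(phi), ev)
      gp <- grad_phi(phi, ga$grad)
      if (max(abs(gp$g[!gp$act])) > 0.05) converged <- FALSE
    }
    list(phi = phi, ev = ev, converged = converged, iter = iter,
         trace = trace)
  }

  res <- run_ai(phi)
  if (is.null(res$ev))
    stop("restricted likelihood undefined at starting values")
  if (!res$converged) {
    # restart from the diagonalized current blocks: degenerate
    # (correlation +-1) blocks trap the AI step on a likelihood ridge
    S0 <- unpackS(res$phi)
    S0 <- lapply(S0, function(S) {
      d <- pmax(diag(S), 10 * exp(2 * phi_floor))
      diag(d, nt)
    })
    phi2 <- clamp(unlist(lapply(term_names, function(nm)
      chol_pack(S0[[nm]]))))
    res2 <- run_ai(phi2)
    if (!is.null(res2$ev) &&
        (res2$converged || res2$ev$dev < res$ev$dev))
      res <- res2
  }
  phi <- res$phi; ev <- res$ev
  converged <- res$converged
  iter <- res$iter; trace <- res$trace
  if (!converged)
    warning("AI-REML did not converge (", iter, " iterations)")

  Sigmas <- unpackS(phi)
  # quadratic polish: one undamped Newton step in covariance space.
  # Near the optimum the deviance is flat to machine precision while
  # the gradient is still computed accurately, so this tightens the
  # estimates beyond what deviance-based stopping can resolve.
  if (converged) {
    ga0 <- reml_grad_ai(model, Sigmas, ev)
    # tiny ridge: flat (confounded) directions have zero gradient, so
    # regularizing them does not bias the identified ones
    rid <- 1e-9 * max(diag(ga0$AI), 1e-300)
    dS <- tryCatch(solve(ga0$AI + diag(rid, nrow(ga0$AI)), ga0$grad),
                   error = function(e) NULL)
    if (!is.null(dS) && all(is.finite(dS)) &&
        max(abs(dS)) < 1e-4 * max(model$var_y)) {
      S2 <- Sigmas
      okpsd <- TRUE
      for (j in seq_len(nterm)) {
        d <- dS[(j - 1L) * npb + seq_len(npb)]
        D <- if (nt == 1L) matrix(d, 1, 1)
             else matrix(c(d[1], d[2], d[2], d[3]), 2, 2)
        S2[[j]] <- S2[[j]] + D
        eps <- 1e-12 * (max(abs(diag(S2[[j]]))) + 1e-300)
        if (inherits(tryCatch(chol(S2[[j]] + diag(eps, nt)),
                              error = function(e) e), "error"))
          okpsd <- FALSE
      }
      if (okpsd) {
        ev2 <- reml_eval(model, S2)
        if (ev2$ok && ev2$dev <= ev$dev + 1e-8) {
          Sigmas <- S2; ev <- ev2
        }
      }
    }
  }
  # flag boundary components
  boundary <- vapply(seq_len(nterm), function(j) {
    ix <- (j - 1L) * npb
    any(phi[ix + diag_idx] <= phi_floor[diag_trait] + 1e-9)
  }, TRUE)
  names(boundary) <- term_names

  # SEs from the AI matrix in covariance-element space at the optimum
  ga <- reml_grad_ai(model, Sigmas, ev)
  covS <- tryCatch(solve(ga$AI), error = function(e)
    matrix(NA_real_, nrow(ga$AI), ncol(ga$AI)))
  sev <- suppressWarnings(sqrt(diag(covS)))
  vc_se <- lapply(seq_len(nterm), function(j) {
    s <- sev[(j - 1L) * npb + seq_len(npb)]
    if (nt == 1L) matrix(s, 1, 1)
    else matrix(c(s[1], s[2], s[2], s[3]), 2, 2)
  })
  names(vc_se) <- term_names

  list(Sigmas = Sigmas, vc_se = vc_se, dev = ev$dev, ev = ev,
       converged = converged, iterations = iter, trace = trace,
       boundary = boundary)
}

# BLUPs of every random term from the final P y; additive effects are
# produced for every pedigree member, phenotyped or not
reml_blups <- function(model, Sigmas, Py) {
  nt <- model$nt
  A <- model$kin$A
  out <- list()
  z <- matrix(0, nrow(A), nt)
  for (t2 in seq_len(nt)) {
    b2 <- model$bidx[[t2]]
    z[, t2] <- A[, model$terms$additive$ind[b2], drop = FALSE] %*% Py[b2]
  }
  ahat <- z %*% Sigmas$additive
  dimnames(ahat) <- list(model$ped$id, model$traits)
  out$additive <- ahat
  for (nm in names(model$terms)) {
    if (nm %in% c("additive", "residual")) next
    trm <- model$terms[[nm]]
    S <- matrix(0, trm$nlev, nt)
    grp <- trm$lev + (model$obs_trait - 1L) * trm$nlev
    ag <- rowsum(Py, grp)
    gi <- as.integer(rownames(ag))
    S[cbind((gi - 1L) %% trm$nlev + 1L, (gi - 1L) %/% trm$nlev + 1L)] <- ag
    u <- S %*% Sigmas[[nm]]
    dimnames(u) <- list(trm$labels, model$traits)
    out[[nm]] <- u
  }
  out
}
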