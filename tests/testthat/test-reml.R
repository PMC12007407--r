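test_that("balanced one-way REML equals the ANOVA estimators", {
  # unrelated clones (A = I), one trial-year cell: the genetic terms
  # jointly estimate the between-clone variance and the residual is MSE
  set.seed(1)
  m <- 30; r <- 4
  ids <- sprintf("L%02d", 1:m)
  ped <- pedigree(ids, rep(NA, m), rep(NA, m))
  y <- rep(rnorm(m, 0, 2), each = r) + rnorm(m * r)
  ph <- data.frame(line_id = rep(ids, each = r), trial = "t1",
                   year = 2020, trait1 = y)
  fit <- suppressWarnings(fit_quiet(ph, ped, "trait1", alpha = 0.05,
    control = lmm_control(tol_dev = 1e-12, tol_par = 1e-10,
                          tol_pred = 1e-10, tol_rel = 0)))
  grp <- rep(seq_len(m), each = r)
  MSB <- r * stats::var(tapply(y, grp, mean))
  MSE <- sum((y - stats::ave(y, grp))^2) / (m * (r - 1))
  between <- sum(vapply(fit$vc[c("additive", "line", "gxty")],
                        function(S) S[1, 1], 0))
  expect_equal(between, (MSB - MSE) / r, tolerance = 1e-8)
  expect_equal(fit$vc$residual[1, 1], MSE, tolerance = 1e-8)
})

test_that("a 12-plot fit matches brute-force likelihood maximization", {
  # two full-sib families from related parents, 2 trials
  ped <- suppressMessages(pedigree(
    c("P1", "P2", "P3", paste0("C", 1:4)),
    c(NA, NA, "P1", "P1", "P1", "P3", "P3"),
    c(NA, NA, "P2", "P2", "P2", "P2", "P2")))
  set.seed(7)
  ph <- data.frame(
    line_id = rep(paste0("C", 1:4), each = 3),
    trial = rep(c("t1", "t1", "t2"), 4),
    year = 2020,
    trait1 = rnorm(12, 10, 2))
  fit <- fit_quiet(ph, ped, "trait1", alpha = 0.1,
                   control = lmm_control(tol_dev = 1e-12,
                                         tol_par = 1e-10,
                                         tol_pred = 1e-10, tol_rel = 0))

  # independent oracle: direct dense REML deviance + Nelder-Mead
  A <- tetra_amatrix(ped, 0.1)$A
  io <- match(ph$line_id, rownames(A))
  Z1 <- A[io, io]
  Zg <- outer(ph$line_id, unique(ph$line_id), "==") * 1
  cell <- paste(ph$line_id, ph$trial, ph$year)
  Zi <- outer(cell, unique(cell), "==") * 1
  X <- stats::model.matrix(~ trial, data = ph)
  n <- nrow(ph); p <- ncol(X)
  dev_fun <- function(lp) {
    tryCatch({
      v <- exp(lp)
      V <- v[1] * Z1 + v[2] * tcrossprod(Zg) + v[3] * tcrossprod(Zi) +
        v[4] * diag(n)
      ld <- determinant(V, logarithm = TRUE)$modulus
      Vi <- solve(V)
      M <- t(X) %*% Vi %*% X
      b <- solve(M, t(X) %*% Vi %*% ph$trait1)
      r <- ph$trait1 - X %*% b
      (n - p) * log(2 * pi) + as.numeric(ld) +
        as.numeric(determinant(M, logarithm = TRUE)$modulus) +
        as.numeric(t(r) %*% Vi %*% r)
    }, error = function(e) 1e10)
  }
  o <- stats::optim(log(rep(stats::var(ph$trait1) / 4, 4)), dev_fun,
                    method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, dev_fun, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit$minus2logL, o$value, tolerance = 1e-6)
})

test_that("REML is invariant to phenotype shifts and equivariant to scale", {
  sim <- simulate_program(small_cfg(), seed = 5)
  f0 <- fit_quiet(sim$pheno, sim$pedigree, "trait1", alpha = 0.05)
  # adding a constant changes only the intercept
  ph <- sim$pheno; ph$trait1 <- ph$trait1 + 100
  f1 <- fit_quiet(ph, sim$pedigree, "trait1", alpha = 0.05)
  expect_equal(f1$minus2logL, f0$minus2logL, tolerance = 1e-6)
  for (nm in names(f0$vc))
    expect_equal(f1$vc[[nm]], f0$vc[[nm]], tolerance = 1e-6)
  expect_equal(unname(coef(f1)[1] - coef(f0)[1]), 100, tolerance = 1e-6)
  expect_equal(coef(f1)[-1], coef(f0)[-1], tolerance = 1e-4)

  # doubling the phenotypes quadruples every component and leaves
  # heritability unchanged (scaling by 2 keeps arithmetic exact)
  ph2 <- sim$pheno; ph2$trait1 <- ph2$trait1 * 2
  st <- lapply(f0$vc, function(S) 4 * S)
  f2 <- fit_quiet(ph2, sim$pedigree, "trait1", alpha = 0.05,
                  start = st)
  f0b <- fit_quiet(sim$pheno, sim$pedigree, "trait1", alpha = 0.05,
                   start = f0$vc)
  for (nm in names(f0$vc))
    expect_equal(f2$vc[[nm]], 4 * f0b$vc[[nm]], tolerance = 1e-8)
  expect_equal(heritability(f2)$h2, heritability(f0b)$h2,
               tolerance = 1e-10)
  expect_equal(heritability(f2)$H2, heritability(f0b)$H2,
               tolerance = 1e-10)
})

test_that("the SCA model nests the baseline model", {
  for (s in c(4, 5)) {
    sim <- simulate_program(small_cfg2(), seed = s)
    m1 <- fit_quiet(sim$pheno, sim$pedigree, c("trait1", "trait2"),
                    sca = FALSE)
    m2 <- fit_quiet(sim$pheno, sim$pedigree, c("trait1", "trait2"),
                    sca = TRUE)
    lr <- lrt(m1, m2)
    expect_gte(lr$stat, 0)
    expect_equal(lr$df, 3L)
    # warm-started from the reduced solution the full model can only
    # improve on it
    st <- m1$vc
    st$sca <- diag(1e-8 * diag(m1$vc$residual), 2)
    m2w <- fit_quiet(sim$pheno, sim$pedigree, c("trait1", "trait2"),
                     sca = TRUE, start = st)
    expect_lte(min(m2$minus2logL, m2w$minus2logL),
               m1$minus2logL + 1e-6)
  }
})

test_that("data simulated without SCA drive the SCA variance to the floor", {
  cfg <- small_cfg()
  cfg$vc_true$sca <- matrix(0)
  sim <- simulate_program(cfg, seed = 8)
  m1 <- fit_quiet(sim$pheno, sim$pedigree, "trait1", sca = FALSE)
  m2 <- fit_quiet(sim$pheno, sim$pedigree, "trait1", sca = TRUE)
  expect_lt(m2$vc$sca[1, 1], 0.02 * m2$vc$residual[1, 1])
  expect_lte(m2$minus2logL, m1$minus2logL + 1e-4)
})

test_that("a bivariate fit with one empty trait reduces to the univariate fit", {
  sim <- simulate_program(small_cfg2(), seed = 9)
  ph <- sim$pheno
  ph$trait2 <- NA_real_
  fb <- suppressWarnings(fit_quiet(ph, sim$pedigree,
                                   c("trait1", "trait2")))
  ph1 <- sim$pheno
  fu <- fit_quiet(ph1, sim$pedigree, "trait1")
  expect_equal(fb$minus2logL, fu$minus2logL, tolerance = 1e-6)
  expect_identical(fb$traits, "trait1")
})

test_that("design assembly handles aliasing and flags confounded G x T x Y", {
  ids <- c("A", "B")
  ped <- pedigree(ids, c(NA, NA), c(NA, NA))
  # 2 clones x 2 trials x 1 year, two plots each: intercept + trial
  ph <- data.frame(line_id = rep(ids, each = 2),
                   trial = rep(c("t1", "t2"), 2), year = 2020,
                   trait1 = c(1.2, 3.4, 2.1, 4.4))
  expect_warning(fit <- fit_quiet(ph, ped, "trait1",
                                  control = lmm_control(max_iter = 5)),
                 "unidentifiable")
  expect_equal(length(coef(fit)), 2L)  # intercept + one trial contrast

  # replication within a cell: no confounding warning
  ph2 <- rbind(ph, ph)
  expect_silent(suppressMessages(suppressWarnings(
    tetra_lmm(ph2, ped, "trait1",
              control = lmm_control(max_iter = 3)))))
})

test_that("breeding-value prediction follows mixed-model identities", {
  sim <- simulate_program(small_cfg(), seed = 10)
  ped <- sim$pedigree
  # append an unphenotyped offspring of two existing lines
  par <- ped$id[c(50, 80)]
  ped2 <- pedigree(c(ped$id, "KID"), c(ped$parent1, par[1]),
                   c(ped$parent2, par[2]),
                   c(ped$crossing_year, NA))
  fit <- fit_quiet(sim$pheno, ped2, "trait1")
  kid <- predict(fit, "KID")[1, 1]
  mid <- mean(predict(fit, par)[, 1])
  expect_equal(kid, mid, tolerance = 1e-10)
  expect_error(predict(fit, "UNSEEN"), "not in pedigree")

  # constant phenotypes with saturated fixed effects: all BLUPs zero
  phc <- sim$pheno
  phc$trait1 <- 5
  fitc <- suppressWarnings(fit_quiet(phc, ped2, "trait1",
    control = lmm_control(max_iter = 30)))
  expect_lt(max(abs(predict(fitc))), 1e-6)

  # predictions correlate positively with the simulated truth
  cl <- unique(sim$pheno$line_id)
  expect_gt(stats::cor(predict(fit, cl)[, 1], sim$additive[cl, 1]), 0.3)
})

test_that("fitted values and residuals decompose the observations", {
  sim <- simulate_program(small_cfg(), seed = 12)
  fit <- fit_quiet(sim$pheno, sim$pedigree, "trait1")
  expect_equal(fitted(fit) + residuals(fit), fit$model$y,
               tolerance = 1e-10)
  # additive BLUPs centre near zero
  cl <- unique(sim$pheno$line_id)
  expect_lt(abs(mean(predict(fit, cl)[, 1])),
            2 * stats::sd(predict(fit, cl)[, 1]))
  # reported objects are coherent
  expect_s3_class(summary(fit), "summary.tetra_lmm")
  expect_true(is.matrix(vcov(fit)))
  expect_equal(attr(logLik(fit), "nobs"), fit$n_obs)
})
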