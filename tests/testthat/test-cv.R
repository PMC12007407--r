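test_that("five-fold partitions are balanced, seeded, and order-invariant", {
  ids <- sprintf("L%02d", 1:10)
  ped <- pedigree(ids, rep(NA, 10), rep(NA, 10))
  ph <- data.frame(line_id = rep(ids, each = 2), trial = "t", year = 1,
                   trait1 = rnorm(20))
  sc <- make_folds(ph, ped, "five_fold", seed = 7)
  expect_equal(unname(sort(lengths(sc$folds))), rep(2L, 5))
  expect_setequal(unlist(sc$folds), ids)
  # reproducible and invariant to phenotype row order
  sc2 <- make_folds(ph[sample(nrow(ph)), ], ped, "five_fold", seed = 7)
  expect_identical(sc$folds, sc2$folds)
  sc3 <- make_folds(ph, ped, "five_fold", seed = 8)
  expect_false(identical(sc$folds, sc3$folds))
  expect_error(make_folds(ph[1:6, ], ped, "five_fold"), "fewer than")
})

test_that("LBCO folds mask half sibs along with the cycle", {
  # K1 (year 1) and K2 (year 2) share parent A: masking cycle 1 must
  # also mask K2's phenotype, but K2 is scored in its own fold
  ped <- pedigree(c("A", "B", "C", "K1", "K2"),
                  c(NA, NA, NA, "A", "A"), c(NA, NA, NA, "B", "C"),
                  c(NA, NA, NA, 1, 2))
  ph <- data.frame(line_id = rep(c("K1", "K2"), each = 2),
                   trial = "t", year = 1, trait1 = rnorm(4))
  sc <- make_folds(ph, ped, "lbco")
  expect_length(sc$folds, 2L)
  expect_equal(sc$folds$cycle1, "K1")
  expect_setequal(sc$mask$cycle1, c("K1", "K2"))
  expect_setequal(sc$mask$cycle2, c("K1", "K2"))
  # one fold per crossing year on a long program
  cfg <- sim_config(n_founders = 8, n_cycles = 28, crosses_per_cycle = 2,
                    progeny_per_cross = 2, selection_fraction = 0.5)
  ped28 <- simulate_pedigree(cfg, seed = 1)
  ph28 <- data.frame(line_id = ped28$id[!is.na(ped28$parent1)],
                     trial = "t", year = 1, trait1 = 0)
  expect_length(make_folds(ph28, ped28, "lbco")$folds, 28L)
})

test_that("corrected clone means strip exactly the fixed part", {
  sim <- simulate_program(small_cfg(), seed = 14)
  fit <- fit_quiet(sim$pheno, sim$pedigree, "trait1")
  yc <- corrected_clone_means(fit)
  # recompute one clone by hand
  cl <- rownames(yc)[5]
  rows <- which(sim$pheno$line_id == cl)
  m <- fit$model
  obs <- which(m$obs_plot %in% rows)
  byhand <- mean(m$y[obs] - (m$X %*% fit$blue)[obs])
  expect_equal(unname(yc[cl, 1]), byhand, tolerance = 1e-10)
  # two identical plots average to either one
  ped <- pedigree(c("A", "B", "K"), c(NA, NA, "A"), c(NA, NA, "B"))
  ph <- data.frame(line_id = c("K", "K"), trial = "t", year = 1,
                   trait1 = c(3.3, 3.3))
  f1 <- suppressWarnings(fit_quiet(ph, ped, "trait1",
                                   control = lmm_control(max_iter = 5)))
  yc1 <- corrected_clone_means(f1)
  expect_equal(unname(yc1["K", 1]),
               3.3 - unname(coef(f1)[1]), tolerance = 1e-8)
})

test_that("a degenerate no-mask fold reproduces the full-data prediction", {
  sim <- simulate_program(small_cfg(), seed = 15)
  fit <- fit_quiet(sim$pheno, sim$pedigree, "trait1")
  clones <- sort(unique(sim$pheno$line_id))
  sc <- structure(list(kind = "five_fold",
                       folds = list(all = clones),
                       mask = list(all = character(0)), seed = 1L),
                  class = "cv_scheme")
  expect_warning(cv <- run_cv(fit, sc), "skipped")
  # nothing was masked anywhere, so no fold produced predictions
  expect_true(all(is.na(cv$abv)))

  # masking a single fold of everything equals re-deriving a_F when
  # the mask is empty: use a scheme whose mask equals its fold
  sc2 <- structure(list(kind = "five_fold",
                        folds = list(a = clones[1:8]),
                        mask = list(a = clones[1:8]), seed = 1L),
                   class = "cv_scheme")
  cv2 <- run_cv(fit, sc2)
  expect_equal(sum(!is.na(cv2$abv[, 1])), 8L)
  expect_true(all(abs(cv2$abv[clones[1:8], 1]) <
                    max(abs(predict(fit)[, 1])) * 2))
})

test_that("masking is total: shuffled masked phenotypes leave predictions identical", {
  sim <- simulate_program(small_cfg(), seed = 16)
  fit <- fit_quiet(sim$pheno, sim$pedigree, "trait1")
  sc <- make_folds(sim$pheno, sim$pedigree, "five_fold", seed = 16)
  cv <- run_cv(fit, sc)

  # permute the phenotypes of fold-1's masked clones among themselves,
  # rebuild the model at the same variance components, and re-solve
  masked <- sc$mask[[1]]
  ph2 <- sim$pheno
  rows <- which(ph2$line_id %in% masked)
  set.seed(1)
  ph2$trait1[rows] <- ph2$trait1[sample(rows)]
  kin <- tetra_amatrix(sim$pedigree, 0.05)
  m2 <- tetrablup:::assemble_model(ph2, sim$pedigree, "trait1", kin)
  keep <- !(m2$ped$id[m2$terms$additive$ind] %in% masked)
  sub <- tetrablup:::subset_model(m2, keep)
  ev <- tetrablup:::reml_eval(sub, fit$vc, need_P = FALSE)
  bl <- tetrablup:::reml_blups(sub, fit$vc, ev$Py)
  scored <- intersect(sc$folds[[1]], rownames(cv$abv))
  expect_identical(bl$additive[scored, 1], cv$abv[scored, 1])
})

test_that("pooled cross-validation statistics are coherent", {
  sim <- simulate_program(small_cfg(), seed = 17)
  fit <- fit_quiet(sim$pheno, sim$pedigree, "trait1")
  cv5 <- run_cv(fit, make_folds(sim$pheno, sim$pedigree, "five_fold",
                                seed = 17))
  cvl <- run_cv(fit, make_folds(sim$pheno, sim$pedigree, "lbco"))
  for (cv in list(cv5, cvl)) {
    expect_true(all(abs(cv$pa) <= 1))
    expect_true(all(abs(cv$rc) <= 1))
    expect_true(cv$theoretical_max > 0 && cv$theoretical_max <= 1)
  }
  expect_gt(cv5$rc, 0)
  # per-fold table covers every fold and trait
  expect_true(all(table(cv5$per_fold$fold) >= 1))
})
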