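# shared fixtures: tiny pedigrees and simulation configurations

# founders A, B plus a founder-cross family and a selfed line
toy_ped <- function() {
  pedigree(id = c("A", "B", "X", "Y", "S"),
           parent1 = c(NA, NA, "A", "A", "A"),
           parent2 = c(NA, NA, "B", "B", "A"))
}

# g-generation single chain: F0 x F0' -> G1, G1 x F_k -> G2, ...
chain_ped <- function(g) {
  id <- c("P0a", "P0b")
  p1 <- p2 <- c(NA_character_, NA_character_)
  prev <- "P0a"; other <- "P0b"
  for (k in seq_len(g)) {
    kid <- paste0("G", k)
    id <- c(id, kid)
    p1 <- c(p1, prev); p2 <- c(p2, other)
    if (k < g) {
      other <- paste0("Q", k)
      id <- c(id, other)
      p1 <- c(p1, NA_character_); p2 <- c(p2, NA_character_)
    }
    prev <- kid
  }
  pedigree(id, p1, p2)
}

# random pedigree: founders then random matings (occasionally selfs)
rand_ped <- function(n, n_founders, self_p = 0.15, seed = 1) {
  set.seed(seed)
  id <- paste0("I", seq_len(n))
  p1 <- p2 <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    if (stats::runif(1) < self_p) {
      s <- sample(i - 1, 1); p1[i] <- p2[i] <- id[s]
    } else {
      s <- sample(i - 1, 2); p1[i] <- id[s[1]]; p2[i] <- id[s[2]]
    }
  }
  pedigree(id, p1, p2)
}

# small univariate program for quick model fits
small_cfg <- function(...) {
  sim_config(
    n_founders = 12, n_cycles = 4, crosses_per_cycle = 8,
    progeny_per_cross = 4, selection_fraction = 0.3,
    vc_true = list(additive = matrix(2), line = matrix(0.4),
                   gxty = matrix(0.3), sca = matrix(0.25),
                   residual = matrix(1)),
    fixed_effects = list(mean = 10, sd_trial = 1, sd_year = 0.5,
                         sd_trial_year = 0.5),
    replication = list(trials_prob = c(0.6, 0.25, 0.15),
                       two_plot_frac = 0.4, n_segments = 2,
                       trials_per_segment = 3),
    n_loci = 100, trait_missing = 0, ...)
}

# small bivariate program
small_cfg2 <- function(...) {
  sim_config(
    n_founders = 12, n_cycles = 5, crosses_per_cycle = 8,
    progeny_per_cross = 5, selection_fraction = 0.25,
    vc_true = list(
      additive = matrix(c(2, 1, 1, 3), 2),
      line     = matrix(c(0.4, 0.1, 0.1, 0.6), 2),
      gxty     = matrix(c(0.3, 0.1, 0.1, 0.5), 2),
      sca      = matrix(c(0.25, 0.1, 0.1, 0.4), 2),
      residual = matrix(c(1, 0.2, 0.2, 1.5), 2)),
    fixed_effects = list(mean = c(10, 20), sd_trial = c(1, 1),
                         sd_year = c(0.5, 0.5),
                         sd_trial_year = c(0.5, 0.5)),
    replication = list(trials_prob = c(0.6, 0.25, 0.15),
                       two_plot_frac = 0.4, n_segments = 2,
                       trials_per_segment = 3),
    n_loci = 100, trait_missing = 0.05, ...)
}

fit_quiet <- function(...) suppressMessages(tetra_lmm(...))
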