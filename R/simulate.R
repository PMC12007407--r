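#' Configuration for the breeding-program simulator
#'
#' Collects the parameters of the synthetic tetraploid breeding program:
#' pedigree structure, the true double-reduction rate, true variance
#' components, fixed-effect sizes and the replication pattern of the
#' trial system.  Defaults emulate a dry-matter-like / yield-like trait
#' pair in a multi-cycle program with uneven replication (most clones in
#' one trial, few in many); they are illustrative of that regime, not a
#' reproduction of any particular dataset.
#'
#' @param n_founders number of founder clones (>= 4).
#' @param n_cycles number of breeding cycles (crossing years).
#' @param crosses_per_cycle crosses made per cycle.
#' @param progeny_per_cross clones kept per cross.
#' @param selection_fraction fraction of recent clones eligible as
#'   parents each cycle (random advancement).
#' @param self_frac fraction of crosses that are self-pollinations.
#'   Commercial potato programs avoid selfing (the default is 0);
#'   self-series research populations use it heavily, and because the
#'   double-reduction rate acts on inbreeding through every selfed
#'   meiosis, selfed material carries most of the likelihood
#'   information about that rate.
#' @param alpha_true true double-reduction rate used for gene dropping.
#' @param vc_true named list of per-term covariance matrices
#'   (`additive`, `line`, `gxty`, `sca`, `residual`), each `t x t`
#'   (t = number of traits) and positive semidefinite.
#' @param fixed_effects list with per-trait vectors `mean`, `sd_trial`,
#'   `sd_year`, `sd_trial_year`: effect sizes of the trial, year and
#'   trial-by-year fixed effects.
#' @param replication list with `trials_prob` (probabilities that a
#'   clone is tested in 1, 2, 3 trials), `two_plot_frac` (fraction of
#'   clone-trial-year cells with 2 plots, giving within-cell replication
#'   that identifies the G-by-T-by-Y variance), and `n_segments`,
#'   `trials_per_segment` (market segments, and trials nested in them).
#' @param n_loci number of independent gene-dropped loci composing the
#'   polygenic additive value.  Each locus carries allele effects drawn
#'   from `N(0, vc_true$additive / (4 * n_loci))`; summing over many
#'   loci makes the covariance of additive values conditional on the
#'   realized transmissions concentrate around
#'   `A(alpha_true) (x) Sigma_a` (with one locus the realized
#'   relationship matrix of a single meiotic history would dominate).
#' @param trait_missing per-trait probability that a plot's record for
#'   one trait is missing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 40,
                       n_cycles = 10,
                       crosses_per_cycle = 15,
                       progeny_per_cross = 8,
                       selection_fraction = 0.15,
                       self_frac = 0,
                       alpha_true = 0.05,
                       vc_true = list(
                         additive = matrix(c(3.2, 4.9, 4.9, 83), 2),
                         line     = matrix(c(0.2, 0.5, 0.5, 28), 2),
                         gxty     = matrix(c(0.3, 0.7, 0.7, 40), 2),
                         sca      = matrix(c(0.27, 0.28, 0.28, 7.5), 2),
                         residual = matrix(c(0.8, 1.2, 1.2, 186), 2)),
                       fixed_effects = list(
                         mean = c(23.5, 96.3),
                         sd_trial = c(1, 8),
                         sd_year = c(0.5, 4),
                         sd_trial_year = c(0.5, 4)),
                       replication = list(
                         trials_prob = c(0.76, 0.14, 0.10),
                         two_plot_frac = 0.3,
                         n_segments = 3,
                         trials_per_segment = 4),
                       n_loci = 300,
                       trait_missing = 0.05) {
  if (n_founders < 4) stop("need at least 4 founders")
  if (selection_fraction <= 0 || selection_fraction > 1)
    stop("selection_fraction must be in (0, 1]")
  nt <- nrow(vc_true$additive)
  for (nm in c("additive", "line", "gxty", "sca", "residual")) {
    B <- vc_true[[nm]]
    if (is.null(B) || !isTRUE(all.equal(B, t(B))) ||
        any(eigen(B, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("vc_true$", nm, " must be a symmetric PSD ", nt, "x", nt,
           " matrix")
  }
  cfg <- as.list(environment())
  cfg$n_traits <- nt
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-cycle breeding-program pedigree
#'
#' Founders are unrelated base clones; each cycle draws a random subset
#' of clones from the three preceding cycles (plus founders early on)
#' as parents and makes `crosses_per_cycle` crosses, each of two
#' distinct parents or (with probability `self_frac`) a
#' self-pollination.  Parent reuse across crosses creates half-sib
#' families; reuse across cycles creates overlapping generations, so
#' matings between relatives arise naturally in later cycles.
#'
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return A [pedigree]; founders carry no crossing year, all other
#'   clones carry their cycle's year (1, 2, ...).
#' @export
simulate_pedigree <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  id <- sprintf("F%03d", seq_len(cfg$n_founders))
  p1 <- p2 <- rep(NA_character_, cfg$n_founders)
  year <- rep(NA_integer_, cfg$n_founders)
  cyc_of <- rep(0L, cfg$n_founders)
  for (cyc in seq_len(cfg$n_cycles)) {
    pool <- id[cyc_of >= max(0L, cyc - 3L) & cyc_of < cyc]
    npar <- max(2L, round(cfg$selection_fraction * length(pool)))
    parents <- sample(pool, min(npar, length(pool)))
    if (length(parents) < 2L) stop("fewer than 2 parents in cycle ", cyc)
    for (cr in seq_len(cfg$crosses_per_cycle)) {
      pp <- if (stats::runif(1) < cfg$self_frac)
        rep(sample(parents, 1L), 2L) else sample(parents, 2L)
      kids <- sprintf("C%02d.%02d.%02d", cyc, cr, seq_len(cfg$progeny_per_cross))
      id <- c(id, kids)
      p1 <- c(p1, rep(pp[1L], length(kids)))
      p2 <- c(p2, rep(pp[2L], length(kids)))
      year <- c(year, rep(cyc, length(kids)))
      cyc_of <- c(cyc_of, rep(cyc, length(kids)))
    }
  }
  pedigree(id, p1, p2, year)
}

#' Drop tetraploid genomes down a pedigree
#'
#' Monte-Carlo allele transmission: founders receive four unique allele
#' labels; each gamete is, with probability `alpha`, two copies of one
#' uniformly chosen parental allele (double reduction) and otherwise two
#' distinct uniformly chosen parental alleles.  Unknown parents act as
#' fresh unrelated non-inbred clones.
#'
#' @param ped a [pedigree].
#' @param alpha double-reduction rate in \[0, 1\].
#' @param n_rep number of independent replicates.
#' @param seed optional RNG seed.
#' @return If `n_rep == 1`, an `n x 4` integer matrix of allele labels
#'   (rownames = line ids); otherwise an `n_rep x 4n` integer matrix
#'   with replicate rows (columns grouped 4 per line, pedigree order).
#' @export
gene_drop <- function(ped, alpha, n_rep = 1L, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  m <- cpp_gene_drop(p1, p2, alpha, as.integer(n_rep))
  if (n_rep == 1L) {
    g <- matrix(m[1L, ], ncol = 4L, byrow = TRUE,
                dimnames = list(ped$id, paste0("allele", 1:4)))
    return(g)
  }
  m
}

#' Monte-Carlo IBD oracle for relationship-matrix entries
#'
#' Estimates entries of the tetraploid additive relationship matrix by
#' repeated gene dropping: for a pair of distinct lines the
#' per-replicate kinship is the fraction of the 16 cross-line allele
#' pairs identical by descent (`A = 4 x` its mean); for a line with
#' itself the per-replicate inbreeding is the fraction of the 6
#' within-line allele pairs IBD (`A = 1 + 3 x` its mean).  Completely
#' independent of the recursive construction in [tetra_amatrix()], so it
#' serves as its verification oracle.
#'
#' @param ped a [pedigree].
#' @param alpha double-reduction rate.
#' @param pairs two-column matrix or data.frame of line ids, or `NULL`
#'   for all pairs including the diagonal.
#' @param n_rep number of gene-dropping replicates (>= 1e4 recommended).
#' @param seed optional RNG seed.
#' @return data.frame with columns `id1`, `id2`, `estimate`
#'   (relationship) and `se` (Monte-Carlo standard error).
#' @export
ibd_oracle <- function(ped, alpha, pairs = NULL, n_rep = 1e4, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  if (is.null(pairs)) {
    idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
    pairs <- cbind(ped$id[idx[, 1]], ped$id[idx[, 2]])
  }
  pairs <- as.matrix(pairs)
  ia <- match(pairs[, 1], ped$id)
  ja <- match(pairs[, 2], ped$id)
  if (anyNA(ia) || anyNA(ja)) stop("pair id not in pedigree")
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  alleles <- cpp_gene_drop(p1, p2, alpha, as.integer(n_rep))
  est <- cpp_ibd_pairs(alleles, as.integer(ia), as.integer(ja))
  data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
             estimate = est[, 1], se = est[, 2],
             stringsAsFactors = FALSE)
}

# unordered parent-pair key for the SCA term; lines with an unknown
# parent get a singleton key
sca_key <- function(ped, ids) {
  i <- match(ids, ped$id)
  p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
  key <- ifelse(is.na(p1) | is.na(p2),
                paste0("solo:", ids),
                paste(pmin(p1, p2), pmax(p1, p2), sep = " x "))
  key
}

rmvn <- function(n, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(sigma))
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% t(L)
}

#' Simulate phenotypes with the full model covariance structure
#'
#' Builds plot-level phenotypes `y = fixed(trial, year, trial:year) +
#' a + g + i + s + e` for all non-founder clones.  Additive values are
#' polygenic: at each of `cfg$n_loci` independently dropped loci every
#' unique allele gets an effect drawn from
#' `N(0, vc_true$additive / (4 n_loci))` jointly across traits, and a
#' clone's additive value sums its four alleles over loci, so
#' `cov(a) = A(alpha_true) (x) Sigma_a` holds in expectation at any
#' double-reduction rate and concentrates around it as loci accumulate.  Line, SCA
#' (unordered parent pair), genotype-by-trial-by-year and residual
#' effects are drawn from their covariance blocks; trial allocation
#' follows `cfg$replication`.
#'
#' @param ped a [pedigree] (from [simulate_pedigree()]).
#' @param genomes allele matrix from [gene_drop()] at `cfg$alpha_true`:
#'   either `n x 4` (one locus) or `n_loci x 4n` (one row per
#'   independent locus).
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return A list of class `sim_truth`: `pedigree`, `genomes`,
#'   `pheno` (plot-level data.frame with columns `line_id`, `trial`,
#'   `year`, `market_segment`, `trait1`, `trait2`, ...), true effect
#'   tables (`additive`, `line`, `sca`, `gxty` per level), the fixed
#'   effects used, and `cfg`.
#' @export
simulate_phenotypes <- function(ped, genomes, cfg, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nt <- cfg$n_traits
  traits <- paste0("trait", seq_len(nt))

  # polygenic additive values from per-locus founder-allele effects
  if (is.matrix(genomes) && !is.null(rownames(genomes)) &&
      ncol(genomes) == 4L)
    genomes <- matrix(t(genomes), nrow = 1L)   # single locus
  L <- nrow(genomes)
  ind_of <- rep(seq_len(nrow(ped)), each = 4L)
  a_true <- matrix(0, nrow(ped), nt, dimnames = list(ped$id, traits))
  for (l in seq_len(L)) {
    lab <- genomes[l, ]
    u <- unique(lab)
    eff <- rmvn(length(u), cfg$vc_true$additive / (4 * L))
    a_true <- a_true + rowsum(eff[match(lab, u), , drop = FALSE], ind_of)
  }

  clones <- ped$id[!(is.na(ped$parent1) & is.na(ped$parent2))]
  ci <- match(clones, ped$id)
  g_true <- rmvn(length(clones), cfg$vc_true$line)
  rownames(g_true) <- clones
  skey <- sca_key(ped, clones)
  ukey <- unique(skey)
  s_eff <- rmvn(length(ukey), cfg$vc_true$sca)
  rownames(s_eff) <- ukey

  # trial system: trials nested in market segments
  rep_cfg <- cfg$replication
  segs <- paste0("seg", seq_len(rep_cfg$n_segments))
  trials_of <- lapply(segs, function(s)
    paste0(s, ".T", seq_len(rep_cfg$trials_per_segment)))
  names(trials_of) <- segs
  seg_of_clone <- sample(segs, length(clones), replace = TRUE)

  rows <- vector("list", length(clones))
  for (j in seq_along(clones)) {
    ntr <- sample(seq_along(rep_cfg$trials_prob), 1L,
                  prob = rep_cfg$trials_prob)
    seg <- seg_of_clone[j]
    trs <- sample(trials_of[[seg]], min(ntr, length(trials_of[[seg]])))
    yr0 <- ped$crossing_year[ci[j]]
    if (is.na(yr0)) yr0 <- 0L   # undated clones tested from year 0
    yrs <- yr0 + sample(2:4, length(trs), replace = TRUE)
    nplot <- 1L + stats::rbinom(length(trs), 1L, rep_cfg$two_plot_frac)
    rows[[j]] <- data.frame(
      line_id = clones[j],
      trial = rep(trs, nplot),
      year = rep(yrs, nplot),
      market_segment = seg,
      stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, rows)
  plots$year <- as.integer(plots$year)

  # fixed effects
  fe <- cfg$fixed_effects
  all_trials <- unlist(trials_of, use.names = FALSE)
  all_years <- sort(unique(plots$year))
  eff_mat <- function(labels, sds) {
    m <- matrix(0, length(labels), nt, dimnames = list(labels, NULL))
    for (t in seq_len(nt)) m[, t] <- stats::rnorm(length(labels), 0,
                                                  sds[t])
    m
  }
  tr_eff <- eff_mat(all_trials, fe$sd_trial)
  yr_eff <- eff_mat(as.character(all_years), fe$sd_year)
  ty <- unique(plots[, c("trial", "year")])
  ty_eff <- eff_mat(paste(ty$trial, ty$year), fe$sd_trial_year)

  # gxty cells and residuals
  cell_key <- paste(plots$line_id, plots$trial, plots$year)
  ucell <- unique(cell_key)
  i_eff <- rmvn(length(ucell), cfg$vc_true$gxty)
  rownames(i_eff) <- ucell
  e_eff <- rmvn(nrow(plots), cfg$vc_true$residual)

  pj <- match(plots$line_id, ped$id)
  cj <- match(plots$line_id, clones)
  Y <- matrix(0, nrow(plots), nt)
  for (t in seq_len(nt)) {
    Y[, t] <- fe$mean[t] +
      tr_eff[plots$trial, t] +
      yr_eff[as.character(plots$year), t] +
      ty_eff[paste(plots$trial, plots$year), t] +
      a_true[pj, t] + g_true[cj, t] +
      s_eff[skey[cj], t] + i_eff[cell_key, t] + e_eff[, t]
    if (cfg$trait_missing > 0)
      Y[stats::runif(nrow(plots)) < cfg$trait_missing, t] <- NA
  }
  colnames(Y) <- traits
  # a plot with every trait missing carries no information
  keep <- rowSums(!is.na(Y)) > 0L
  pheno <- cbind(plots, Y)[keep, , drop = FALSE]
  rownames(pheno) <- NULL

  structure(list(pedigree = ped, genomes = genomes, pheno = pheno,
                 additive = a_true, line = g_true, sca = s_eff,
                 gxty = i_eff,
                 fixed = list(trial = tr_eff, year = yr_eff,
                              trial_year = ty_eff, mean = fe$mean),
                 cfg = cfg),
            class = "sim_truth")
}

#' Simulate a complete breeding program
#'
#' Convenience wrapper: [simulate_pedigree()], [gene_drop()] at the true
#' double-reduction rate, then [simulate_phenotypes()], all under one
#' seed.  Identical seeds give bit-identical results.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return A `sim_truth` (see [simulate_phenotypes()]).
#' @export
simulate_program <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  genomes <- gene_drop(ped, cfg$alpha_true, n_rep = cfg$n_loci)
  simulate_phenotypes(ped, genomes, cfg)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated breeding program\n")
  cat("  lines:", nrow(x$pedigree), " phenotyped clones:",
      length(unique(x$pheno$line_id)), " plots:", nrow(x$pheno), "\n")
  cat("  true double-reduction rate:", x$cfg$alpha_true, "\n")
  invisible(x)
}
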