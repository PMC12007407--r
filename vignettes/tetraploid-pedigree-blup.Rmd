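---
title: "Pedigree BLUP for autotetraploids with double reduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree BLUP for autotetraploids with double reduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrablup)
```

This vignette is the package's account of its science: the model, the
tetraploid relationship matrix, the estimation machinery, the
synthetic-data generator used for validation, and the numerical and
design choices that were genuinely open.

## The model

Plot-level phenotypes from a tetraploid breeding program are described
by, for one or two traits jointly,

$$ y = Xb + Z_1 a + Z_2 g + Z_3 i + Z_4 s + e $$

* $b$: fixed effects of trial, year and their interaction. Trials are
  market-segment specific (a "starch elite trial" is a different level
  from a "table elite trial"), so market segment enters through the
  trial factor. First-level reference coding; aliased columns are
  dropped automatically because breeding trial systems are very
  unbalanced.
* $a \sim N(0, A \otimes \Sigma_a)$: additive genetic effects, with
  $A$ the pedigree-derived tetraploid numerator relationship matrix at
  double-reduction rate $\alpha$ and $\Sigma_a$ an unstructured
  cross-trait block.
* $g \sim N(0, I \otimes \Sigma_g)$: a clone ("line") effect carrying
  the remaining non-additive genetic variation (and any permanent
  effect of the clone across trials).
* $i \sim N(0, I \otimes \Sigma_i)$: genotype-by-trial-by-year
  interaction, one level per (clone, trial, year) cell.
* $s \sim N(0, I \otimes \Sigma_s)$: specific combining ability,
  present only in the extended model ("M2"); the baseline model ("M1")
  omits it.
* $e$: plot residual with unstructured cross-trait block; a plot with
  one trait missing contributes only its observed sub-block (missing
  at random assumed).

The SCA term is keyed by the *unordered* parent pair, so reciprocal
crosses share a level; the effect represents the interaction between
the parental genomes, for which direction is immaterial. Lines with an
unknown parent get singleton keys: they cannot share a cross with
anyone, so they contribute to $\Sigma_s$ only through shrinkage.

## The tetraploid relationship matrix

In tetrasomic meiosis a gamete receives two of a parent's four
alleles. With probability $\alpha$ (double reduction) both gamete
alleles are copies of a single parental allele. Writing
$\theta_{ij}$ for the probability that a random allele of $i$ is IBD
to a random allele of $j$, $\phi_i = 1/4 + 3/4 F_i$ for self-kinship,
and $\gamma_p = \alpha + (1-\alpha) F_p$ for the within-gamete IBD of
a gamete from $p$, the offspring $i$ of $s \times d$ satisfies

$$ F_i = \tfrac16\gamma_s + \tfrac16\gamma_d + \tfrac23\kappa_{sd},
   \qquad \theta_{ij} = \tfrac12(\theta_{sj} + \theta_{dj}), $$

with $\kappa_{sd}$ the parental kinship ($\phi_s$ for selfing, 0 if a
parent is unknown). The matrix is reported on the founder-at-1 scale:
$A_{ii} = 1 + 3F_i$, $A_{ij} = 4\theta_{ij}$. This convention makes
$d(A) \approx 1$ for shallow pedigrees and puts $\sigma_a^2$ on the
scale of a non-inbred clone's additive variance; parent–offspring and
full-sib relationships equal $0.5$ at any $\alpha$ in non-inbred
pedigrees, and the selfing inbreeding increment at $\alpha = 0$ is
$1/6$. Unknown parents are treated as unrelated non-inbred base
individuals in which double reduction still occurs
($\gamma = \alpha$).

Two independent routes to $A$ exist in the package: the recursion
above and a gene-dropping Monte-Carlo oracle that simulates allele
transmission (with the same gamete model) and counts IBD fractions.
The test suite requires every entry of the recursion to match the
oracle within Monte-Carlo error on random pedigrees with selfing.

## Estimation

Variance components are estimated by REML. The engine works directly
on the observed-data covariance $V = \sum_j Z_j (I \otimes \Sigma_j)
Z_j' + R$ (dense, order = number of observed plot-trait records),
which at the package's design scale — traced sub-pedigrees, a few
thousand plots — is faster and simpler than sparse mixed-model-equation
factorizations. Updates are Newton steps using the average-information
matrix; first derivatives use exact trace terms.

Numerical choices:

* **Parameterization.** Each covariance block is optimized through its
  log-Cholesky factor (diagonal on log scale), which keeps every block
  positive semidefinite by construction, so an update can never leave
  the feasible cone. The fallback when a full AI step fails is
  therefore not a cone projection but damping (below).
* **Damping.** The AI step uses persistent Levenberg–Marquardt
  damping: a rejected step multiplies the damping (bending the step
  toward a short gradient step), an accepted one divides it. This is
  essential near degenerate optima — small bivariate datasets quite
  often place a block on the correlation $\pm 1$ boundary, where the
  undamped AI matrix is nearly singular.
* **Floors and boundaries.** Variances are floored at
  $10^{-10} \times$ the trait's phenotypic variance. Log-diagonals
  pinned at the floor with the gradient pointing further down are
  frozen (active-set projection), and components decaying
  geometrically toward the floor are snapped to it when that does not
  worsen the deviance. Boundary components are flagged on the fit.
* **Convergence.** Deviance change below $10^{-8}$ (absolute, or
  $10^{-9}$ relative for large deviances) with either a parameter
  change below $10^{-8}$ or a predicted remaining improvement below
  $10^{-3}$; at most 200 iterations; a converged claim is audited
  against the projected gradient. Because the deviance is flat to
  machine precision well before the parameters are, a converged fit
  takes one final undamped Newton step in covariance space (accepted
  only if it does not worsen the deviance), which carries closed-form
  cases to machine accuracy. Starting values split each trait's
  phenotypic variance equally across terms with zero cross-trait
  covariance.
* **Known limitation.** When several blocks sit exactly on the
  correlation boundary, cold-started fits of nested models can
  disagree by $\sim 10^{-3}$ deviance units; `lrt()` therefore
  re-solves the full model warm-started from the reduced solution
  whenever the recorded deviances violate nesting.

Fixed effects are estimated by GLS at the REML estimates and random
effects by BLUP; additive predictions are produced for every pedigree
member, phenotyped or not, through the relationship matrix.
Identifiability of the genotype-by-trial-by-year variance requires
clones replicated within trial-year cells; the assembler warns when no
such replication exists (the term is then confounded with the
residual).

## Estimating the double-reduction rate

$\alpha$ enters the analysis only through $A$. `profile_dr()` rebuilds
$A$ on a grid of rates (default $0.05, 0.1, \dots, 0.9$), refits the
model at each rate — fixed-effect structure held constant so the
restricted likelihoods are commensurable — and takes the deviance
argmin, with ties broken toward the smallest rate. Fits are
warm-started along the grid; a cold-start audit re-fits the argmin
point and checks agreement.

The information about $\alpha$ in such a profile deserves comment,
because it shapes what validation can demonstrate. The family
$\{A(\alpha)\}$ is close to scale-proportional: most of the change
with $\alpha$ is absorbed by rescaling $\hat\sigma_a^2$, and only the
*contrast* in inbreeding across individuals discriminates rates. In an
outcross-only program that contrast is small: a noise-free calculation
on a thousand-clone pedigree gives expected deviance differences of
order one unit across the whole grid — consistent with real
tetraploid datasets an order of magnitude larger resolving only "low
versus high" rates. Because every selfed meiosis adds $\alpha/3$ to
the offspring's inbreeding directly, selfed material carries most of
the attainable information; the rate-recovery experiment in the test
suite therefore uses a deep (25-cycle), partially selfed
(`self_frac = 0.4`), strongly bottlenecked program of about 880
clones — a self-series research population rather than a commercial
program — and recovery is asserted only at grid resolution (the true
point for a low rate, a grid neighbour for an intermediate one), in a
majority over five seeds.

## Heritability, variance shares, model comparison

Plot-level heritabilities use the average diagonal $d(A)$ to put the
additive variance on the plot scale:

$$ h^2 = \frac{d(A)\,\hat\sigma_a^2}{d(A)\,\hat\sigma_a^2 +
  \hat\sigma_g^2 + \hat\sigma_i^2 + \hat\sigma_s^2 + \hat\sigma_e^2},
  \qquad
  H^2 = \frac{d(A)\,\hat\sigma_a^2 + \hat\sigma_g^2 + \hat\sigma_s^2}
  {\text{same denominator}}, $$

with the $\sigma_s^2$ terms omitted under M1. A clone-mean variant
divides $\sigma_i^2$ and $\sigma_e^2$ by the (harmonic mean) numbers
of trial-year cells and plots per clone; it is an extension used for
the cross-validation ceiling below.

M1 vs M2 are compared by a likelihood-ratio test with degrees of
freedom equal to the number of extra (co)variance parameters in the
SCA block — one univariate, three bivariate — against the plain
chi-square. With the true SCA variance on the boundary of its space
this reference is conservative (the test suite checks a rejection rate
of at most 7.5% at nominal 5% over 200 null replicates); no mixture
correction is applied.

## Cross-validation

Two schemes over clones: a seeded random five-fold partition (all
plots of a clone in one fold), and leave-one-breeding-cycle-out
(LBCO), one fold per crossing year. For LBCO the masked set of a cycle
additionally contains every phenotyped clone sharing a known parent
with a cycle member, so full and half sibs cannot lend their
phenotypes to the prediction of that cycle; masked siblings are still
scored in their own fold. The published description of the sibling
rule is ambiguous; this reconstruction (fold = cycle, mask = cycle ∪
parents' other offspring) is the reading adopted here and is
documented rather than asserted.

Variance components are fixed at the full-data REML estimates inside
the folds and only the mixed-model solve is repeated (a `refit` flag
enables per-fold re-estimation); this stabilizes small folds and
matches common practice. Reported per trait, pooled over all scored
clones: predictive ability $\mathrm{PA} = \mathrm{cor}(\bar y_c,
\hat a_R)$ with $\bar y_c$ the clone means corrected by the full-data
fixed effects; accuracy ratio $\mathrm{RC} = \mathrm{cor}(\hat a_F,
\hat a_R)$; and the theoretical maximum of PA, $\sqrt{h^2_{\bar y_c}}$
computed from the clone-mean heritability with harmonic-mean
replication — a reconstruction, since only the concept and not a
formula is available for it.

## The synthetic-data generator

No real tetraploid breeding dataset ships with the package, so
validation rests on a generator that emulates one: founders, then
cycles of crosses among a random subset of recent clones (overlapping
generations, shared parents, optional selfing), phenotypes composed of
trial/year/trial-by-year fixed effects and the exact random-effect
structure of the model, and a trial system in which roughly 76% of
clones appear in one trial, 14% in two and 10% in three, with a stated
fraction of trial-year cells receiving two plots (which is what
identifies the interaction variance).

Additive values are built from founder-allele effects at `n_loci`
independently gene-dropped loci (default 300): each unique allele at
each locus receives an effect drawn from
$N(0, \Sigma_a / (4\,n_{loci}))$ and a clone's additive value sums its
four alleles over loci. This makes $\mathrm{cov}(a) = A(\alpha_{true})
\otimes \Sigma_a$ hold in expectation *at any rate* and concentrates
around it as loci accumulate. A single locus would not do: one meiotic
history's realized relationship matrix deviates from its expectation
$A$ by amounts that do not shrink with population size (a pilot showed
realized additive variance 35% below nominal), so single-locus data
cannot support parameter-recovery claims; the default emulates a
polygenic architecture instead. The same gene-dropping machinery at
`n_rep` replicates is the IBD oracle for $A$.

The default variance blocks emulate a strongly additive
dry-matter-like trait paired with a noisier yield-like trait (additive
share ≈ 67% and ≈ 24% respectively, small SCA) — illustrative of that
regime, not a reproduction of any dataset. What the generator does
*not* emulate: spatial field trends and inter-plot interference,
selection on phenotype during advancement (advancement is random),
heterogeneous residual variances per trial, linkage (loci are
independent), and locus-specific double-reduction rates (a single
genome-wide rate is used, as in the analysis model; real rates rise
from centromere to telomere). Passing tests therefore demonstrate
correctness of the machinery under the stated model, not robustness to
these departures.

## Problem sizes used by the test suite

Chosen to exercise each claim at the smallest scale that supports it:
oracle equivalence on five 18-line pedigrees × four rates × $10^5$
gene drops; closed-form and brute-force REML checks on 100-120 and 12
plots; bivariate SCA parameter recovery on one program of ~2,010 lines
(every (co)variance within 3 standard errors of truth); rate recovery
on ~880-line self-series programs, five seeds per true rate; LRT
calibration on 200 null replicates of ~120-line programs;
cross-validation properties on ~600-line programs over five seeds.

## Design decisions that were genuinely open

* **Completeness index.** Only anchor cases are commonly stated (1
  when both parents are known, 2 when all grandparents are). The
  package uses the simplest recursion consistent with them,
  $C(i) = \sum_{\text{known } p} (1 + C(p))/2$, which yields
  fractional values for ragged pedigrees.
* **A-matrix scaling.** Reported with founders at 1
  ($A_{ii} = 1 + 3F$); $\sigma_a^2$ is interpreted on this scale.
* **Interface.** The package follows the classic R modelling idiom —
  one fitting function returning a classed object with
  `print`/`summary`/`coef`/`predict`/`logLik`/`fitted`/`residuals`
  methods, plain functions around it — rather than a shell pipeline;
  `run_pipeline()` chains the stages for scripted use and accepts a
  YAML configuration.
* **Deviance comparability.** Profiles compare REML deviances across
  rates with the fixed-effect structure held fixed; deviance
  differences are invariant to phenotype shifts, which the tests
  assert.

## Session information

```{r}
sessionInfo()
```
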