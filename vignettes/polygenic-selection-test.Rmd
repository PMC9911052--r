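---
title: "Testing for selection on polygenic traits: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for selection on polygenic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the statistic

Selection on a polygenic trait moves many allele frequencies by a little
rather than a few by a lot.  Per-locus selection scans have essentially no
power in this regime: each locus's frequency shift is indistinguishable from
drift.  What selection cannot hide, however, is the *coordination* of the
shifts: alleles that increase the trait tend to move up together (or down,
under negative selection).

This package tests for that coordination with a composite statistic over all
$m$ genotyped markers,

$$\hat{G} \;=\; \sum_{j=1}^{m} \Delta_j\,\alpha_j,$$

where $\Delta_j$ is the change in counted-allele frequency at marker $j$
between an early and a late sample of the same population
(`frequency_change()`, late minus early), and $\alpha_j$ is the estimated
allele-substitution effect of that allele on the trait, in trait units per
allele copy (`fit_rrblup()` or `fit_bayesc()`).  Under drift alone the two
factors are uncorrelated, so $\hat{G}$ is centred at zero; directional
selection makes it positive (selection for the trait) or negative (selection
against it).  Both factors must be oriented to the same counted allele;
`align_effects_and_change()` enforces this, and flipping the orientation of
any marker (dosage $\to 2-$dosage, $\alpha \to -\alpha$,
$\Delta \to -\Delta$) leaves $\hat{G}$ unchanged.

## The permutation null and linkage disequilibrium

Significance is judged against a null in which effects are unrelated to
frequency changes: the $\alpha$ vector is repeatedly permuted against the
fixed $\Delta$ vector and the statistic recomputed (`ghat_test()`).
Permuting $\alpha$ rather than $\Delta$ is an arbitrary but fixed choice;
under exchangeability the two are equivalent.

The permutation treats markers as exchangeable, which they are not: linked
markers carry correlated $\Delta$s and correlated estimation errors in
$\alpha$, so the genome contributes far fewer *independent* observations
than $m$.  Ignoring this understates the null variance and inflates
significance.  Three corrections are offered:

* **`scale`** (default, recommended): the permutation standard deviation is
  inflated by $\sqrt{m / m_\mathrm{eff}}$, where $m_\mathrm{eff}$ is the
  effective number of independent genome segments.  The p-value is the
  two-sided normal tail of the scaled z-score.  A normal approximation is
  used deliberately: the correction is defined on a variance, which an
  empirical permutation rank cannot absorb; the permuted statistics are a
  sum of $m$ exchangeable products and are close to normal for any
  realistic $m$.
* **`trim`**: keep every `blocksize`-th marker in map order — a
  deterministic, seed-free thinning — and run the unscaled permutation test
  on the thinned vectors.
* **`naive`**: the unscaled test on all markers, valid only for independent
  markers; kept as a baseline and as the `scale` limit when
  $m_\mathrm{eff} = m$.

For `naive` and `trim` an exact empirical p-value $(r+1)/(P+1)$ over $P$
permutations is reported alongside the normal approximation.

The direction call (`positive` / `negative` / `none`) uses a configurable
significance level (default 0.05), and a confidence interval is
back-calculated from the p-value and the estimate via the normal-quantile
identity $SE = |\hat{G}| / |\Phi^{-1}(p/2)|$ (`ci_from_pvalue()`), which is
the standard way to recover an interval from a test statistic when no
analytic standard error exists.  The interval is flagged infinite when the
estimate is exactly zero or $p = 1$.

## Effective number of independent markers

Two estimators of $m_\mathrm{eff}$ are provided; both are invariant to
marker orientation and sample order.

**`simple_m()`** eigen-decomposes the marker correlation matrix per
chromosome and returns the smallest number of leading eigenvalues capturing
a fraction `var_fraction` (default 0.995) of the total eigenvalue mass,
summed over chromosomes.  Chromosomes with more than `block_size` (2,000)
markers are processed in contiguous non-overlapping blocks whose counts are
summed — the fixed-length blocking strategy of the original eigenvalue
method — because a full eigendecomposition is infeasible at very large $m$
and summing overlapping blocks would double-count markers.

**`ld_decay()`** estimates, per chromosome, how squared genotype correlation
$r^2$ decays with inter-marker distance: pairwise $r^2$ within a sliding
window of `max_win_snp` markers is binned by distance (bin width 1/100 of
the chromosome span), the binned means are smoothed by a monotone
non-increasing isotonic fit (raw binned means are noisy and no smoothing
rule is canonical), and the independence distance $d^\*$ is the first bin
at which the smoothed curve falls below `max_r2`.  The chromosome
contributes $\lceil \mathrm{span}/d^\* \rceil$ segments.  The default
`max_r2 = 0.03` is of the order of the chance $r^2$ ($\approx 1/n$) at a
few hundred samples, plus margin; when LD never decays below the threshold
the chromosome counts one segment, with a warning.  Positions are used in
whatever unit the map declares (bp or cM); only ratios of distances enter
the result.

## Estimating allele-substitution effects

**`fit_rrblup()`** fits $y = X\beta + Zu + e$ with
$u \sim N(0, I\sigma^2_u)$, $e \sim N(0, I\sigma^2_e)$, where $Z$ holds
column-centred dosages.  Centring uses the column mean; dosages are *not*
variance-standardised, so $\alpha_j$ stays in trait units per allele copy as
the statistic requires.  REML is exact, not iterative: the fixed part
(intercept, plus optional covariates such as year or environment, absorbed
by orthogonal projection) is projected out, the cross-product $Z'Z$ is
eigen-decomposed once, and the restricted likelihood is maximised by a
single 1-D search over $\lambda = \sigma^2_e/\sigma^2_u$ on the log scale
(search interval $e^{\pm 18}$, tolerance $10^{-10}$).  This is both faster
and more reproducible than EM-style iteration at the marker counts involved
(order $10^3$–$10^4$).  A degenerate trait (no residual variance after
projection) returns all-zero effects with a warning rather than an error,
since downstream code can still run.  Phenotypes may cover only a subset of
the genotyped samples — the "modern phenotypes" design — in which case the
fit uses the subset and `predict()` extends to all genotypes.

**`fit_bayesc()`** is a single-site Gibbs sampler for the spike-and-slab
model in which a fixed prior fraction $\pi$ (default 0.95) of markers has
exactly zero effect and the rest share a common effect variance.  Priors on
both variance components are scaled inverse chi-squared with $\nu = 4$
degrees of freedom and data-derived scales (half the phenotypic variance
apportioned to the genetic and residual sides); $\pi$ is fixed rather than
estimated, the original form of the method.  Defaults are 10,000 iterations
with 2,000 burn-in and a recorded seed; the returned effect is the
posterior mean (zeros included) with per-marker inclusion probabilities.
$\pi = 1$ short-circuits to all-zero effects; a diverging variance chain
stops with the iteration number.  Because the prior scales are data-derived,
the sampler is exactly scale-equivariant under a fixed seed — multiplying
all phenotypes by $c$ multiplies every posterior-mean effect by $c$ — which
the test suite exploits.

## The simulator

`simulate_study()` reproduces the validation design: candidate loci placed
uniformly on `n_chrom` chromosomes of `chrom_len` cM drift through
`n_hist = 100` generations of random mating (Wright–Fisher, diploid,
constant size), after which markers and QTL are ascertained among loci with
founder MAF $\ge 0.05$ (mimicking array design and preventing degenerate
monomorphic panels) and two populations evolve from the identical founder
state and RNG stream for `n_gen = 20` generations: population A mates at
random, population B undergoes truncation selection (the top
`selected_fraction = 0.2` by phenotype become parents — "strong" selection;
the exact published breeding scheme is not reproduced, so this is a config
key, not a claim of fidelity).  Recombination follows the Haldane mapping
function: crossovers are Poisson with mean `chrom_len`/100 per meiosis, no
interference.  QTL effects are standard normal rescaled so the additive
variance in the founder sample equals `h2` (phenotypic variance 1 at
generation 0); phenotypes add $N(0, 1-h^2)$ noise each generation.  The
test suite verifies the neutral arm against closed-form drift expectations
(variance of frequency change and heterozygosity decay per generation) and
the selected arm against the direction of the breeder's equation.

`test_selection()` applies the full analysis to one simulated population:
effects estimated from *all* recorded generations' genotypes and
phenotypes, frequency change between generations 15 and 20,
$m_\mathrm{eff}$ from `simple_m()`, and the `scale` permutation test.
One modelling detail matters greatly when effects are estimated across
generations: generation means must be absorbed as fixed effects.  With an
intercept-only fit, each generation's mean phenotype noise (standard
deviation $\sigma_e/\sqrt{n}$) is attributed to whatever marker-frequency
differences distinguish the generations — and the frequency change being
tested is *exactly* such a between-generation contrast, so the estimated
effects become coupled to $\Delta$ even under pure drift, inflating the
null.  With generation fixed effects the coupling vanishes (the null
p-value distribution is uniform to Monte-Carlo accuracy in the package's
calibration studies) and power is unchanged or better, because marker
effects are then estimated from within-generation variation only.
`test_selection()` therefore absorbs `factor(generation)` by default; the
same applies to real temporal data, where cohort or year-of-registration
means should be included as covariates in `fit_rrblup()`/`fit_bayesc()`.
`run_sweep()` replicates this over levels of one design parameter (sample
size, heritability, QTL number or marker density) with seed-paired
selected/unselected arms and summarises rejection rates.

### Problem sizes used in the package's own studies

The reference validation design (30 chromosomes, ~10,000 markers, 1,000
replicates) is far larger than what a test suite should run.  The package's
replicated studies therefore use the `desk_scale_config()` preset — 5
chromosomes × 100 cM, 1,000 markers, 150 QTL, $n = 200$ per generation,
$h^2 = 0.5$, 100 historical generations at $N = 200$ — chosen once so that
one simulate–estimate–test replicate takes roughly two seconds on one core,
and replicate counts of 60–100 per condition (8–15 per sweep level) are
practical.  At these counts the binomial noise on a rejection rate is a few
percent, which the test thresholds accommodate.  Two consequences of the
reduced scale are worth naming: drift is stronger at $N = 200$ than in a
livestock-scale population (the null is exercised harder, not less), and
the marker-density sweep (300–3,000 markers against ~4,200 genotyped
individuals) never enters the strongly multicollinear regime
($m \gg n$, hundreds of thousands of markers) where the full-scale design
shows its elevated null rejection; the desk-scale null stays close to
nominal at every density tested.

## What the generator does and does not emulate

The simulator produces unstructured, randomly mating populations with
biallelic loci, equal-effect-variance QTL, purely additive gene action and
a single phenotyped trait measured without year or environment structure.
It does not emulate population stratification or admixture, genotyping
error, missing-data patterns, dominance or epistasis, pedigree-based
selection on estimated breeding values, mutation, or overlapping
generations.  Passing the calibration suites therefore shows the test is
correct *under drift and truncation selection in an exchangeable
population*; it does not show robustness to cryptic structure, which in
real data must be assessed separately (the usual practice is a PCA of the
genotypes before trusting a selection signal).

## Numerical and design notes

* $\Delta$ is late minus early, so positive $\hat{G}$ means
  trait-increasing alleles rose in frequency.
* Frequencies weight individuals equally and use non-missing calls only;
  mean imputation is applied before effect estimation and LD computation,
  never before frequency computation.
* Markers monomorphic at both time points are retained ($\Delta_j = 0$
  contributes nothing); monomorphic markers are excluded from correlation
  and $r^2$ computations, where they are undefined.
* `{0,1,2}` coding is required; `{-1,0,1}` input is rejected rather than
  rescaled, since silent rescaling would corrupt allele orientation.
* The `scale` inflation is applied to the permutation *standard deviation*
  as $\sqrt{m/m_\mathrm{eff}}$; the type-I calibration suite is the arbiter
  of this convention, and the `scale` method with
  $m_\mathrm{eff} = m$ reproduces the naive p-value exactly.
* Exact invariances (statistic under orientation flips, p-value under a
  global flip or early/late swap) are asserted exactly in the tests;
  quantities that are invariant only in distribution (p-values under
  partial flips or joint relabelling) are asserted to Monte-Carlo
  tolerance.
* All randomness — simulation, sampler, permutations — flows through R's
  RNG, so a single `set.seed()` (or the `seed` arguments, which save and
  restore the ambient stream) makes every pipeline byte-reproducible.

## Known limitations

* The back-calculated confidence interval inherits the normal
  approximation; for p-values near 1 or estimates near 0 it is flagged
  infinite rather than fabricated.
* $m_\mathrm{eff}$ from `simple_m()` at `var_fraction = 0.995` is a
  convention, not an estimate of a physical quantity; the residual
  anticonservatism left by any single inflation factor is visible as a
  type-I error slightly above nominal in hard-LD regimes.
* The `trim` method discards information by construction and is dominated
  by `scale` whenever a credible $m_\mathrm{eff}$ is available.
* BayesC posterior means are Monte-Carlo estimates; runs are reproducible
  only under a fixed seed.
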