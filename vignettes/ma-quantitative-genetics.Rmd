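---
title: "Quantitative genetics of a two-environment mutation-accumulation experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of a two-environment mutation-accumulation experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutarch)
```

## The experimental design being modeled

A mutation-accumulation (MA) experiment propagates many independent lines
from a single ancestral genotype through repeated single-cell bottlenecks,
so that genetic drift rather than selection decides the fate of new
mutations. `mutarch` analyzes the two-environment version of this design in
diploid budding yeast: one set of lines bottlenecked on standard medium
("normal-MA", ~1,503 generations) and one on high-salt medium ("salt-MA",
~1,573 generations), with all fitness assays performed in the standard
environment. Four fitness components are tracked: diploid maximal growth
rate, sporulation efficiency, and — after sporulating a subset of lines and
dissecting tetrads — haploid viability (spores recovered per tetrad) and
haploid maximal growth rate.

Every analysis stage compares MA lines to the unmutated ancestor, which is
kept as frozen replicates. Because the ancestor has no line structure, all
variance comparisons impose the comparator treatment's line/replicate
structure on it through random pseudo-line partitions
(`ancestor_pseudo_lines()`), repartitioned in every bootstrap iteration.

## Moments: ΔM, V~m~, ΔV~E~, h²~m~

Per generation over `t` generations of MA:

* `delta_mean()`: ΔM = (mean of MA line means − ancestor mean) / t. Lines
  are weighted equally whatever their replicate counts.
* `among_line_variance()`: the among-line variance component of a one-way
  random-effects model, by direct restricted-likelihood maximization,
  profiled to a one-dimensional search. The component is deliberately left
  unconstrained (it can go negative) so that on balanced data the REML
  estimate coincides exactly with the ANOVA estimator
  (MS~between~ − MS~within~)/r; truncation at zero is the caller's choice
  and is applied inside square roots and CVs only.
* `mutational_variance()`: V~m~ = (among-line − among-pseudo-line)/t. The
  division is by `t`, not `2t`; the diploid `2t` convention is available as
  a labeled option.
* `delta_ve()`: the change in residual (within-line) variance relative to
  the ancestor, returned both total and per generation.
* `mutational_heritability()`: h²~m~ = V~m~/ΔV~E~ with ΔV~E~ *total* (not
  per generation) in the denominator — an intentional asymmetry of scales
  that the moments interface documents and preserves; the conventional
  V~m~/V~E,residual~ form is a flagged alternative.

Inference is by line-level bootstrap (`bootstrap_statistic()`): lines are
resampled with replacement within each treatment, the ancestor is
repartitioned into pseudo-lines each iteration, and two-sided p-values are
`2 min(P(stat* ≤ 0), P(stat* ≥ 0))`. Per-line departures from the ancestor
use a Steel-type many-to-one rank test (`many_to_one_rank_test()`); because
exact joint-rank tables are impractical for unbalanced designs, the
familywise null is calibrated by Monte-Carlo permutation of all
observations across groups (default 10,000 permutations).

## Nested variance components for derived haploids

Tetrad dissection makes the variance in haploid growth decomposable by
meiotic history: diploid parent line, tetrad within parent, haploid strain
(spore) within tetrad, and residual. `fit_nested_reml()` maximizes the
restricted likelihood of the four-component nested Gaussian model directly
(block likelihoods per parent; log-variance parameterization; multi-start
at 0.1×, 1×, 10× of a moment-based seed, plus a Nelder-Mead polish).
Components pinned at zero give the null fits for `lrt_component_zero()`;
because a variance of zero sits on the boundary of its parameter space, the
LR statistic is referred to the 50:50 mixture ½χ²₀ + ½χ²₁ (the standard
one-tailed boundary correction — the mixture weights are a documented
choice). Treatment comparisons of proportional components
(`compare_proportion_between_treatments()`) standardize each treatment to
mean 0, sd 1, and test a shared-versus-separate focal component by χ²₁.

The within-tetrad (spore) component is the genetically interesting one:
a heterozygous mutation segregates 2:2 among the four spores, so each locus
with haploid effect *a* contributes *a*²/4 to the expected within-tetrad
variance (exactly *a*²/4 in every tetrad for a single locus, additively in
expectation across loci). The simulator reproduces this law and the test
suite checks it by brute-force enumeration of the 6^k segregation patterns.

## Genetic correlations and the M-matrix

`fit_bivariate_lines()` fits the bivariate among-line model with an
unstructured 2×2 line covariance and independent trait-specific residuals.
Replicates of different traits come from different assays and are not
paired, so no residual covariance is identifiable — this is the module's
identifiability contract, not an approximation. The line covariance is
parameterized by its Cholesky factor (guaranteeing positive
semi-definiteness); fits where a line variance collapses to zero are
flagged inestimable rather than returning NaN (the situation the study hit
for haploid viability × haploid growth under normal-MA). LRTs against
r~g~ = 0 are two-tailed χ²₁; against r~g~ = 1, boundary-halved.

`assemble_m()` builds M from per-trait V~m~ and pairwise correlations
(M~ij~ = r~g,ij~ √(V~m,i~ V~m,j~)); flagged correlations propagate to
flagged entries, and `complete_submatrix()` restricts to the largest
complete trait set before any downstream comparison. `random_skewers()`
compares two M-matrices by the mean correlation of their response vectors
to 100,000 shared random unit-length selection gradients, against a null of
correlations between independent random vectors. `evolvability_max()` is
the dominant eigenvalue.

One genuinely open design point: "the correlation between the two response
vectors" can mean the Pearson correlation of their components or the
uncentered cosine. The package defaults to Pearson, which reproduces the
published three-trait metric (0.52–0.53 vs printed 0.53; the cosine gives
0.62), and offers `method = "cosine"`. The two differ in their geometry:
the cosine is exactly invariant under a common rotation of trait space,
while the Pearson metric centers components in the trait basis and is
therefore basis-dependent — the property tests exercise rotation
invariance on the cosine variant for this reason.

## Mutation rates and effect sizes

`bateman_mukai()` implements the moment method: U~min~ = ΔM²/V~m~ and
s~max~ = V~m~/|ΔM|, a lower bound on the genomic rate (and upper bound on
the effect) that is tight only when all effects are equal. For haploid
growth, method A uses the among-parent component only and method B the
total non-residual variance from the nested model; the estimate records
which was used.

`ml_line_likelihood()` is the package's central likelihood: an MA line mean
is `m0` plus a compound-Poisson sum of mutational effects plus Gaussian
measurement error. Mutation counts are Poisson(U·t); effect magnitudes are
gamma(shape β, rate α) with mean β/α, negative (deleterious, a decline)
with probability 1 − P~B~ and positive with probability P~B~ — a gamma
reflected about zero with the same shape and scale on both sides. The
density is evaluated by characteristic-function inversion: the CF of the
signed effect is closed-form, the compound-Poisson CF
`exp(λ(φ_s(ω) − 1))` is exact in the mutation number (no truncation of the
Poisson sum is needed), the Gaussian error multiplies in, and a single
midpoint-rule quadrature over frequency recovers the density. The
frequency grid adapts to the data: its extent comes from the Gaussian
factor's decay (the error sd), its resolution from the span of the
observations plus the effect-sum tail (a Poisson-count-quantile ×
gamma-quantile bound); if the required grid exceeds a hard cap the
function raises an error rather than silently degrading. On wide grids the
density integrates to 1 to ~1e-12, and it matches a 10⁷-draw Monte-Carlo
oracle within Monte-Carlo error (the test convolves the model with the
kernel bandwidth analytically, so that comparison has no smoothing bias).

`ml_profile_fit()` reproduces the profile strategy: β and P~B~ are fixed on
grids (defaults: the study's β grid 0.01–40 and P~B~ grid 0–0.55) while
(U, α) are maximized at each grid point; the equal-effects model is fitted
alongside as the β → ∞ envelope. The ancestral mean `m0` is by default
estimated jointly using the ancestor replicates' own Gaussian likelihood
term (a switch fixes it at the ancestor sample mean), and the line-mean
error variance is the ancestral residual variance divided by the harmonic
mean replicate count — the line-means simplification, with its documented
assumption that MA and ancestral replicates share an error variance.
Confidence bounds are 2-log-likelihood profile intervals: for U and the
mean effect the profile is walked outward from the MLE in log-steps,
maximizing over the remaining parameters and the (β, P~B~) grid, and the
crossing is interpolated; for β and P~B~ the interval is read off the grid
profile, coarse by construction, exactly as a grid search reports it. No
correction is made for selection during colony expansion between
transfers (a deliberate scope choice; the hook for it is the generative
simulator, not the estimator).

`dominance()` uses the paired declines of diploids and their derived
haploids for the same trait: with additive loci, w̄~dip~ = n·a(1+k) and
w̄~hap~ = n·a, so k = w̄~dip~/w̄~hap~ − 1 and h = (k+1)/2 independent of the
mutation number n. `estimate_dominance()` restricts both means to the
lines measured in both ploidies.

## The simulator: what it emulates and what it does not

`simulate_diploid_ma()` / `simulate_haploid_derivation()` generate the full
design: Poisson mutation counts per line, reflected-gamma homozygous effect
magnitudes, heterozygous expression h in diploids, free 2:2 segregation of
every mutation among the four spores of each tetrad, per-spore survival
`p0 · Π max(0, 1+s)` truncated to [0,1] for the viability count, and
Gaussian replicate noise. Default study conditions (`ma_study_configs()`):
42 / 47 lines, 1,503 / 1,573 generations, 10 replicates per line, 200
ancestor replicates, haploids from 17 / 21 lines with 5 tetrads each.
Mutational parameters default to the treatment-specific growth-rate
estimates (normal: U = 1.5e-4, β = 4.4, E(hs) = 0.060, h = 0.35; salt:
U = 3.6e-4, β = 1.8, E(hs) = 0.029, h = 0.20; P~B~ = 0), with homozygous
magnitudes E(hs)/h.

Choices the data do not pin down, made once and documented here:

* Trait baselines: ancestral sporulation efficiency 0.234 and mean
  viability 2.3 spores/tetrad are reported ancestral phenotypes; growth
  baselines (0.35 h⁻¹ diploid, 0.30 h⁻¹ haploid) are typical plate-reader
  values for this species.
* Residual sds: ancestral sds (0.04 growth, 0.08 sporulation) and inflated
  MA sds (e.g. 0.056 for normal-MA diploid growth) were set so the implied
  mutational heritabilities fall in the observed 1e-4 to 1e-3 range and
  ΔV~E~ > 0 (decanalization) holds where observed. They are per-trait
  knobs, not fitted quantities.
* Viability generation: the study gives no generative model for spore
  survival; per-spore Bernoulli survival with multiplicative fitness of
  carried mutations (baseline p0 = 0.575, matching 2.3/4) is a documented
  stand-in.
* Sporulation efficiency is simulated as a continuous trait like growth
  rate, although it is assayed as a fraction; at the observed scale
  (0.23 ± 0.1) the Gaussian approximation is harmless for the moment and
  REML machinery being tested.
* Pleiotropy: by default every mutation has the same magnitude on all
  traits (mutational correlation 1). `pleiotropy_rho` lowers the
  cross-trait copula correlation of magnitudes to exercise the
  genetic-correlation machinery; signs are always shared.
* Reproducibility: each line draws from its own deterministic RNG stream,
  so enlarging an experiment never changes existing lines.

Consequently, passing tests show that the estimators recover the generative
quantities of *this* model — additive loci, no epistasis, no selection
during MA, Gaussian noise, no genotype-by-assay interactions. They cannot
show that real fitness data satisfy those assumptions; in particular the
simulator has no petite/mitochondrial class, no plate structure unless the
growth-curve module is used, and no sequence-level information.

## Numerical conventions

* REML optimizations run over log variances with multi-start seeding; the
  one-way fit is profiled to 1-D and Newton-polished so balanced-design
  estimates agree with closed-form ANOVA to ~1e-8, and the nested fit is
  polished to <1e-6 of the closed form.
* Degenerate inputs (all observations identical) return all-zero
  components rather than failing; components below 1e-12 of the total are
  reported as exact zeros.
* Correlations at the boundary are pinned to ±(1 − 1e-9); inestimable
  bivariate fits are flagged, never silently NaN.
* The CF quadrature cap is 2^17 frequency points; `U = 0` short-circuits to
  the exact Gaussian likelihood.
* Bootstrap and skewers calculations are fully seeded; identical seeds give
  byte-identical results.

## Problem sizes used in the shipped analyses and tests

The `analysis/` scripts run the full study-scale design (89 lines, four
traits, 2,000 bootstrap iterations, 100,000 skewer vectors). The test
suite uses the same study-scale conditions for the calibration checks —
coverage of the 2-LL intervals at 47 lines × t = 1573 over 100 simulated
replicates (with the fitting grid β ∈ {0.5, 1, 2, 5}, P~B~ = 0 and m0
fixed at the ancestral mean, a problem-size choice for the replicated
fit), 600 null simulations × 1,000 bootstrap iterations at 42 lines for
the type-I check, and 250 simulations for the boundary-LRT check — and
smaller designs for unit oracles where the quantity being checked is
exact rather than statistical.

## Known limitations

A consequential interaction worth calling out explicitly: the line-means
likelihood assumes the error variance of MA line means equals the
ancestral residual variance over the replicate count. When mutation also
inflates the environmental variance — decanalization, which the simulator
emulates by default and the moments module estimates as ΔV~E~ > 0 — that
assumption is violated, and the ML fit absorbs the surplus within-line
spread as extra small-effect mutations, biasing U upward and the mean
effect downward while the Bateman-Mukai moments (which use the among-line
variance only) remain centered. The coverage calibration in the test suite
therefore generates line means under the likelihood's own error model;
analyses of decanalized data should read the ML rate as conditional on
that error assumption, exactly as the line-means simplification implies.

Other limitations:

* The bivariate REML handles trait pairs; a full four-trait multivariate
  fit is not implemented (the study's M-matrix is likewise assembled from
  pairwise estimates).
* Profile CIs for β and P~B~ inherit the grid's coarseness by design.
* The growth-curve position correction is a generic ancestor-referenced
  additive adjustment (optionally with a covariate regression); the
  original plate-correction formula was not published in the main text and
  is configurable here.
* The Steel-type test calibrates the joint null by permutation, which
  assumes exchangeability of replicates across groups under the null;
  heteroscedastic groups would need a studentized variant.
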