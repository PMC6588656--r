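---
title: "Models and methods in crosspred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in crosspred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

crosspred couples a simulator of a multi-parent wheat breeding population
with the two-stage genomic prediction workflow used to analyse such
populations. This vignette records the models, the parameters that matter,
the numerical choices, and the design decisions taken where the problem was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The simulated world

### Crossing design

`design_crosses()` builds a pedigree of bi- and tri-parental crosses subject
to *usage buckets*: groups of parents constrained to appear in a given range
of crosses. The default mirrors a commercial programme: 27 parents, 39
bi-parental and 5 tri-parental crosses, with 5 parents in six or more
crosses, 6 in three or four, 1 in exactly two and 15 in a single cross.
Counts are first sampled inside the buckets (minima assigned, surplus slots
distributed at random among parents with remaining capacity), then crosses
are assembled greedily, always drawing the parents with the most remaining
slots with random tie-breaking. The greedy order (three-parent crosses
first) keeps the maximum remaining count no larger than the number of
remaining crosses, so a feasible count vector is always realizable; the
result is validated against every bucket and infeasibility is reported with
the binding constraints.

### Genomes, meiosis and line development

Founders are fully inbred (elite cultivars; F1 uniformity requires it), so
one 0/1 haplotype per parent suffices. Marker allele frequencies across
founders follow a configurable spectrum (default uniform on 0.05–0.95).
Meiosis uses the Haldane model: per chromosome, crossover counts are Poisson
with mean equal to the map length in Morgans, positions uniform, no
interference. The default map is 2,000 markers on 21 chromosomes of 150 cM
(desk stand-in for a 35k array; fully configurable).

A bi-parental line descends from its own F2 plant (selfed F1), advanced by
single-seed descent to one F3 plant; the genotype is the mean dosage of six
selfed F4 plants, emulating DNA bulked from ~6 plants per F2:4 line, and is
therefore continuous in [0, 2] (a rounding flag gives hard calls).
Tri-parental crosses use the breeding convention (P1 × P2) F1 × P3, each
line descending from its own three-way F1. Closed forms used as test
oracles: expected within-cross allele frequency equals the parental mean
dosage over two, and F4 heterozygosity is (1/2)³ = 1/8 of the F1's.

### Trait

`simulate_trait()` draws additive effects at QTL positions; by default the
trait is polygenic (effects at *every* marker). This default matters: with
frequencies estimated in the data, centred genetic values equal `W a`, so
their covariance is exactly proportional to the VanRaden `G` built from the
same data and the GBLUP model is well-specified. With a sparse QTL subset
(`n_qtl` finite) part of the genetic variance is invisible to a G-based
model and every downstream variance and heritability estimate is attenuated
— a real phenomenon users can switch on deliberately. Drawn effects are
rescaled so the realized genetic variance is `var_g` (default 0.5 in squared
yield units, a typical genetic variance for wheat yield around site means of
5–11 t/ha); supplying explicit effects bypasses the rescaling.

### Trials

`allocate_trials()` reproduces the unbalanced 2-site × 2-season allocation:
crosses split into groups A (half; replicated at one season-1 location), B
(quarter; unreplicated in season 1) and C (quarter; absent in season 1,
replicated in season 2), with per-line plot-count patterns
(2,1,1,0)/(2,1,0,1)/(1,2,1,0)/(1,2,0,1) for A (balanced proportions after a
random shuffle), (1,1,1,1) for B and (0,0,2,2) for C — every line totals
exactly 4 plots. Entries are randomly grouped into contiguous sub-blocks
(emulating the α-lattice randomization) and repeated checks fill the plot
grid to a full rectangle; field dimensions and check counts are free
configuration, as the source design does not fix them.

`simulate_trials()` generates plot yield = site-year mean + genetic value +
spatial field + nugget. The field is a separable AR1(ρ_row)×AR1(ρ_col)
Gaussian process with unit marginal variance (Cholesky of the two AR1
correlation matrices). Defaults: ρ_row = ρ_col = 0.4 and an equal
spatial/nugget split — moderate, field-realistic values chosen once;
`scale_to_h2 = FALSE` turns the two parameters into absolute variances for
direct experimentation.

### Heritability calibration

The noise level is set from the heritability target (default 0.65). Three
bases are supported; the default, `"pm-locations"`, targets the quantity the
analysis itself reports: the Piepho–Möhring line-mean heritability
H̄² = σ²_g/(σ²_g + v/n) with `v` the total non-genetic plot variance and `n`
the per-line number of locations, averaged over lines (solved for `v` by
`uniroot`; monotone). Two calibration subtleties are deliberate:

* σ²_g is taken as `genetic_variance_reml(g, G)` — the package's own REML
  run on the noiseless genetic values — i.e. the genetic variance *as the
  analysis defines it*. For the polygenic default this essentially equals
  the closed form `g'G⁻¹g/N`; for sparse-QTL traits it is smaller, and using
  it keeps the estimated heritability centred on the target instead of
  systematically below it.
* `n` counts locations (2–4 under the unbalanced allocation), not plots, so
  lines observed at fewer locations contribute lower per-line values, as in
  the reported formula.

A `"plot"` basis (single-plot variance ratio) and `"line-mean"` basis
(constant plots per line) are available; under `"plot"` with
`sigma2_g = var(g)` the realized plot-level variance ratio equals the target
by construction.

## 2. The analysis pipeline

### Stage 1: spatial adjustment

Each trial is fit separately with `y = 1μ + Zg + s + ε`, `g` iid random line
effects, `s` the separable AR1×AR1 field, `ε` a nugget. The restricted
likelihood is profiled over the overall scale and maximized over
(ρ_row, ρ_col, two variance ratios): a coarse 3×3 grid over the
autocorrelations (robust to multimodality) followed by Nelder–Mead on
transformed parameters (ρ = 0.95·tanh z keeps the search inside
(−0.95, 0.95); log ratios clamped to e^±25), relative tolerance 1e−8,
maximum 200 iterations, non-convergence flagged with best-found parameters.
Two algebraically identical routes compute the likelihood: a dense route on
the covariance of observed plots (any layout; missing cells handled by
subsetting, no imputation) and an eigen/Woodbury route when the trial covers
a complete grid and lines are few relative to plots (the AR1⊗AR1 kernel is
diagonalized by the Kronecker eigenbasis, making each evaluation O(L²·n)
instead of O(n³)). Route agreement is itself a test. Grids with a single
row or column fall back to one-dimensional AR1 with a warning.

Variance parameters are estimated with line effects *random* (near-saturated
trials leave far too few residual degrees of freedom to estimate four
covariance parameters around fixed line effects). The removed trend,
however, is computed by default with line effects *fixed* at their GLS
estimates (`trend_method = "gls"`): the field is predicted only from the
genotype-free residuals, so the adjustment provably cannot absorb genetic
contrasts. This distinction matters at one plot per line per trial, where
genotype, the white component of the field, and nugget are confounded at a
single plot: the joint BLUP (`trend_method = "blup"`) splits each plot's
deviation among them and attenuates the downstream genetic variance by tens
of percent, while the GLS trend leaves the regression of line BLUEs on true
genetic values at slope ≈ 1 (the package's tests measure both). The cost is
weaker smoothing in near-saturated trials — the information for separating
field from genotype simply is not in such a design, and the package prefers
unbiased downstream genetics over aggressive-looking adjustment.

The adjusted value is raw − trend (identity tested to numerical tolerance),
and per-trial summaries report line counts, mean, CV% and the raw–adjusted
correlation of line means.

### Stage 2: BLUEs

`estimate_blues()` solves the fixed-effects model `value = trial mean + line
effect` over all trials by exact sparse normal equations, identifiability
fixed by a sum-to-zero constraint on line effects (a Lagrange row), and
reports BLUEs re-centred on the grand mean so differences are exact GLS
contrasts. Plots are weighted equally (the combining model is unweighted as
printed). Disconnected line–trial incidence is detected by graph traversal
and reported as an error listing the groups. The fixed-effect choice (true
BLUEs, not BLUPs) follows the standard reading of a two-stage pipeline.

### GRM

VanRaden method 1: `G = WW'/(2Σpᵢ(1−pᵢ))`, `W` the column-centred dosages,
frequencies estimated on the full genotyped set (training plus validation —
this leaks no phenotype information). Markers with zero dosage variance are
excluded from numerator, denominator and the marker count. Continuous bulk
dosages enter the formula unchanged. `stabilize()` adds a recorded ridge
(default 1e−6) before inversion.

### AI-REML and prediction

`fit_aireml()` estimates (σ²_g, σ²_e) for `y = μ + g + e`,
`g ~ N(0, Gσ²_g)`. All per-iteration quantities (traces, quadratic forms,
average-information matrix) are O(n) in the eigenbasis of the training block
of G, computed once. The update is the AI step; whenever it would push a
component below the floor (1e−8 × total variance — components are floored,
never negative) or decrease the restricted likelihood, an EM-REML step is
taken, with step-halving of the AI direction as a last resort. Convergence
follows the normalized-component rule |θ⁽ᵗ⁺¹⁾ − θ⁽ᵗ⁾| < 1e−5 with θ the
variance components divided by their sum; maximum 100 iterations; start
values are half the sample variance of `y` each. A constant response returns
the boundary estimate σ²_g = 0 with a warning.

`predict_lines()` offers the full mixed-model equations and the
conditional-mean form ĝ = σ²_g G·ₜ Vₜ⁻¹(y − μ̂); the two are algebraically
identical and tested to 1e−8. Predictions are invariant to adding a constant
to the training phenotypes (absorbed by μ̂).

### Cross-validation machinery

All resampling designs emit `training_design` objects whose
training/validation disjointness is enforced at construction: tenfold with
whole crosses as folds (fold sizes as equal as possible, re-sampled per
replicate), tenfold over individual lines, leave-one-cross-out, random
masking of training fractions, the crosses-by-lines grid (n lines from each
of n crosses, infeasible cells skipped with a message), and
relatedness-stratified designs (one-parent, both-parents, unrelated, mixed)
with 0–3 quarters of the validation cross added to training and evaluation
on the held-out quarter, cycling quarters across replicates. "Related" is
purely pedigree-based (shares ≥ 1 parent); no genomic threshold is imposed.
Quarters are a fixed random partition per master seed so quarter-cycling is
exhaustive and reproducible. `run_designs()` re-estimates variance
components for every training set. Accuracy is the Pearson correlation
between validation BLUEs and predictions, within each validation cross
and/or pooled; the Wald test uses r√((n−2)/(1−r²)) on n−2 degrees of
freedom, one-sided against ρ > 0; accuracy increments are compared by paired
two-sided t tests with degenerate inputs (zero-variance differences)
handled by convention (p = 1 for identical pairs). `top_fraction_accuracy()`
recomputes accuracy on the k best lines per cross by BLUE (default 15),
exposing range-restriction attenuation.

## 3. What a green test does and does not establish

The generator reproduces the statistical *structure* of a real programme —
pedigree relatedness, Mendelian sampling through three selfing generations,
bulk genotypes, unbalanced trials, autocorrelated field noise, a stated
heritability. It deliberately omits: linkage disequilibrium among founders
(allele draws are independent given the spectrum; no coalescent history),
genotyping error and marker QC artifacts, genotype-by-environment
interaction (one genetic value per line across trials), non-additive gene
action, and selection during line development. Consequently simulated
prediction accuracies are substantially higher than those typical of real
multi-parent wheat data, and green trend tests establish directions and
orderings (accuracy rises with training size; related beats unrelated;
many-crosses-few-lines beats the reverse at fixed size; partial inclusion of
the validation cross helps monotonically), not real-data magnitudes. One
trend needs scale to emerge: the fixed-size crosses-versus-lines advantage
is a statistical tie when only ~14 candidate crosses exist (both arms then
almost always contain relatives of the validation cross) and reappears
clearly with a 30-cross pool, closer to a commercial programme's.

## 4. Numerical choices and degenerate inputs

* ρ search bound 0.95; coarse grid {−0.5, 0, 0.5}²; likelihood evaluations
  returning non-finite values score +1e10.
* AR1 kernels are built from power look-up tables indexed by integer lag,
  avoiding repeated `pow` calls.
* Eigen route eligibility: complete grid and L ≤ n/3 (beyond that the dense
  Cholesky is cheaper); both routes share the dense final pass for
  variances and trends.
* GRM with all markers monomorphic, BLUEs on disconnected designs,
  correlations of zero-variance vectors, heritability with σ²_g = v = 0,
  |r| = 1 in the Wald test, and zero-variance paired differences all have
  explicit, tested behaviours (error, error, NA, NA with warning, p ∈ {0,1},
  p ∈ {0,1} respectively).
* All randomness flows from one master seed through `child_seed()` (an
  affine map kept below 2³¹), so every stage is independently reproducible
  and pipeline reruns are byte-identical.

## 5. Known limitations

Full-scale spatial fits (~3,000 plots per trial) take minutes each with the
dense route; the eigen route does not apply there because lines ≈ plots.
The GLS trend is a near-no-op in trials with almost no replication — by
design, but users wanting ASREML-like smoothing at the cost of genetic
attenuation should set `trend_method = "blup"`. Heritability estimated
through the full pipeline still sits slightly below the generator target
(the spatial stage and BLUE step are not information-free); the acceptance
suite quantifies this within ±0.1. The inter-quantile summaries reported for
accuracy distributions use the 10th/90th percentiles; the convention in the
source material is not fully specified.
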