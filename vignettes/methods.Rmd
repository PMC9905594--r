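---
title: "Source apportionment of co-culture volatilomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source apportionment of co-culture volatilomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covolatilome)
```

## The problem

When a fungus and a bacterium are co-plated, the headspace volatile profile
(volatilome) of the plate mixes three sources: the growth medium itself,
the bacterium, and the fungus — and each partner may also *consume*
volatiles the others emit. PTR-ToF-MS measures this mixture as a wide
table of concentrations (ppbV) per mass peak. This package implements a
complete analysis of such tables: background correction against the
medium, production/consumption calling, linear source apportionment of
co-cultures, discovery of interaction-regulated volatiles, discriminant
classification, and growth-rate statistics.

## Background correction against the medium null

Each peak's null distribution is built from the medium-blank vials
(3 vials × 4 time points = 12 measurements). A straight-line fit of blank
concentration on time decides the null's form: if the slope is
insignificant the 12 observed values are the null; if significant, the
null is drawn from a normal with the model-predicted mean *at the sample's
own time point* and the residual standard deviation — the trend is exactly
why the pooled observations would be invalid.

Every individual measurement is then tested against its null. The default
test is the prediction-interval form

$$t = \frac{x - \bar{x}_0}{s_0\sqrt{1 + 1/n_0}}, \qquad df = n_0 - 1,$$

which asks whether a *single draw* is consistent with the null
distribution and therefore holds the false-nonzero rate at the nominal
$\alpha$. The alternative of comparing the measurement to the null *mean*
(standard error $s_0/\sqrt{n_0}$) is available via `method = "mean"`, but
it treats a one-off measurement as if it were an estimate of the null mean
and rejects far too often (a ~50% false-nonzero rate in simulation); we
made the calibrated form the default so that the corrected value zero
means what it should. Significant measurements become signed differences
from the null mean — positive production, negative consumption — and
insignificant ones become exactly zero. No detection threshold is applied
at this stage; thresholds act downstream on calls and group means.

In simulations where cultures are statistical copies of the blanks, the
observed nonzero rate sits slightly above $\alpha$ (≈ 0.06 at
$\alpha = 0.05$): peaks whose blank series is randomly "trendy" are
switched to model-drawn nulls, and that selection costs a little
calibration. This is intrinsic to the trend-switching rule, not a bug.

## The three decomposition models

Per strain, with per-peak means over replicates and time points (central
limit smoothing), the models are

* model 1: $C = a B + b F$ over all retained peaks;
* model 2: $C = a B$ over the peaks the fungus neither produces nor
  consumes (operationally: corrected fungal mean exactly zero, bacterial
  mean positive);
* model 3: $C - \hat{a}_2 B = b F$ over the peaks the fungus produces or
  consumes.

Intercepts are fitted and *reported*, not suppressed: a zero intercept is
a checkable prediction of the additive model, and fitting it keeps the
test honest (`through_origin = TRUE` gives the constrained variant).
Observations are unweighted peak means; the source study gives no
replicate-variance weighting and we do not invent one. Model 3 is fitted
regardless of the significance of $\hat{a}_2$, carrying the upstream
p-value in the result, since a gate level is nowhere stated.

Coefficients are compared across models by value, not standardized,
because they share units by construction.

## Regulated volatiles from recurrent residual outliers

A volatile regulated by the interaction violates additivity in the same
direction across strains. We flag per-fit outliers with externally
studentized residuals (|z| > 2 by default) — the leave-one-out form, so a
large outlier does not mask itself — and report peaks flagged in at least
`min_frequency` strain-models (default: 25% of the fits supplied),
with per-strain deviation signs and a per-species direction summary.
Under heteroscedastic concentration noise any common-scale residual rule
is imperfect: very abundant peaks carry more residual variance and very
faint deviations hide below the pooled scale. The defaults are tuned to
the regime the emulated study reports — regulated compounds that are
abundant (tens of ppbV) and deviate several-fold.

## The discriminant stage

Each measurement row (sample × time point) is one observation. The split
is stratified per class (so both partitions represent every group),
seeded, and 70/30 by default; centring and unit-variance scaling are
fitted on the training rows only; near-constant training peaks
(sd < 1e-6) are dropped. Only discriminants carrying ≥ 10% of the
between-class variance are retained for interpretation, and association
scores are read from the discriminant scaling with a 5% two-tail extreme
rule (the study states no tail width; 5% is conventional). Centroid
distances between a strain's pure- and co-culture rows use *all* model
LDs. A numeric surrogate for the graphical variance-homogeneity check
(log covariance-determinant ratio) was considered and not gated on; the
emulated analysis confirms homogeneity visually and so do we, by the
autoplot method.

## Growth-rate ANOVA

The nested fixed-effects model uses sequential (type-I) sums of squares in
the order: species, medium, cultivation mode, strain-in-species, then the
two-way and three-way interactions. Sequential SS makes the %SS effect
sizes a single exact decomposition of the total sum of squares (residual
included), which is how the emulated study's effect column reconciles.
Model reduction drops insignificant terms at $\alpha$ starting from the
highest-order interactions and never drops a term contained in a kept
higher-order term. Pure-vs-co growth comparisons are Welch tests per
strain × medium with no multiplicity correction, matching the per-strain
reporting style of the source tables.

## The synthetic world

`simulate_experiment()` emulates the study design: 6 species / 25 strains
by default, 113 peaks, 3 technical replicates × 4 time points, 3 medium
and 3 empty blank vials, 5 growth replicates per strain × medium × mode.
Peak roles split into medium-emitted (22%), bacterially produced (28%,
higher levels — the bacterium is the better producer), fungally produced
(14%, faint: log-normal around 0.6 ppbV), fungally consumed (12% of
medium-emitted levels, consuming 60–95% of the medium emission),
isotopologues (10%, shadowing a parent at a fixed 1–8% ratio), and inert
noise. Co-cultures are additive in the pure-culture signals scaled by
latent per-strain coefficients `a_true`, `b_true`; a planted set of
regulated peaks multiplies its culture contribution by a factor ≥ 3 or
≤ 1/3.

Noise has three layers, all parameters of the design:

* technical: multiplicative log-normal, sd 0.03 — the replicate scale of
  direct headspace injection on a stable autosampler;
* biological: per vial × peak log-normal, sd 0.15, multiplying the
  culture contribution only. This is what keeps peak columns from being
  mutually proportional (real production ratios vary between vials);
  without it every bacterial peak would correlate with every other at
  r > 0.99 and the autocorrelation filter would eat the dataset;
* an additive half-normal floor (sd 0.02 ppbV) for instrument baseline.

Regulated peaks are planted among the bacterially produced majors, with
up-regulation on mid-abundance peaks and down-regulation on more abundant
ones, so both directions deviate from additivity by comparable absolute
amounts — in the emulated study every recurrent outlier is a major
compound (formaldehyde at ~91 ppbV, methanol at ~41 ppbV, ethanol, acetic
acid, acetoin).

What a green test on this world does establish: the estimators are
unbiased and well-calibrated when their assumptions hold, the filters
recover the planted structure, and the pipeline is deterministic under a
seed. What it does not establish: robustness to matrix effects,
instrument drift beyond a linear blank trend, non-multiplicative
regulation, or the taxon-specific covariance structure of real
volatilomes — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Autocorrelation groups are resolved transitively (union-find); the
  lowest-m/z member survives, because the removed peaks are typically
  heavier isotopologues. Constant columns have undefined correlations and
  are kept with a warning.
* Zero-variance nulls declare any deviating measurement significant, with
  a warning — the measured difference is then the corrected value.
* Collinear decomposition predictors abort with the condition number;
  model 2 with fewer than 3 eligible peaks is *skipped with a status*
  rather than errored, mirroring sparse strains in real tables.
* Concentration display bins are closed on the left (0.2 ppbV falls in
  bin 1).
* Bin, threshold and LRI computations are vectorized and exact; the LRI
  refuses to extrapolate outside the alkane ladder.
* All stochastic steps (simulation, model-drawn nulls, LDA splits) take
  explicit seeds; a pipeline run is byte-reproducible from its config.

## Scale of the shipped test suite

Monte-Carlo properties are asserted at 50 seeds where they are cheap
(coefficient recovery, regulated-VOC recovery, type-I calibration, LDA
permutation null) and at 5–20 seeds for auxiliary distributional checks,
keeping the suite within a few minutes on one CPU; the asserted bounds are
the design bounds, not tuned to the draw.

## Known limitations

* The blank screen pools all non-blank samples (the study does not say
  whether it tested per group); a per-group variant would be stricter for
  peaks produced by few strains.
* Correction-induced shrinkage: zeroing insignificant cells biases very
  faint signals toward zero; with the default noise and consumption
  levels this is negligible for the fitted coefficients (bias ≤ 0.01 in
  the acceptance checks) but would matter for signals near the null sd.
* The binomial consumption model can meet complete separation when one
  taxon never consumes; the fit is flagged rather than penalized-refitted.
* Growth ANOVA assumes a crossed, reasonably balanced design; empty
  species × medium × mode cells abort by name.
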