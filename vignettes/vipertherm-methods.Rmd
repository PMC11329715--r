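---
title: "Methods: set-point estimation, thermoregulation indices and the warming budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-point estimation, thermoregulation indices and the warming budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipertherm)
```

This vignette documents the models and conventions behind each stage of the
package, the parameters that matter, and the choices made where the
underlying field methodology leaves the procedure open.

## Set-point estimation from gradient trials

An individual's gradient-trial readings are treated as draws from its
preferred-temperature distribution. The estimator fits a Gaussian kernel
density with the Silverman-type rule-of-thumb bandwidth
`0.9 * min(SD, IQR/1.34) * n^(-1/5)` (the `stats::density` default,
`bw.nrd0`), evaluates it on a fixed grid from 15 to 45 °C in 0.05 °C steps
(601 points), and rescales the curve so its maximum is exactly 1.
`extract_tset()` then reads T~p~ at the maximum (ties broken toward the
lowest temperature) and the set-point bounds as the smallest and largest
grid temperatures where the normalized density reaches 0.5.

Two definitions of a "central 50 %" range circulate: the interquartile range
of the readings and the half-maximum crossings of the density. The
half-maximum rule is primary here because it is the operational rule the
grid-and-read procedure implies; the interquartile variant is available via
`method = "iqr"`. For a Gaussian distribution the half-maximum width is the
FWHM, `2 * sqrt(2 * log(2)) * sigma ≈ 2.355 sigma`, which the test suite uses as a
closed-form oracle. On multimodal curves the bounds deliberately bracket
*all* crossings (first and last), so two well-separated preference modes
yield one wide range rather than a silently chosen mode.

Numerical conventions: readings outside the grid are clipped to 15/45 °C
with a warning rather than dropped (they carry real information about
preference extremes); a series with fewer than 5 readings or zero variance
is an error, not a degenerate estimate; bounds landing on a grid edge set a
`clipped` flag. Population-level estimates pool all readings of the
population and rerun the same procedure — pooling keeps the estimate
consistent with the individual procedure at the cost of weighting
individuals by their number of readings; the alternative (min/max of
individual bounds) was considered and not implemented because it grows
without bound in n. Note that pooling duplicated series changes the
bandwidth through the `n^(-1/5)` factor, so pooled estimates match
single-series estimates only up to that factor (exactly equal for a single
individual).

## Thermoregulation indices

`deviation()` is 0 inside the set-point range and the distance to the
nearest bound outside it — the standard accuracy convention, applied
identically to body and operative temperatures, which makes d~b~ and d~e~
translation-invariant when temperatures and bounds shift together.

d~e~ uses only readings in the diurnal activity window, **\[06:00, 20:00)**
— inclusive start, exclusive end, so exactly 14 h of a 5-min logger series
(168 readings per series per day) enter. Confidence intervals for d~b~ and
d~e~ are percentile bootstrap over records (default 10 000 resamples,
seed-deterministic), not clipped at zero; with all-identical deviations the
interval collapses to zero width. Records are pooled across individuals by
default; per-individual averaging before pooling is available
(`per_individual = TRUE`) since the field protocol does not fix this.

E~x~ needs a "corresponding" operative temperature for each spot record,
which the protocol leaves undefined. The package matches the
nearest-in-time reading within ±2.5 min (half the logger cadence) in *each*
of the population's sun/shade series, and counts the habitat as overlapping
the set-point range when at least one matched reading lies inside it —
i.e., the animal *could* have been at a preferred temperature somewhere.
The ratio is returned unclamped: values above 1 mean animals are inside
their preferred range more often than the unregulated environment would be.
A population whose matched operative temperatures never overlap the range
has E~x~ undefined; the report carries `NA`. Likewise populations with
loggers but no captured animals get `NA` (never 0) for d~b~, E, I and E~x~.

## The annual restriction-time budget

The full biophysical route to operative temperature (coupled
microclimate + ectotherm energy balance) is intentionally out of scope.
`synthesize_hourly_te()` is a documented simplified synthesizer: daily mean
air temperature is the linear interpolation of the cell's 12 monthly means
across day-of-year at month midpoints (365-day year, December wrapping to
January); each day carries a sinusoidal cycle peaking at 14:00 with
half-range `diurnal_amplitude`; and the exposed model gains
`radiative_gain` °C during 06:00–20:00, representing solar load on a
passive (non-thermoregulating, "dead") 33.5 g cylindrical model. Defaults
`diurnal_amplitude = 8` and `radiative_gain = 12` °C reflect typical
alpine-meadow diurnal ranges and the midday excess of a sun-exposed copper
model over air temperature. The synthesizer is deterministic, additive in
uniform offsets (a +2 °C scenario shifts all 8760 h by exactly +2), and its
annual mean decomposes as `mean(daily means) + gain * 14/24`, which the
tests verify by brute-force averaging.

h~r~ counts hours with T~e~ **strictly** greater than the upper set-point
bound (ties are not restriction). Consequences tested as invariants:
conservation (`h_r + hours below-or-equal = 8760`), monotonicity in any
non-negative warming offset and in the threshold. Because the synthesizer
is simplified, *absolute* h~r~ values are not comparable to a full
biophysical model's output; scenario *contrasts* and the latitude gradient
are the meaningful quantities. Future pathways are averaged over their
GCMs with equal weights per cell before differencing against the current
scenario. Which upper bound applies to a cell is open in the protocol; the
pipeline assigns each cell the population-level bound of the
nearest-latitude population, with a single global bound available by
passing a scalar.

## Phylogenetic signal

Trees arrive as newick without branch lengths; `grafen_lengths()` assigns
Grafen heights (node height proportional to descendant-tip count) scaled to
unit depth, giving an ultrametric tree. The Brownian covariance C has
`C[i, j]` equal to the root-to-MRCA shared path length.

Blomberg's K is the observed `MSE0/MSE` (variance about the phylogenetic
GLS mean over the phylogenetically corrected MSE) divided by its Brownian
expectation `(tr(C) - n / sum(C^-1)) / (n - 1)`; K is exactly 1 on a star
tree for any trait, ≈1 under Brownian motion (the test suite's 1000-rep
simulation battery centres near 0.98 on a 5-tip tree), and is invariant to
affine trait transforms and uniform branch rescaling. Its p-value is a
tip-shuffling permutation test, `(1 + #{K_perm >= K_obs}) / (n_perm + 1)`.

Pagel's λ multiplies the off-diagonal covariances; the profile
log-likelihood (GLS mean and rate maximized analytically) is optimized over
`[0, lambda_max]` where `lambda_max` is computed from positive-definiteness by
bisection rather than fixed at 1 — population-level trees can support
λ above 1 and the estimator should be allowed to say so. The optimizer is
checked against a 0.001-step grid search, and the λ = 1 likelihood equals
the untransformed Brownian likelihood exactly. Significance is a
likelihood-ratio test of λ̂ against λ = 0 with a χ²₁ upper tail (testing
against 0, the common default; against 1 would ask a different question).
Two caveats, both quantified by the package's own simulations: at 5 tips
both tests have very low power, and the LR test is conservative — under a
correctly specified λ = 0 null at 32 tips the empirical type-I rate is
below 1 % at nominal 5 %, because λ̂ sits on the zero boundary in ~85 % of
null draws, far above the asymptotic one-half of the usual boundary-mixture
argument. The independent reference implementation (`phytools::phylosig`)
agrees with both statistics to numerical precision, and with this null
behaviour.

## Comparative statistics

OLS fits delegate to `stats::lm`; the Wilcoxon rank-sum delegates to
`stats::wilcox.test` with an explicit branch rule — exact enumeration when
`m * n <= 400` and the pooled sample is tie-free, otherwise the normal
approximation with continuity and tie correction — chosen so that every
small-sample comparison in a typical study is exact while the rule stays
cheap and predictable. Pairwise population contrasts use pooled-variance t
statistics from the one-factor model with Holm adjustment by default
(conservative, dependency-free); the single-step multivariate-t adjustment
is available through `multcomp::glht` when installed. Factor coding in the
sex and gravidity linear models uses the alphabetically first level
(female; non-gravid) as reference.

## What the synthetic generator does and does not emulate

`generate_roster()` and friends encode the statistical structure the
analysis assumes: per-individual latent preferred temperatures with
between- and within-individual Gaussian variation (truncated to 15–45 °C);
a female-only SVL slope of 0.02 °C/mm; cross-population defaults whose
means encode an overall T~p~ of 28.77 °C and a latitude slope of
1.557 °C/degree exactly; 13 hourly gradient readings (06:00–18:00);
diurnal sun/shade operative sinusoids (sun amplitude 13 vs shade 7 °C) with
AR(1) noise at 5-min cadence; a 5 % fraction of early-morning spot records
below the individual's latent lower bound (animals at the start of morning
basking); a 102-cell monthly climate grid with a seasonal cycle, a negative
latitude trend and scenario offsets (optimistic ≈ +2 °C, pessimistic
≈ +5 °C, three GCM variants each); and a two-lineage population tree with
the southern population sister to the rest. Default per-population counts
(19, 5, 31, 3, 15) follow the emulated study design.

It does **not** emulate geography (latitude is a scalar covariate, no
rasters), capture effort, seasonal phenology, behavioural microhabitat
choice, or measurement-device error structure. Passing tests therefore
demonstrate that the estimators recover known structure from data obeying
the stated assumptions — not that real viper data satisfy those
assumptions.

Within-individual SD defaults to 2 °C and between-individual SD to 1.5 °C,
round values in the range typical of squamate gradient trials; they are
config, not conclusions. All generator stages draw from named,
seed-derived RNG streams (`stage_seed()`), so a pipeline rerun under one
root seed is byte-identical while stages stay independently reproducible.

## Problem sizes

The default test suite runs the full pipeline at reduced scale (8–10 cells,
2 field days, a few hundred bootstrap resamples) and the simulation
batteries at 200–1000 replicates; the acceptance script runs the study-scale
configuration (73 individuals, 14 days, 102 cells, 10 000 resamples, 999
permutations). These sizes keep every quantity's Monte-Carlo error well
inside the tolerances asserted for it.
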