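---
title: "Clustering community time series by their wavelet spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering community time series by their wavelet spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveclust)
```

## Why spectra instead of correlations

Correlation-based community inference summarizes a pair of abundance series
by a single number computed over all time points. That number is blind to
two things that matter ecologically: phase (two taxa oscillating in
antiphase are dynamically coupled but anticorrelated) and nonstationarity
(two taxa can share a time-averaged spectrum while their rhythms occupy
disjoint epochs). `waveclust` clusters series on their Morlet wavelet power
spectra — time-by-period maps of oscillatory energy — so both failure modes
are handled: antiphase pairs have *identical* spectra, and series whose
periodicities drift are distinguished by *when* their power occurs, not
just by which periods carry it.

The cost is stronger data requirements. The method assumes equidistant
sampling (interpolation supplies it), stationary sampling noise after
variance-stabilizing preprocessing, and series long enough to resolve the
periods of interest: at least ~25 points in total, and trustworthy periods
no longer than roughly a third of the record. These assumptions are
enforced as errors or hard caps rather than silently ignored.

## Preprocessing compositional counts

`preprocess_counts()` runs a fixed order: depth filter → relative
abundance → core-taxon selection → CLR → interpolation → Box–Cox. The order
is not arbitrary: selection must see relative abundances, the log-ratio
transform must precede interpolation (interpolating raw compositions can
leave the simplex), and variance stabilization must come last so the
wavelet transform sees near-Gaussian, unit-variance input.

Parameters (`preprocess_config()`):

| parameter | default | units | role |
|---|---|---|---|
| `min_reads` | 500 | reads | drop under-sequenced samples (strict `<`) |
| `detection` | 0.005 | fraction | core-selection abundance threshold (strict `>`) |
| `prevalence` | 0.25 | fraction of samples | core-selection prevalence |
| `n_boot` | 100 | resamples | bootstrap stabilization of core selection |
| `target_dt` | 1.6 | days | equidistant grid spacing |
| `boxcox_lambda_grid` | −2…2 by 0.01 | — | exponent search grid |

Decisions made where the method leaves room:

* **CLR zeros.** Zeros are replaced per sample by half the smallest nonzero
  fraction of that sample (then the sample is renormalized). This keeps the
  imputation on each sample's own abundance scale; a global pseudocount is
  available as an alternative policy.
* **Bootstrap aggregation.** With `n_boot > 0`, samples are resampled with
  replacement and a taxon is kept when it passes the detection/prevalence
  criterion in more than half of the resamples — a majority vote, which is
  the simplest aggregation that damps the influence of a few extreme
  samples.
* **Interpolation.** Monotone cubic Hermite (Fritsch–Carlson slopes). The
  monotone slope rule cannot overshoot, which matters for spiky
  low-abundance taxa where an ordinary cubic spline would ring. The grid is
  anchored at the first retained sample and never extrapolates; a span *T*
  yields `floor(T/dt) + 1` points.
* **Box–Cox domain.** The exponent is chosen to maximize the probability
  plot correlation coefficient (plotting positions `(i − 3/8)/(n + 1/4)`),
  on the grid plus a continuous local refinement. CLR output can be
  negative, so a series whose minimum is not strictly positive is lifted to
  a floor of 1 before transforming. Already-positive series are *not*
  shifted: an additive shift changes the family (a shifted lognormal is not
  lognormal), and the untouched transform correctly recovers λ ≈ 0 for
  lognormal and λ ≈ 1 for Gaussian input. Transformed series are
  standardized to zero mean, unit variance.

## The wavelet transform

`morlet_cwt()` standardizes the series, zero-pads to the next power of two,
and convolves in the frequency domain with the Morlet wavelet at scales
`s_j = s0 * 2^(j * dj)`.

* `omega0 = 6`: the classical compromise making the Morlet wavelet
  approximately admissible while keeping good period resolution; with it
  the scale-to-period factor is 4π/(ω₀ + √(2 + ω₀²)) ≈ 1.033.
* `dj = 1/12` (twelve sub-octaves): adjacent grid periods differ by ~6%,
  fine enough that a sinusoid's dominant period is recovered within one
  grid step (verified for 4, 8, 13 and 20-day test signals).
* `s0 = 2·dt`: the Nyquist-limited smallest scale.
* The largest period is capped at a third of the span; longer periods
  cannot complete enough cycles to be trusted.
* Power is the squared modulus of the transform of the standardized series,
  without per-scale rectification. Any scale bias this leaves cancels in
  the significance test, because surrogates are transformed identically.
* The cone of influence marks, for each time, the largest period whose
  e-folding distance (√2·scale) fits inside the record; averaged spectra
  and dominant-period extraction exclude cells outside it. Dominant-period
  ties resolve to the shorter period.

## Markov surrogates and significance

The null hypothesis is that the observed periodicities could be produced by
a stochastic process with the same mean, variance, value distribution and
short-term autocorrelation as the data. `markov_surrogates()` builds that
null constructively: values are discretized into equal-frequency bins
(`min(15, n/10)` by default — enough states to capture lag-1 structure
without starving the transition matrix), a first-order transition matrix is
estimated, and surrogate chains are simulated.

Two published conventions conflict here: drawing bin values *with*
replacement preserves the transition structure but only approximates the
value distribution, while exact permutation preserves the distribution but
needs a constrained chain. We resolve it in favour of exactness: the chain
is simulated *conditioned on the remaining pool sizes* (the transition row
is reweighted by how many unused values each bin still holds, and values
are drawn without replacement), so every surrogate is exactly a permutation
of the source — the distribution-preservation contract holds to the last
value — while lag-1 autocorrelation is preserved to within 0.1 even for
strongly autocorrelated input (AR(1), φ = 0.9). When ties collapse
equal-frequency bins the bin count is reduced with a warning.

`significance_mask()` transforms each surrogate with identical parameters
and flags cells where observed power exceeds the pointwise quantile of the
surrogate ensemble. The test is pointwise by construction, so on pure noise
a fraction ≈ 1 − confidence of in-cone cells is flagged (calibration on
AR(1) noise stays within [0.02, 0.10] at the 95% level). Two levels are
used: 90% for the power entering the clustering distance, 95% for display.
Defaults are 1000 surrogates for final analyses; the examples and tests use
100–200, which is enough for the 90–95% quantiles.

## The spectrum distance

`mca_distance()` compares two masked spectra by maximum covariance
analysis: SVD of the cross-covariance matrix between the two fields,
retaining the leading axes that hold ≥ 95% of the squared covariance. Per
axis the discrepancy is `(1 − |cos θ|)` between the paired singular vectors
plus half the L2 gap between unit-normalized leading patterns, weighted by
the axis' squared-covariance fraction. Identical spectra give exactly 0;
the pairwise matrix is symmetrized by averaging both orientations.

The genuinely open design choice is which axis plays the role of MCA
variables. We evaluated both on the demonstration panel:

* With **scales as variables**, singular vectors live in scale space.
  A series that switches from 13- to 4-day rhythm then sits closer to a
  *stationary* 13-day series (exact scale-band overlap) than to a 20 → 4-day
  series that shares its whole temporal trajectory — the opposite of what
  spectrum clustering is meant to express.
* With **time points as variables**, computed on each spectrum's temporal
  anomaly field (power minus its per-scale time mean), singular vectors are
  time profiles and leading patterns are scale profiles. Stationary bands
  drop out of the anomalies, so the comparison keys on when power migrates;
  the 13 → 4 and 20 → 4 signals pair up, and two signals sharing only a
  time-averaged spectrum stay far apart.

The package defaults to the time orientation; the scale variant remains
available (`orientation = "scale"`) behind the same interface. A pair in
which either spectrum has no significant power at all has no defined MCA
distance; such pairs are assigned the largest distance observed in the
panel, with a message.

Ward clustering uses the `ward.D2` convention (Lance–Williams on squared
dissimilarities) via `stats::hclust`; heights are monotone and ties resolve
by `hclust`'s deterministic merge order.

## Comparing trees

`bk_curve()` cuts both trees at every `k = 2 … n−1` and computes
`B_k = T_k/√(P_k Q_k)` from the k×k contingency table of shared members.
The rejection line is `null_mean + z(1−α)·null_sd` under the null of
unrelated trees, with moments either from the asymptotic distribution under
random relabeling with fixed marginal cluster sizes, or from an empirical
permutation null (default 999 relabelings). The two agree within 0.05 at
n = 19, and under random trees the empirical exceedance of the asymptotic
line sits near the nominal α. `B_k` is undefined (returned as `NA`) when a
partition is all singletons. Total branch length — the sum of all vertical
segments of the merge tree, leaves at height 0 — is computed with
`vegan::treeheight` and cross-checked in the tests against an explicit
edge-enumeration oracle.

## What the synthetic data emulate — and what they do not

`make_demo_panel()` reconstructs an eight-signal test panel from its
qualitative description: an antiphase 8-day pair, stationary 20- and 13-day
signals, a noisy 8-day signal, and three period-switching signals with
phase-continuous switches (an abrupt phase reset would inject spurious
broadband power at the switch). Three signals are not pinned down by the
description; we fill them with stationary 20-day, stationary 13-day, and a
noisy 8-day sinusoid (sd 0.3) in *quadrature* phase, so the panel exercises
both stationary and nonstationary regimes and the noisy signal shares a
spectrum — but no rank correlation — with the antiphase pair. The panel is
fully deterministic.

`make_synthetic_community()` emulates a dense 16S genus table: irregular
timestamps (multiplicative jitter around a 1.6-day mean interval), latent
log-abundances that are group sinusoids (default two groups of five taxa at
30- and 64-day periods, amplitude 1.5, taxon noise sd 0.3, phases spread
evenly within a group) plus heavy-tailed spiky fillers near the detection
threshold, and per-sample multinomial count sampling at 10,000 reads over
450 days — sizes matching a long dense human-gut sampling campaign. What it
does **not** emulate: sequencing-depth variation between samples,
overdispersion beyond multinomial, taxonomic misassignment, true ecological
interactions (groups are imposed, not emergent), or trends and transients
other than fixed-period oscillation. Passing the recovery tests therefore
shows the pipeline recovers *planted periodic group structure through
compositional counting noise* — not that real communities are this clean.

## Numerical choices and degenerate inputs

* Constant series fail loudly everywhere (CWT, correlation, Box–Cox).
* Sub-Nyquist periods (≤ 2·dt) are rejected at generation time.
* Spectra must share period axis, time axis and transform parameters to be
  compared; mismatches are errors, not silent recycling.
* All stochastic steps (noise injection, bootstrap, surrogates,
  permutation nulls) take explicit seeds and leave the caller's RNG state
  untouched; per-series surrogate seeds are derived as `seed + i`.
* Problem sizes in the test suite are chosen to exercise the method at
  realistic scale while staying quick: 100-point demonstration signals with
  100–200 surrogates, a 19 × ~280 community table for recovery, 50
  replicates for significance calibration, and exhaustive Bk enumeration at
  n ≤ 5 with randomized checks at n = 6–7.

## Limitations

* The surrogate test is pointwise; contiguous significance areas are not
  corrected for multiplicity (no area-wise test).
* The MCA distance is one defensible functional among several; absolute
  distances are not comparable across panels, only orderings within one.
* Cross-wavelet coherence, non-equidistant wavelet variants, consensus
  trees over more than two subjects, and causal inference are out of scope.
* Interpolation before spectral analysis can smooth over genuinely missing
  dynamics; inspect interpolated series against the raw data when sampling
  gaps are long.

```{r demo, eval = FALSE}
res <- run_demo_analysis(n_surrogates = 200, seed = 1)
autoplot(res$spectra$s7, mask = res$masks$s7)
autoplot(res$bk)
```
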