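---
title: "Methods: models, parameters and numerical choices in meapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in meapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meapop)
```

meapop analyses spontaneous population spiking recorded from neural
cultures on multi-electrode arrays. This vignette is the package's account
of the science: what each stage assumes, which parameters matter and why
their defaults are what they are, what the synthetic-data generators do and
do not emulate, and the numerical decisions that a careful reader would
want spelled out.

## The measurement model

An MEA well is a square grid of extracellular electrodes (by default 8 × 8
at 300 µm pitch, a 2.1 × 2.1 mm field, sampled at 12.5 kHz). Each electrode
records a voltage mixture: action potentials of nearby neurons, attenuated
copies of more distant neurons, and broadband noise. The pipeline's job is
to demix that signal into single units and then characterise the *joint*
statistics of the unit population.

Two assumptions run through everything downstream of sorting:

- **Stationarity.** All population statistics (correlations, entropies,
  maximum-entropy fits) are time-averaged; they only mean something if the
  underlying rates are stable across the recording. Hence the explicit
  stationarity gate: recordings that fail it are excluded rather than
  analysed.
- **Binary sufficiency at 10 ms.** Activity is binarized into 10 ms bins,
  with any number of spikes in a bin registered as a single 1. The raster
  carries a `multi_spike_fraction` attribute so the user can confirm that
  multi-spike bins are rare (in sparse cultures typically < 5% of occupied
  bins); where they are not, the binary description genuinely discards
  information and the bin size should be reconsidered.

## Spike sorting

The chain is: band-pass filter → threshold detection → noise rejection →
PCA → Gaussian-mixture clustering → merging → quality control.

**Filtering** (`filter_trace`). A 3rd-order Butterworth band-pass at
500–3,500 Hz isolates the spike band, followed by a 60 Hz notch for mains
contamination. Both are applied forward–backward (`signal::filtfilt`), so
the filter has zero phase: waveform shape, on which all later clustering
rests, is not skewed by group delay. The trace is reflected for 4 s at both
ends before filtering and trimmed after, suppressing edge transients while
returning exactly the input length. The filter order is a mild choice —
zero-phase application squares the magnitude response, so an effective
6th-order rolloff — and the passband gain is within 5% of unity.

**Detection** (`detect_events`). Samples deviating from the trace mean by
more than `k_sd = 5` standard deviations are flagged; each contiguous
excursion yields one event aligned to its extremum, and excursions closer
than 1 ms are merged (dead time). The SD is the literal standard deviation
about the mean; a median-absolute-deviation estimate is available
(`robust_sd = TRUE`) for traces where frequent large spikes inflate the
naive SD. With one event per excursion, raising the threshold can only
remove events — detection counts are monotone in `k_sd`, which the tests
verify over 4.5–5.5.

**Symmetric-noise rejection** (`reject_symmetric_noise`). High-frequency
periodic noise that crosses the amplitude threshold differs from an action
potential in two ways: it is time-symmetric, and its positive and negative
excursions are nearly equal. An event is discarded only when *both* hold —
the correlation between the waveform and its time-reverse (reflected about
the alignment extremum, so the test is phase-independent) exceeds 0.9, and
the absolute difference between peak and trough magnitudes is below 8 µV.
The amplitude difference is interpreted on the µV scale of the waveform;
both thresholds are configuration fields.

**Clustering** (`project_and_cluster`). Multi-channel snippets (1 ms
before, ~2 ms after the trough: 13 + 25 samples at 12.5 kHz, concatenated
across channels) are projected onto their first two principal components
and clustered with a Gaussian mixture fitted by EM (`mclust`), selecting
the number of components by BIC over 1–8. mclust initialises EM from
deterministic model-based hierarchical clustering, so results are
reproducible without restart machinery. Two components are the default
projection because well-isolated units separate in two dimensions; both
the dimensionality and the component range are configurable.

**Merging and deduplication.** Clusters whose mean waveforms correlate
above 0.8 are merged to prevent overclustering. Merging takes the
transitive closure of above-threshold pairs (connected components), which
makes it order-independent and idempotent — re-merging merged output is a
no-op. The same neuron picked up on neighbouring channels is removed by
cross-channel deduplication: a smaller unit is absorbed when more than
half of its spikes coincide within ±0.5 ms with a larger unit's and their
concatenated waveforms correlate above the merge threshold.

**Quality control.** Units pass if (a) fewer than 5% of their interspike
intervals fall below the 2.5 ms absolute refractory period, (b) their mean
waveform has a single dominant extremum (multiple large extrema indicate
compound spikes from overlapping cells), and (c) they retain at least
`min_spikes = 10` events (smaller "units" are threshold flotsam). The ISI
criterion is sometimes quoted with a 5 ms window in the literature; both
the window and the violation fraction are configuration fields, with
2.5 ms / 5% as defaults.

## Localization and positional entropy

A unit's position is the weighted mean of channel coordinates with weights
`w_c = ∫|waveform_c|` — the integral of the absolute mean waveform on each
channel. Weighting by the integral rather than the peak makes the estimate
robust to single-sample noise. Positional entropy then asks how
homogeneously units cover the field: tile the extent with square regions
of side `s`, take the fraction of units per region as a distribution, and
compute `H = −Σ p log₂ p`, normalised by the most-random ceiling
`H_max = log₂(min(n_units, n_regions))` — with fewer units than regions no
arrangement can do better than one unit per region, so this is the correct
ceiling on both sides. Regions are half-open and anchored at the array's
lower-left corner; boundary units belong to the lower-index region. The
sweep default covers 100 µm–1 mm in ten logarithmic steps. The
distribution is over *units*, not spikes: the quantity characterises where
cells sit, not how much they fire.

## Stationarity

Two complementary checks per unit, then a population-level decision:

1. **Half-split rates.** Under a homogeneous Poisson train each half-rate
   has variance `r̄/(T/2)`, so the difference has standard error
   `√(2 r̄/(T/2))`; a unit passes when `|r₁ − r₂|` is within 3 of these
   SEs. (The √2 matters: omitting it makes the band ≈ 2.1 SE and falsely
   flags ~3.4% of genuinely stationary units.)
2. **Moving-rate KL divergence.** A sliding-window rate (100 ms window,
   5 ms step) is computed for each half; the two rate distributions are
   histogrammed on 30 shared equal-width bins with a pseudocount of
   `1/(n·bins)` on empty bins, and compared by `KL(first ‖ second)` in
   bits. The direction is a convention (a symmetrised option exists); the
   pseudocount keeps the divergence finite without visibly distorting
   occupied bins.

The same-unit divergences are then contrasted with divergences between
halves of *different*, randomly paired units using a one-sided Welch test.
In a stationary recording with heterogeneous rates, same-unit divergences
are far smaller. The recording passes when this contrast is significant
and at most 5% of units fail the half-split band — an allowance matching
the 3-SE check's own false-positive rate, so that large stationary
recordings are not rejected by a single unlucky unit. Note the contrast
has no power when all units share the same rate distribution (the
cross-pairs then look like same-unit pairs); the report warns in the fully
degenerate case.

## Pairwise correlation

Binarized trains are convolved with a Gaussian kernel of σ = 25 ms
(truncated at ±4σ, normalised to unit mass so spike counts are conserved)
and Pearson's r is computed for all pairs. Smoothing turns near-coincident
spikes into overlapping bumps, making r sensitive to synchrony at the
tens-of-milliseconds scale rather than demanding exact bin coincidence.
"25 ms Gaussian" is read as σ = 25 ms (not FWHM); σ is configurable. Units
with no spikes have undefined correlation and yield `NA` with a warning —
never a silent zero.

## Count and word entropy

For K units in a bin there are K + 1 possible *counts* (how many fired)
and 2^K possible *words* (which fired). Count entropy measures synchrony
structure; word entropy additionally resolves identity, and since the
count is a function of the word, `H_word ≥ H_count` on every raster — a
relation the tests enforce exhaustively. Entropies use the plug-in
(maximum-likelihood) estimator in bits; its negative bias shrinks as
(support size)/(2n) and a Miller–Madow correction is available behind the
`correction` argument. Because recordings yield different unit counts,
entropies are compared at matched population sizes by subsampling
(default 100 random subsets per K over K = 2–18), with bootstrap
resampling of time bins (default 100) reported as a stability SD — the
bootstrap spread is reported, not turned into an automatic pass/fail.
Words are encoded as integers with unit i on bit i − 1 in catalog order;
the convention is stable and documented so serialized distributions are
portable.

## The pairwise maximum-entropy model

The second-order (pairwise Ising) model is the distribution over binary
words with maximal entropy subject to matching each unit's firing
probability and each pair's co-activation probability:

`P(s) = Z⁻¹ exp(Σᵢ hᵢ sᵢ + Σ_{i<j} J_ij sᵢ sⱼ)`, `s ∈ {0,1}^K`.

`hᵢ` is the excitability of unit i (at independence, exactly the logit of
its firing probability) and `J_ij` the pairwise interaction. Fitting
maximises the concave exponential-family log-likelihood whose gradient is
the empirical-minus-model moment gap; the package uses damped Newton
ascent with the exact Fisher information (the covariance of the
sufficient statistics under the model), all moments evaluated by full 2^K
enumeration. K ≤ 14 keeps enumeration at ≤ 16,384 states; typical fits
converge in well under ten iterations to a maximum moment residual below
10⁻⁶ (the `tol` default). Initialisation is the independent model
(`h = logit(means)`, `J = 0`); by concavity this affects speed only.
Empirical moments are clipped to `[1/(2n), 1 − 1/(2n)]` before fitting so
that units silent (or saturated) in the training half produce finite
parameters, at a documented O(1/n) bias; a warning reports the clip.

Evaluation divides the raster into contiguous halves (consistent with how
stationarity is screened; an interleaved split is available), fits on the
first and computes `KL(empirical_test ‖ model)` in bits. The direction is
chosen because the model is strictly positive on all 2^K words, making
the divergence always finite; the empirical distribution has zeros, so
the reverse direction would not be. A small held-out divergence means
rates and pairwise couplings suffice to explain the population; the
excess above the finite-sample floor measures higher-order structure.
The finite-sample floor itself is visible in the synthetic cohorts: data
genuinely generated by a pairwise model at K = 5 and 2,000 training bins
still shows ~0.01–0.02 bits of held-out divergence, which is why cohort
comparisons are made at matched K and duration.

## Rank statistics

Group comparisons use the Brunner–Munzel test of stochastic equality,
which unlike Wilcoxon does not assume equal variances under the null. The
implementation uses midranks, the Brunner–Munzel variance estimator and a
t approximation with Satterthwaite-type degrees of freedom; it is
cross-checked in the tests against an independent placement-formula
implementation to 10⁻⁶ and holds its nominal size (empirical type-I error
within [0.04, 0.06] at α = 0.05 under unequal variances). Two degenerate
regimes are handled explicitly: all values tied (no evidence, p = 1) and
complete separation of the samples, where the variance estimator vanishes
although the evidence is maximal — the statistic is reported as ±∞ with
p = 0 and a warning. Bonferroni correction is explicit:
`bonferroni_alpha(n_comparisons)` requires the family size as an argument
and never infers it from the data (with 15 comparisons at α = 0.05 this
gives the 0.0033 threshold used in cohort tables). The
Kolmogorov–Smirnov/Levene screen (`distribution_checks`) documents *why*
a rank test is indicated; the Wilcoxon wrapper is provided for paired
entropy comparisons where its extra power under equal variances is wanted.

## What the synthetic generators emulate — and what they do not

`sample_ising` draws i.i.d. words from an exact small Ising model, so the
fitter can be validated against planted parameters with known asymptotic
standard errors. `generate_correlated_trains` uses the dichotomized
Gaussian: per-unit thresholds `Φ⁻¹(1 − rate·bin)` guarantee the target
rates exactly in expectation, and the observed binary correlation is an
analytic, monotone function of the latent one (a bivariate-normal orthant
probability), giving the correlation stage a closed-form oracle. Spike
times are jittered uniformly within their bin so that re-binarizing at
10 ms reproduces the generated raster exactly. `synthesize_voltage`
plants single-trough biphasic templates at unit positions, scales them by
`1/(1 + d/λ)` with λ = 150 µm across the grid — a generic monotone decay;
no biophysical propagation model is claimed — and adds white Gaussian
noise.

Defaults emulate sparse spontaneous culture activity: firing rates in the
0.1–5 Hz range, latent correlations 0–0.6, and spike-to-noise amplitude
ratios around 10. These are plausible ranges for spontaneous culture
recordings chosen once for this package, not measured constants.

The generators deliberately do *not* emulate: bursting and slow
population events (the analyses here target millisecond-scale structure),
electrode drift or amplitude nonstationarity, spike-waveform overlap
collisions, correlated (non-white) recording noise, or glial
contamination. Consequently, passing tests demonstrate correctness of the
computations and recoverability under the stated model — not robustness
to every pathology of real MEA data. On real recordings the stationarity
gate and QC flags are the guard rails, and sorted outputs should be
inspected.

## Numerical conventions and degenerate inputs

- Time is in seconds (float64); bins and regions are half-open `[t, t+Δ)`
  aligned to the recording start, so boundary events belong to the lower
  bin deterministically.
- Word integers put unit i on bit i − 1 in catalog order.
- All stochastic steps take explicit seeds; `run_pipeline` derives every
  stage's randomness from `config$seed`, and re-running with identical
  inputs and config reproduces results bit-for-bit.
- Empty trains, all-zero traces, single-spike units, all-tied samples and
  saturated/silent units all take defined paths (empty results, vacuous
  passes, clipped moments) with warnings rather than NaNs.
- The test suite and the reproduction script use deliberately modest
  problem sizes — e.g. 10⁵–10⁶ samples for closed-form checks, 50
  recordings per cohort arm at K = 5 and 4,000 bins, one 60 s planted
  voltage recording at 9 channels — sizes at which every targeted effect
  is resolvable with comfortable margins while the whole suite runs in
  well under a minute.

## Known limitations

- Exact enumeration bounds the maximum-entropy model at K ≤ 14 (and the
  samplers at K ≤ 16); larger populations require approximate fitters
  (pseudolikelihood, MCMC) that are out of scope here.
- The plug-in entropy estimator is biased low at small samples; the
  Miller–Madow option mitigates but does not remove this. Comparisons
  should be made at matched n and K, as the pipeline does.
- The stationarity contrast requires heterogeneous firing rates across
  units to have power.
- Sorting quality degrades gracefully but inevitably as templates overlap
  in waveform shape *and* position; the merge threshold (0.8) encodes the
  judgement that such clusters are one unit.
- Voltage I/O uses a flat binary matrix with a JSON sidecar; it is a
  simple, validated interchange format rather than a self-describing
  container.
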