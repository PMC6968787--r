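---
title: "Methods: acute post-impact EEG features, group statistics and integer risk scores"
author: "acuteqeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acute post-impact EEG features, group statistics and integer risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific and numerical choices behind
`acuteqeeg`. The package analyses two-channel epidural EEG recorded around a
controlled cortical impact (CCI) in rats, and ships a synthetic signal
generator emulating three strains (kindling-susceptible PPKS, outbred SD,
kindling-resistant PPKR) so that every stage of the analysis is testable
without animal recordings.

## The analysis pipeline

A recording consists of a left and a right (injured, ipsilateral) epidural
channel sampled at 1,024 Hz with one event mark at the impact. Five 60-second
epochs are cut relative to the impact sample: a baseline epoch ending 0.5 min
before the impact, and post-injury epochs beginning 0.5, 5, 10 and 15 min
after it. Intervals are half-open in 0-based sample indices, with start index
`cci_sample + round(offset * fs)`; the 0.5 s impactor artifact lies wholly in
the excluded 30 s on either side of the event, and filtering is applied per
epoch **after** extraction, so artifact energy cannot ring into any analysed
sample. (Whether filtering preceded or followed epoch selection is not
something the analysed experiment pins down; per-epoch filtering is the
package's choice precisely because it gives this isolation guarantee.)

**Bandpass filter.** Each epoch channel is bandpass filtered to 0.5–32 Hz
with a linear-phase equiripple FIR filter applied forward–backward, so the
net filter has exactly zero phase. The design fixes what the equiripple
family leaves open: stopbands at ≤ 0.1 Hz and ≥ 40 Hz, net passband ripple
≤ 1 dB, and net stopband attenuation ≥ 40 dB (each single pass therefore
targets half those values in dB). A passband edge of 0.5 Hz at 1,024 Hz
sampling makes the transition width four ten-thousandths of the sampling
rate, which forces a filter of several thousand taps (3,201 at 1,024 Hz,
scaled proportionally at other rates). The design is computed by iteratively
reweighted least squares with Lawson weight updates — a standard route to
minimax (equal-ripple) FIR designs that remains numerically stable at these
orders, where classical Remez-exchange implementations fail to converge. Two
implementation details matter:

* the cosine-basis normal equations are assembled from trigonometric moments
  through their Toeplitz-plus-Hankel structure, so each iteration costs
  O(M²) rather than O(M² · grid);
* the transition bands carry low-weight raised-cosine ramp targets. An
  unconstrained transition band in an over-determined minimax design can
  grow large peaks (we observed 280× gain at 34 Hz in an unconstrained
  801-tap design at 256 Hz); the weak ramp constraint caps this at ~1.16
  while leaving the pass/stop solution essentially untouched.

After design, taps are normalized so the passband peak gain is exactly 1.
Designs are cached per sampling rate. Filtering is FFT convolution with the
symmetric combined (forward–backward) impulse response, so output length
equals input length and the group delay is identically zero.

**Spectra.** Power spectral densities are Welch averages of a short-time
Fourier transform with a 512-point Hamming window and 128-point overlap
(hop 384), with the per-window mean removed. The window gives a native bin
spacing of 2 Hz at 1,024 Hz; since the analysis is defined on a 0.5 Hz grid,
each window is zero-padded to 2,048 FFT points, which interpolates the
spectrum to exactly 0.5 Hz spacing without changing the window statistics.
Bins outside 0.5–32 Hz are discarded, leaving 64 bins. One-sided density
scaling (`2 / (fs · Σw²)`) makes the full-band integral match the
time-domain variance (verified to 5% against a Parseval oracle in the test
suite). Post-injury spectra are normalized per subject by the baseline total
power, taken as the mean of the two channels' baseline totals.

**Features.** Nineteen scalars summarize each epoch: total (non-normalized)
power; percent band power per hemisphere in delta (0.5–4 Hz), theta
(4.5–8 Hz), alpha (8.5–13 Hz) and beta (13.5–32 Hz) — the four bands
partition the 64 bins, so each side's percentages sum to 100; mean
interhemispheric magnitude-squared coherence per band; and spectral entropy,
kurtosis and line length per hemisphere.

* *Coherence* is `|Pxy|² / (Pxx · Pyy)` with cross- and auto-spectra averaged
  across Welch windows **before** the ratio (without averaging the ratio is
  identically 1), using the same window/overlap/padding as the PSD. The band
  summary is the unweighted mean over band bins.
* *Spectral entropy* is the Shannon entropy, in nats, of the 64-bin spectrum
  renormalized to a probability distribution; it ranges from 0 (single bin)
  to ln 64 ≈ 4.159 (flat). Natural logarithms are used and recorded.
* *Kurtosis* is the population fourth standardized moment
  E(x−μ)⁴/σ⁴ with the biased variance — no small-sample correction and no
  −3, so Gaussian signals score 3 and the ±1 alternating sequence exactly 1.
* *Line length* treats the trace as a planar curve sampled at unit index
  steps: Σ√(1 + Δy²), with Δy in microvolts. This mixes index and amplitude
  units, so the conventional amplitude-only variant Σ|Δy| is always computed
  and stored alongside for sensitivity analysis; the path form is the
  canonical feature.
* *Total power* is the 0.5 Hz-binned density integral (Σ power · 0.5 Hz); by
  Parseval this agrees with the time-domain variance of the bandpassed
  signal within windowing error, and the integral form is used. Normalized
  spectra are refused by `total_power()` so a baseline constant can never be
  applied twice.

## Group statistics

Bin-wise comparisons fit fixed-effects linear models of log10 normalized
power (or coherence) on the design factors. The construct-level summary fits
one joint model across all 64 bins with the bin as a blocking covariate and
reports the F test, p-value and LogWorth (−log10 p) per factor; significant
frequency intervals come from independent per-bin F tests at α = 0.05,
reported as maximal runs of consecutive significant bins in bin-centre Hz.
Both pieces are deliberate resolutions of an under-specified "least squares
fit across bins" procedure: the blocking-covariate model gives one
effect-level number, the per-bin fits give interval brackets, and the two
are reported together. No correction across the 64 bins is applied by
default (mirroring uncorrected per-bin brackets); Benjamini–Hochberg is
available behind `adjust = "BH"`. The subject is the experimental unit;
hemisphere enters as a fixed within-subject factor without random effects —
a simplification consistent with fixed-effects least squares. Type-I error
of the per-bin tests is verified by simulation to sit in [0.03, 0.07] at
α = 0.05.

Scalar features use one-way ANOVA with Tukey HSD post-hoc comparisons at
α = 0.05 (`aov` + `TukeyHSD`, Tukey–Kramer under unequal group sizes). At
two groups the Tukey-adjusted p equals the pooled t-test p (verified to
1e-9), which pins the implementation to the studentized-range family.

## The sparse integer risk score

The learner builds a risk-calibrated supersparse linear integer model
distinguishing plasticity-susceptible (PPKS) from non-susceptible (SD, PPKR)
subjects from the 19 features of the 0.5-min post-injury epoch:

1. **Dichotomization.** Each feature is split at the threshold maximizing
   the LogWorth of the 2×2 feature-by-class table, candidates being
   midpoints of consecutive sorted distinct values. The association p-value
   is the likelihood-ratio chi-square (G²) with a Fisher-exact fallback when
   any expected cell is below 1 — the split statistic itself is a package
   choice, as partitioning criteria of this kind are a family rather than a
   single test. Ties break toward the smaller threshold; the point is
   awarded on the susceptible-enriched side.
2. **Search.** The model is a logistic regression
   P(susceptible) = plogis(intercept + score) whose score sums at most five
   dichotomized features with coefficients in {−1, +1} and an integer
   intercept in −10..10. The search maximizes log-likelihood −
   `l0_penalty` × (number of terms) by **exhaustive enumeration** over
   feature subsets, sign assignments and intercepts — about 10⁷ candidate
   models at 19 features, made cheap by tabulating subjects over the ≤ 2ᵏ
   indicator patterns of a subset and sweeping all intercepts with two small
   matrix products. At this scale enumeration is mathematically exact, so
   the mixed-integer solver used by general RiskSLIM implementations is
   unnecessary; a test asserts bit-identical argmax against an
   independently coded naive enumeration. Tie-breaking is deterministic
   (fewer terms, then lexicographic feature order), making the fit invariant
   to row order and, up to that rule, to column order.
3. **Calibration.** For every achievable integer score the fitted object
   records the empirical susceptible fraction (exact count ratios, auditable
   from the table) and the logistic probability; prediction prefers the
   empirical entry and falls back to the logistic map. Both are emitted
   because published tools of this type print empirical-looking tables
   without stating which is which.

The default penalty (4.5 nats per term) was set by two simulations: an
all-noise null at the typical cohort size (n = 32, 19 features) must return
at most one term in ≥ 95% of replicates — any penalty above ~3 achieves
this — and at larger samples (n = 80) the optimized split threshold inflates
a pure-noise feature's best log-likelihood gain to ~4 nats, so the default
sits above that ceiling while remaining well below the gain of a genuine
class shift. With bounded ±1 coefficients a term's achievable gain saturates,
which is why the penalty, not the coefficient magnitude, controls sparsity.

The package also ships `susceptibility_scorecard()`, a replica of a published
three-rule tool (one point each for delta-band coherence < 3, contralateral
beta power < 3%, contralateral kurtosis < 4; probabilities 6.7% for scores
0–1, 75.0% for 2, 88.9% for 3). The printed coherence threshold of 3 lies
outside the mathematical range [0, 1] of magnitude-squared coherence —
likely a scaled or mistyped quantity in the original — so the rule is always
satisfied by genuine coherence values; the object encodes the threshold as
printed and flags the inconsistency, and the same flagging applies to any
learned threshold outside a canonical feature's range.

## The synthetic generator

No public recordings exist for this experimental preparation, so the
generator is a first-class module whose parameters map one-to-one onto the
measured features. Each regime (baseline, post-injury) synthesizes
band-structured Gaussian noise in the frequency domain: per frequency, the
two channels mix a common and a private complex-Gaussian source as
√s·C + √(1−s)·P with the shared fraction s set per band — which controls
interhemispheric coherence band-by-band (measured magnitude-squared
coherence ≈ s², so ordering and monotonicity are preserved) — shaped by
per-band gains times f^(−α) with a 1/f exponent α, supported on 0.25–45 Hz
with an exponential roll-off above the beta band. Phase is zero-lag: only
coherence magnitude is modelled, since lag is unidentifiable from
magnitude-squared coherence. Segments switch from the baseline to the
post-injury regime at the impact sample, where a 0.5 s saturating square
pulse emulates the impactor artifact; channels are scaled to a target RMS
(50 µV by default — all downstream features except total power and line
length are scale-invariant, so absolute scale is a configuration constant).

Two time-domain mechanisms realize the non-spectral features:

* **Burst suppression (`am_depth`).** A slow (0.8 Hz, random-phase) burst
  envelope attenuates the supra-delta content by up to `am_depth` while the
  delta content swells in anti-phase so that the instantaneous total
  variance stays constant. This concentrates time-averaged power into delta
  (lowering spectral entropy) while the signal remains a constant-variance
  Gaussian process — so the mechanism is kurtosis-neutral by construction
  (small residual kurtosis, ~0.03, arises only from the bandpass filter
  re-weighting the time-varying correlation structure), keeping the entropy
  and kurtosis axes of the strain pattern independent. Physiologically this
  mirrors burst suppression, where slow waves dominate during suppression
  of faster activity.
* **Sparse transients (`spike_rate`, `spike_amp`).** Poisson-timed biphasic
  30 ms waveforms of amplitude `spike_amp` × RMS raise kurtosis. All
  baselines carry a background process (0.25/s at 6 SD), both because real
  epidural recordings contain occasional transients and because it gives
  kurtosis a realistic, reasonably symmetric between-subject spread. In the
  pattern checks, kurtosis changes are tested on the log scale (kurtosis is
  a positive ratio statistic with a right-skewed sampling distribution).

`strain_presets()` encodes the strains: PPKR's baseline delta excess and
4–32 Hz deficit; post-injury supra-delta gain loss in SD (broadband) and
PPKR (theta/beta) but identical band gains in PPKS; theta-range coherence
loss in all strains with post-injury delta shared fractions ordered
PPKS (0.25) < SD (0.50) < PPKR (0.82); ipsilateral-only burst suppression in
PPKS/SD; ipsilateral-only transient elevation in PPKR. Cohorts add
between-subject jitter: log-normal gain and RMS multipliers shared between
regimes (stable individual traits, so within-subject contrasts survive),
a smaller independent post-regime gain jitter, logit-scale shared-fraction
jitter, and a smooth per-subject log-spectral curve (SD 0.22, ~2 Hz
correlation length) emulating stable individual spectral shape. Subject
seeds derive from the master seed by a stated counter scheme
(`(seed·48271 + index) mod (2³¹−1)`), so manifests are order-independent
and bit-reproducible; the manifest records every jittered parameter and
regenerates each recording exactly.

One tension deserves emphasis: for PPKS the emulated pattern pairs an
ipsilateral entropy drop with an unchanged frequency distribution. Spectral
entropy is a deterministic functional of the binned spectrum, so both cannot
hold exactly; the generator realizes the entropy drop through the
ipsilateral burst suppression, which necessarily concentrates the
ipsilateral spectrum. The qualitative pattern check therefore tests the
"broadband loss present/absent" findings on the contralateral hemisphere,
where the strain-characteristic bilateral gain changes appear uncontaminated
by the entropy mechanism. Effect sizes in the presets were fixed once, by
simulation at n = 10 per strain, so that all ten tracked directional
findings are detected in essentially every cohort draw; they are study
conditions, not fitting parameters.

What the generator does **not** emulate: neural-mass or biophysical
dynamics, anesthesia depth, non-stationarity within a regime beyond the
burst envelope, inter-channel lag, volume conduction, electrode artifacts
other than the impact pulse, and the chronic post-injury period. Passing
tests therefore demonstrate that the analysis recovers the *statistical
structure it parameterizes* — spectra, coherence, entropy, kurtosis,
transients — not that it would behave identically on animal recordings.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains cohort generation → epoching/filtering → features →
statistics → pattern check → risk-score fit, writing one artifact per stage
(`manifest.csv`, `features.csv`, `spectra.csv`, `coherence.csv`,
`stats.json`, `patterns.csv`, `scorecard.json`, `run_info.json`). Every CSV
opens with the configuration hash and later stages refuse mismatched inputs,
so each stage is independently re-runnable from files. Raw recordings are
not written: a 30-subject cohort at 1,024 Hz would exceed half a gigabyte as
text, and the manifest plus the deterministic generator reconstructs any
recording bit-exactly, so the manifest *is* the synth-stage artifact.

Default study conditions are 10 subjects per strain at 1,024 Hz with 18-min
recordings. The test suite exercises the same code at reduced sampling rates
(128–256 Hz; the 0.5 Hz bin grid requires the rate to divide 1,024) and with
12–20 cohort draws for the pattern-reproduction checks — sizes chosen so the
suite completes comfortably on one CPU while keeping every detection rate it
asserts at or above 90%. The bundled `scripts/acceptance.R` recomputes the
published scorecard's worked examples from a fresh session and writes them
as JSON.

## Known limitations

* The binwise construct test treats bins as exchangeable strata and ignores
  spectral autocorrelation; its per-bin intervals are uncorrected, exactly
  as the emulated reporting style, and should be read as brackets, not
  adjusted inference.
* Hemisphere is modelled as a fixed effect; a mixed model with subject
  random effects would be more efficient but is out of scope.
* The risk-score search is exact only within its discrete design space
  (single split per feature, ±1 coefficients, integer intercept); it does
  not explore multi-way splits or re-optimized thresholds per subset.
* Coherence control in the generator is exact for the mixing model used;
  estimated magnitude-squared coherence carries the usual positive
  finite-window bias, so small shared fractions do not estimate to zero.
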