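---
title: "Estimating speech reception thresholds from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating speech reception thresholds from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The speech reception threshold (SRT) is the signal-to-noise ratio at
which a listener understands 50% of speech in noise. It is normally
measured behaviorally with an adaptive sentence test, which requires an
attentive, responsive listener. Neural speech tracking offers an
objective alternative: EEG recorded while a person listens to continuous
speech carries a response to the speech amplitude envelope, and the
fidelity of that response degrades as the noise level rises. `neurosrt`
implements a complete pipeline that turns this observation into a
threshold estimate — a *neural SRT* — and validates every stage against
synthetic data with known ground truth.

The pipeline has five stages:

1. **Envelope extraction** — the stimulus feature driving all models.
2. **EEG preprocessing** — bad-channel handling, referencing, filtering,
   resampling, normalization.
3. **Backward decoding** — lagged ridge regression reconstructing the
   envelope from EEG; per-trial reconstruction accuracy versus SNR is
   fitted with a constrained sigmoid whose midpoint is the neural SRT.
4. **Forward encoding (TRF)** — per-condition temporal response
   functions, parameterized by Gaussian deflections (P1, N1, P2) whose
   latencies and amplitudes are tested against SNR with a mixed model.
5. **Behavioral reference** — the adaptive word-scored staircase that
   measures the behavioral SRT the neural estimate is compared to.

# Stimulus envelope

`extract_envelope()` computes the broadband amplitude envelope as the
magnitude of the analytic signal (Hilbert transform), applies a power
law with exponent 0.6 to mimic cochlear compression, band-passes the
result between 1 and 8 Hz with third-order Butterworth high- and
low-pass filters each run forward and backward (a 12th-order zero-phase
band-pass overall), and resamples to 64 Hz. Continuous-speech audio
meant to mimic the long-term spectrum of the sentence-test corpus can
first be passed through `spectral_match()`, a first-order low-pass at
2 kHz realized with the exact analog frequency response.

Numerical choices a user should know about:

* **Filtering rate.** A third-order Butterworth high-pass at 1 Hz is
  numerically ill-conditioned in transfer-function form at audio rates,
  so audio sampled above 1024 Hz is brought to a 512 Hz intermediate
  rate (anti-aliased) before band-passing. The 1–8 Hz passband is
  unaffected.
* **Resampling.** All rate changes use zero-stuffing plus a linear-phase
  Kaiser-windowed FIR anti-alias filter whose integer group delay is
  compensated exactly, so resampling is zero-phase and envelope peaks
  stay aligned with the stimulus (verified to within one sample at
  64 Hz).
* **Edges.** Signals are reflect-padded by one filter-settling length
  before filtering; trials are always processed independently and never
  concatenated across the lag boundary.
* **Residual mean.** The high-pass suppresses DC but edge transients
  leave a small residual mean, which is removed exactly at the end; the
  lagged models mean-center their inputs, so this is neutral downstream.
* **Degenerate input.** All-zero audio returns an all-zero envelope with
  a warning flag rather than an error, because downstream correlations
  are undefined for it; NaN audio is an error.

# Lagged ridge regression

Both directions of modeling share one primitive. `build_lag_matrix()`
expands a signal into a time-by-(channel × lag) design matrix: under the
backward convention row *t* holds the EEG at *t* + τ for every lag τ in
the window (the decoder reconstructs the envelope at *t* from EEG that
follows it), and under the forward convention the envelope at *t* − τ
(the encoder predicts EEG from stimulus history). Out-of-range samples
are zero-padded.

`ridge_fit()` solves (XᵀX + λ·m̄·I)w = Xᵀy on mean-centered columns,
where m̄ is the mean diagonal of the centered Gram matrix. This makes λ
dimensionless: a given λ exerts comparable shrinkage regardless of trial
length, channel count or signal scale, so one λ per participant is
meaningful and values are comparable across participants. The decoder is
trained by pooling the rows of all clean-speech trials into a single
regression; λ is chosen by leave-one-out cross-validation over the clean
trials on a grid of integer powers of 10 from 10⁻⁴ to 10¹⁰ (decade
steps; ties broken toward heavier shrinkage). The encoder uses a fixed
λ = 100 across conditions and participants so TRFs remain comparable.

Windows: −100 to 350 ms for the decoder, −100 to 500 ms for the
encoder; positive lags mean the EEG follows the stimulus, and the
negative edge provides an acausal margin. At 64 Hz the lag count is
`round((τmax − τmin)/1000 × 64) + 1`.

# EEG preprocessing

`preprocess_trial()` applies, in fixed order: replacement of bad
channels (RMS more than 3× the mean RMS across channels, pooled over
the recording) by spherical-spline interpolation (Perrin-style,
stiffness m = 4, 50 Legendre terms); common-average referencing;
zero-phase 1–8 Hz band-pass; resampling to 64 Hz; division of every
channel by the mean of the per-channel standard deviations (one scalar
per trial, so relative topography is preserved); and a final
common-average re-reference. Synthetic recordings are generated
band-limited at 64 Hz and skip the filter/resample stages. A no-op
`artifact_hook` is provided where an ICA-based artifact-removal stage
would run on real recordings; artifact removal itself is outside the
package's scope.

# The neural SRT

For each trial the reconstruction accuracy is Pearson's correlation
between the decoder output and the presented envelope. Clean-condition
accuracies are computed by leave-one-out training within the clean
condition, so no trial is scored by a model that saw it. The noise
floor is built from mismatched envelopes — excerpts processed
identically but never presented; for synthetic runs these come from the
surrogate-envelope generator under unused seeds (default pool size 68).
Both series are truncated to the shorter length before correlating, and
the floor *b* is the mean over all trial × mismatch pairs.

Accuracy versus SNR is modeled as

S(SNR) = (p − b) / (1 + exp(4·s/(p − b)·(m − SNR))) + b

with the upper asymptote *p* fixed at the clean-condition mean accuracy
and the lower asymptote *b* fixed at the noise floor; only the midpoint
slope *s* and midpoint *m* are fitted, by least squares on the
trial-level points (not condition means). S(m) = (p + b)/2 and
dS/dSNR = s at the midpoint, which the tests verify to machine
precision. The midpoint *m* is the neural SRT, reported without bias
correction.

Fitting protocol: *s* starts at 0 and *m* uniformly within ±10 dB of
−2.52 dB (the average behavioral SRT of normal-hearing listeners on the
Danish sentence test); bounds are s ∈ [0, 10¹⁰], m ∈ [−10¹⁰, 10¹⁰];
100 restarts are run and the final parameters are the mean of the 10
restarts with the highest R². Because the least-squares basin is very
flat in (s, m), each restart's quasi-Newton search is finished with a
damped Gauss–Newton polish using the analytic Jacobian; noiseless
samples are then recovered to ~10⁻⁸. R² is computed on the trial-level
points that were fitted. The whole procedure can be repeated (default
100 times) with fresh restart seeds; the spread of the repeated
midpoints (max pairwise difference) is reported as a robustness
diagnostic.

Two permutation safeguards precede any fit: an inclusion gate per
participant (one-sided two-sample permutation test of the clean
accuracies against within-trial mismatch means; the fit is skipped when
it fails, and with *k*-vs-*k* values the test needs k ≥ 4 to be able to
reject at α = 0.05), and one-sided paired sign-flip tests of each
adjacent SNR pair at the cohort level (exact enumeration when at most
2¹⁴ sign patterns exist, otherwise at least 10⁴ random flips, giving a
p resolution of 0.01 or better).

# TRF deflections and SNR effects

Per condition, encoders are trained leave-one-out over trials; the
condition's TRF is the mean of the fold models and its prediction
accuracy the fold-averaged per-channel correlation between predicted
and recorded EEG. A global set of 17 electrodes with the highest
grand-average prediction accuracy is selected (ties broken by montage
order), conditions must pass a permutation gate against an
encoder-based mismatched-envelope floor, and the mean TRF over the
selected electrodes is parameterized by three Gaussians,
a(t) = p·exp(−((t − l)/w)²), fitted within per-component bounds
(P1: p ∈ [0, 5], l ∈ [0, 100] ms; N1: p ∈ [−5, 0], l ∈ [70, 150] ms;
P2: p ∈ [0, 5], l ∈ [100, 300] ms; w ∈ [0, 50] ms). The mean TRF is
computed first and then fitted, not the reverse. Fits with R² < 0.5 are
excluded; fits whose latency lands on a window bound are flagged
unreliable. Grand-average TRFs are truncated to −100 to 400 ms for
display because the final stretch of the window carries edge effects.

Each of the six features (latency and amplitude of P1, N1, P2) is then
modeled as `feature ~ SNR + (1 | participant)` by maximum likelihood
(`nlme::lme`), with SNR coded in dB relative to the behavioral SRT
(conditions are defined relative to it; the clean condition has no SNR
and is excluded). The SNR fixed effect is tested with a Wald test and a
Holm–Bonferroni correction is applied across the six tests. The
degrees of freedom reported are those of the fitted mixed model, not
forced to any particular convention.

# The synthetic-data generator

The generator exists so that every stage is testable without any
recordings, and its defaults are the study conditions the package
emulates: 16 trials per condition of ~1 minute each at five SNRs in
2 dB steps around the (behaviorally measured) SRT plus clean speech —
96 trials — with 64 channels on an idealized spherical 10-10 montage.

* **Envelopes** are 1–8 Hz band-passed Gaussian noise at 64 Hz,
  mean-removed: the modulation spectrum peaks in the 2–6 Hz range
  typical of speech. Real speech rhythm, pauses and spectral detail are
  *not* emulated.
* **The TRF kernel** is a sum of three Gaussians (P1/N1/P2) with
  baselines l₀ = 50/120/200 ms, p₀ = 0.10/−0.15/0.18 a.u., widths
  25/30/40 ms at the reference SNR, shared across channels up to a
  smooth frontocentrally peaked unit-norm topography (Gaussian in
  angular distance from FCz, 45° spread). Latencies and amplitudes move
  linearly with SNR using per-dB slopes of −0.940/−1.517/−6.001 ms and
  0.011/−0.015/0.018 a.u. — the mixed-model coefficients estimated on
  real listeners — so latencies shorten and magnitudes grow with SNR.
  Guards reject parameter combinations that would invert the P1 < N1 <
  P2 latency order or flip an amplitude sign. Clean speech maps to an
  effective relative SNR of +6 dB (highest gain, shortest latencies).
* **Listeners** have a true SRT, a per-word logistic psychometric
  function (probability correct exactly 0.5 at the SRT), and a neural
  gain g(SNR) ∈ (0, 1], logistic in SNR and centered on the true SRT.
  No quantitative link between stimulus SNR and neural tracking
  strength is established in the literature, so the logistic form is a
  modeling choice of this package. It makes the accuracy-versus-SNR
  curve sigmoid with its informative region near the behavioral
  threshold, which is precisely the structural assumption the fitting
  stage relies on; end-to-end SRT recovery is therefore a meaningful
  but not a vacuous test (the shapes agree, the scales and noise do
  not).
* **EEG** is the kernel-envelope convolution scaled by g(SNR) plus
  noise: 90% 1/f-shaped and 10% white, with SD equal to `noise_level`
  times the mean clean-signal channel SD. The default `noise_level =
  10` puts clean-speech reconstruction accuracies around 0.4–0.55 — the
  upper end of the range reported for envelope tracking in EEG — while
  keeping the accuracy curve informative around the SRT. Real EEG is
  noisier and richer (artifacts, non-stationarity, per-channel response
  variation); passing tests on this generator demonstrates correctness
  of the pipeline, not expected field performance.
* **Determinism.** All randomness flows from one master seed through a
  documented splitting scheme (`derive_seed()`); every generated
  artifact records its seed, and a run is byte-reproducible from
  (config, seed).

One structural limitation is worth stating: because the synthetic
kernel is separable (one time course times a topography), noise-free
synthetic EEG is rank-one across channels, and decoding reduces to a
finite-window inversion of a filter with in-band spectral dips. Exact
reconstruction is therefore impossible even without noise; the
achievable ceiling is r ≈ 0.999 on interior samples, and the test suite
asserts the backward/forward consistency invariant at r > 0.99.

# Validation sizes

The test suite validates the pipeline at sizes chosen to keep the whole
suite fast while preserving the design's structure: unit tests use 4–16
channels and 10–20 s trials; the end-to-end cohort check uses 20
simulated listeners, 6 conditions × 8 trials × 30 s at 32 channels with
the default noise level, and requires at least 75% of listeners to be
recovered within ±2 dB of their true SRT; permutation calibration uses
1000 null replicates at reduced counts. The full-scale defaults (20
listeners, 96 one-minute trials, 64 channels) run the same code paths.

# Known limitations

* Artifact removal (ICA-based component rejection, line-noise filters)
  is out of scope; the preprocessing exposes a hook for it.
* The simulated listener's neural gain and noise model are stylized;
  absolute accuracy values should not be read as predictions for real
  recordings.
* The behavioral staircase applies no rounding to SNR steps (a
  continuous dB track); hardware implementations often quantize.
* The sigmoid's asymptotes are fixed, not fitted; when the clean
  condition is not representative of the noise conditions' plateau the
  midpoint inherits a small bias (the end-to-end tests bound it).
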