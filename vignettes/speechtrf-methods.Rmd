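---
title: "Dual-level auditory TRF analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-level auditory TRF analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a listener attends to continuous speech, the auditory pathway
produces responses at two very different time scales from the same EEG
recording: a brainstem/midbrain response locked to fast fluctuations of
the stimulus (a wave V-like deflection peaking a few milliseconds after
acoustic energy), and a cortical response tracking the slow speech
envelope (a P1–N1–P2-like complex spread over hundreds of
milliseconds). `speechtrf` estimates both with the same machinery — a
temporal response function (TRF) — and then asks the group-level
questions a clinical study would ask: do response amplitudes differ
between two participant groups, and do they predict group membership
once hearing threshold (PTA) and age are controlled for?

## The forward model

The TRF is a lag-indexed linear kernel `w` mapping a stimulus feature
`s(t)` to the recorded response `r(t)`:

    r(t) = sum_l w(l) s(t - l) + noise.

Stacking delayed copies of the feature into a time × lag matrix `S`
(`lag_matrix()`), the ridge estimate with Laplacian smoothing is

    w = (S'S + lambda * M)^-1 S'r,

where `M = D'D` is the second-difference (Laplacian) penalty
(`laplacian_matrix()`): it shrinks squared differences of neighboring
lag weights, so large `lambda` yields smooth kernels rather than small
ones. `ridge_solve()` performs the linear solve without forming an
inverse; a singular system receives a `1e-10 * trace` diagonal jitter
before failing hard.

Key estimation conventions, each of which was a genuinely open choice:

* **Scaling.** The EEG is z-scored *globally* (one mean/SD over all
  epochs and channels) before any train/test split; features are
  standardized with training-set statistics (`scale_pair()`,
  z-scoring by default, max-normalization by option — the choice only
  rescales `lambda`). Only after scaling are missing markers (tail
  padding of short segments, artifact-zeroed windows) replaced by
  zeros, so they cannot bias the statistics. Masked samples enter the
  solve as zeros rather than being row-dropped; the mask is retained so
  the alternative can be explored.
* **No intercept.** Both sides are centered by the scaling, so the
  model carries no explicit intercept column.
* **Regularization path.** `lambda` is selected by leave-one-segment-out
  cross-validation over the grid `10^(-3..9)` (13 points,
  `cv_lambda()`): every training segment serves as the validation
  segment once, encoding accuracy is the Pearson correlation between
  predicted and actual response (averaged over channels), and ties on
  the accuracy curve break toward the *smaller* `lambda` (least
  smoothing bias). A final model is refitted on all training segments
  at the winner and evaluated once on held-out test segments (3 of 25
  by default, split at the segment level with a fixed seed).
* **Test accuracy** is computed per held-out segment and then averaged
  (the alternative — concatenating segments first — is a one-line
  switch in user code; per-segment averaging avoids splicing
  discontinuities into the correlation).
* **Polarity averaging.** The subcortical model is fitted twice, for
  features derived from the original and the sign-inverted stimulus,
  and weights/accuracies are averaged (`fit_dual_polarity()`). Any
  response component that is *odd* under stimulus polarity — i.e.
  electrical stimulus artifact — cancels in the average, exactly like
  alternating-polarity click averaging.

## The two preprocessing chains

Both chains are built from the same Hamming-window FIR design rule
(`fir_length()`): `ceil(3.3 / transition_bw * fs)` rounded up to odd,
with the narrowest transition bandwidth governing band-pass designs.
This rule reproduces the reference tap counts of all five standard
designs used by the chains (2705, 357, 1691, 423, 1057). The Hamming design has a nominal 0.0194 dB pass-band
ripple and 53 dB stop-band attenuation; the realized attenuation of the
finite designs is verified to exceed 53 dB in the tests, while the
measured pass-band ripple of a finite design slightly exceeds the
nominal figure near the band edges (≤ 0.05 dB is what we assert).

* **Subcortical chain** (wave V latencies): *causal* one-pass FIR
  filtering — group delay left in place, so no future samples leak into
  pre-stimulus lags (a property the tests check explicitly) — band-pass
  80–1365.3 Hz, IIR notches at all 50 Hz multiples (2nd-order
  Butterworth band-stops applied forward–backward, effective order 8,
  5 Hz wide), target rate 4096 Hz, vertex electrode (Cz, falling back
  to Pz), ±100 µV artifact zeroing in 1 s windows (`zero_artifact_segments()`).
* **Cortical chain** (envelope tracking): zero-phase FIR filtering
  implemented as one-pass linear-phase filtering with group-delay
  compensation — *not* `filtfilt`, which would square the magnitude
  response and double the design's attenuation and ripple — anti-alias
  at one third of each target rate (transition bandwidth 0.3 × cutoff),
  decimation to 128 Hz, 1–9 Hz band-pass, EOG-regression artifact
  removal (`remove_ocular()`; an external ICA can be plugged in), and
  bad-channel interpolation by inverse-distance weighting of the 4
  nearest neighbors on the standard montage (the interpolation
  algorithm is not dictated by anything upstream; nearest-neighbor
  weighting is the documented stand-in, spherical splines would be a
  drop-in alternative).
* **Evoked responses**: click-ABR epochs (−10..30 ms, baseline
  −10..−5 ms, 40 µV epoch rejection) and speech-onset AEPs
  (−300..600 ms, baseline −200..−50 ms) via `epoch_and_decimate()`,
  `baseline_correct()`, `reject_epochs()`, `evoked_average()`.

## Response measures

TRF weights are baseline-corrected (−10..−5 ms subcortical,
−200..−50 ms cortical) and z-standardized with a single mean/SD pooled
over all participants' samples (`standardize_weights()`). Pooling over
participants × time is our reading of "standardized across
participants"; per-time-point standardization is available by
configuration. Peaks are extracted (`extract_peak()`) as the extremum
inside a search window — wave V 4–11 ms (positive), N1 50–120 ms
(negative), P2 120–300 ms (positive) for TRFs; 4–9 ms, 50–150 ms and
150–300 ms for the evoked responses — with mean amplitude over a
centered window (3 ms subcortical, 50 ms cortical). Exact ties resolve
to the earliest sample, for determinism; a "peak" of the wrong sign is
flagged rather than silently reported. Cortical waveforms are averaged
over the frontotemporal cluster F3, FC1, FC5, FC6, FC2, F4 before peak
extraction.

The electrode-wise group comparison (`electrode_permutation_test()`)
is a cluster-based permutation test: per-electrode two-sample t
statistics, spatial clusters over a montage-distance adjacency
(threshold 0.55 head radii — the adjacency is a package choice, since
no canonical neighbor list exists for this montage), cluster mass
compared against the permutation distribution of the maximum mass
under group-label shuffling. Cluster-forming threshold defaults to
two-sided t at α = 0.05 and 1000 permutations; both are configuration,
not inference.

## Statistics layer

* `mann_whitney()` wraps `stats::wilcox.test` (exact enumeration for
  small untied samples, normal approximation with tie correction
  otherwise) and adds the rank-biserial effect size
  `r = 2U/(n1 n2) − 1`.
* `bayes_rank_two_sample()` implements the latent-normal
  data-augmentation Gibbs sampler for a rank-based two-sample test:
  latent values truncated to the observed pooled rank order, a
  standardized group difference `delta` with a Cauchy(0, 0.707) prior
  handled through its inverse-gamma scale mixture, and a Savage–Dickey
  Bayes factor at `delta = 0` (Gaussian-kernel posterior density
  estimate). One-tailed hypotheses are expressed through the
  `alternative` of the frequentist test; the Bayesian `delta` sign
  convention is "first sample larger → positive".
* `rope_proportion()` reports the fraction of posterior mass inside
  ±0.1 (a conventional small-effect region). The phrase "proportion of
  the posterior represented by the 95% credible interval" is ambiguous
  between full-mass and CrI-restricted proportions, so both are always
  computed; the full-mass number is the default and the mode is flagged
  in the output.
* `logistic_fit()` fits `group ~ waveV * N1P2diff + PTA + age`
  (`build_design()`; low group coded 0, TRF amplitudes z-scored,
  evoked amplitudes in µV) by IRLS with Wald inference and explicit
  separation detection. `logistic_bayes()` samples the same model by
  adaptive random-walk Metropolis (proposal shaped by the ML Wald
  covariance, globally rescaled toward 25–35% acceptance during
  warm-up; split-half R-hat flags non-convergence above 1.05). A flat
  prior is the noninformative baseline, but a Savage–Dickey Bayes
  factor under a flat prior is ill-posed, so per-predictor BFs are
  computed under documented weakly informative normal priors
  (SD 2.5 on slopes, 10 on the intercept); both prior modes are
  exposed. ROPE proportions are evaluated on predictor-standardized
  coefficients. No multiple-testing correction is applied anywhere —
  each peak is tested separately by design.

## The synthetic generator

Because no public recording exists for this paradigm, the package
ships a generator that emulates the study conditions: 25 speech
segments of ~45.7 s, EEG at 16,384 Hz, 32 scalp + 4 auxiliary
channels, and a two-group cohort of 19 vs 25 participants
(`synth_config()` defaults). Stimulus features are modulated-noise
surrogates — non-negative broadband carriers whose envelope is
modulated in the 2–8 Hz syllable band, with a ~0.47 s near-silent
lead-in standing in for stimulus-onset jitter (the retained-silence
duration is a parameter, since only its range is known). TRF machinery
is agnostic to stimulus content, which is why no acoustic speech
synthesis is attempted. Ground-truth kernels are Gaussian-bump sums: a
wave V-like positive peak at 9 ms (amplitude 0.35 µV per unit feature,
width 1.2 ms) and a P1–N1–P2 complex at 50/91/170 ms (+1.5/−3/+2.5 µV,
widths 14/20/28 ms), the cortical kernel being the outer product of
that waveform with a topography that peaks over the frontotemporal
cluster (a weight vector, not a leadfield — there is deliberately no
forward head model). Noise is 1/f (8 µV), white (4 µV), 50/100/150 Hz
line sinusoids (5 µV; three harmonics suffice to exercise the notch
stage at desk scale), and biphasic 300–500 ms blink transients with a
frontal-dominant projection (0.2/s, 120 µV) — something real for the
artifact stage to remove. `snr_db` rescales total noise to a requested
signal-to-noise variance ratio, which is the dial the recovery
experiments turn. Group structure: participant kernel scales are
log-normal (sdlog 0.25), the low group's scales multiplied by
`1 + effect_delta` (pure amplitude effect by default; an optional
latency shift exists because the tested hypothesis is about
amplitudes). Everything derives deterministically from one master seed.

**What the generator does not emulate** — and therefore what passing
tests do *not* show about real data: no cochlear nonlinearity beyond a
power-law surrogate, no head-model topographies, no non-stationary
artifacts (electrode drift, movement), no stimulus-correlated noise,
and kernels that are exactly time-invariant. Recovery results bound
what the estimator can do under its own assumptions, not what real EEG
will yield.

The auditory-periphery firing-rate model used on real stimuli is *not*
re-implemented: `nerve_rate_surrogate()` is a documented band /
half-wave-rectify / compress (exponent 0.4, a standard cochlear
compression value) / smooth / average surrogate over 43 log-spaced
bands (125 Hz–16 kHz), preserving the properties the TRF uses (onset
emphasis, envelope following), and `read_feature_file()` imports
externally computed rate series for users of the real model.

## Problem sizes and numerical choices in the shipped tests

The validation suite chooses sizes that keep the default run in a few
minutes on one CPU; they are the package's own study conditions:

* Kernel recovery: one participant at the full 25 × 48 s design
  (subcortical at 4096 Hz, cortical at 128 Hz), SNR 10 dB, full 13-point
  `lambda` grid; recovery criterion r ≥ 0.9 against the generative
  kernel (achieved ≈ 0.9999 subcortical, ≈ 0.996 cortical).
  Recovery cohorts are *level-isolated* (the other level's kernel
  amplitude set to zero): at full bandwidth the slow cortical response
  leaks into the −10..30 ms window at the vertex, and the 80 Hz causal
  high-pass that separates the levels in the real pipeline would also
  reshape the wave V kernel, confounding a correlate-with-truth
  criterion. Latency checks use 4-participant cohorts at reduced
  segment counts.
* Statistical calibration (type-I 5% ± 2%, power ≥ 80% at
  `effect_delta = 0.5`, BF10 > 3) uses the generator's *light mode*
  (`generate_cohort(signal = FALSE)`): peak amplitudes drawn from the
  cohort amplitude model (participant scale × kernel peak × 10%
  measurement noise) without EEG synthesis — hundreds of full-EEG
  cohorts are not a sensible use of compute, and these properties
  concern the statistics, not the deconvolution.
* The pipeline demo (`run_pipeline()`) synthesizes directly at the two
  analysis rates rather than at 16,384 Hz followed by decimation; the
  decimation stage has its own unit tests.
* Numerical guards throughout: ridge jitter `1e-10 * trace`;
  encoding accuracy of a constant prediction returned as 0 with a
  warning; Savage–Dickey densities floored at `1e-300`; truncated-
  normal draws fall back to the nearer bound when the interval mass
  underflows; EOG regression skips flat reference channels.

## Known limitations

Subcortical TRFs from ~17 min of speech are intrinsically noisy; the
leave-one-out-then-refit strategy (chosen over nested cross-validation
for data economy) can overfit, and negative test accuracies for some
simulated participants at low SNR are expected, mirroring practical
experience. The Bayes factors from the two samplers are estimator-
specific (kernel density at zero); they are not claimed to equal any
other software's numbers, only to order evidence sensibly — which is
what the calibration tests assert.
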