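---
title: "Modelling and decoding auditory oddball evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and decoding auditory oddball evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`oddballerp` implements an end-to-end computational study of auditory
novelty responses in the anaesthetised-mouse preparation: a synthetic
generator for epidural evoked-potential recordings under frequency and
intensity oddball stimulation, the standard epoched-ERP preprocessing
chain, time-resolved multivariate decoding with group-level cluster
statistics, and a hierarchical recurrent network that learns to map a
time–frequency representation of the sound directly onto the evoked
waveform. This vignette explains the models, their assumptions, the
tunable parameters, and the design decisions taken where the design was
genuinely open.

## The experiment being emulated

Both oddball paradigms present sequences of 1000 pure tones: 800
standards (10 kHz, 80 dB SPL, 100 ms), 100 "increasing" deviants and
100 "decreasing" deviants (frequency paradigm: ±2.5 kHz; intensity
paradigm: ±10 dB), with a constant 450 ms offset-to-onset interval and
never two deviants in a row. Trials span −0.1 to 1.0 s around a first
tone and therefore contain two consecutive evoked responses — the first
tone (standard or deviant) and the following standard at 0.55 s. Trial
counts are balanced by keeping only the 200 standards that immediately
precede a deviant. Signals are recorded bilaterally over auditory
cortex at 1000 Hz, band-pass filtered 0.1–30 Hz, baseline-corrected on
the 0.1 s pre-stimulus window, and resampled to 100 Hz, giving 111
samples per trial.

## The synthetic cohort generator

`cohort_config()` + `build_synthetic_dataset()` generate the cohort the
downstream analyses assume. Every trial is

* a noise-free condition **template**: a sum of Gaussian bumps
  (latency = mean, width = SD), one pair of onset (negative, 30 ms
  post-onset) and offset (positive, 30 ms post-offset) responses per
  tone, their gains increasing with tone level and modulated by tone
  frequency, so the standard's amplitudes always lie between the two
  deviants';
* a long-latency positive ("danger") bump at 0.38 s on fD1, fD2 and iD1
  trials, a late positive bump at 0.88 s on iD2 trials (the 80 dB
  standard after a 70 dB deviant is a rising sound-level transition),
  and a subtle negative ("safety") deflection at 0.70 s on fD2 and iD1
  trials — the asymmetric long-latency structure the decoding analyses
  look for;
* times a per-animal, per-component multiplicative gain
  (`animal_effect_sd`, default 0.1, mean 1), which preserves each
  animal's template geometry;
* plus a 10 Hz background rhythm with per-trial random phase
  (`alpha_amplitude`, default 0.2 — small relative to the unit onset
  peak so that it does not mask components, yet large enough for
  alpha-like units to emerge in the trained network);
* plus white noise at the native rate (`trial_noise_sd`, default 1.0),
  which the 0.1–30 Hz filter stage band-limits to an effective SD of
  roughly 0.25 amplitude units.

The defaults are the study conditions (14 animals, 2 channels,
800/100/100 sequences). Noise parameters are the package's own choices
— the source recordings' per-animal variance is not published — picked
so that single-trial long-latency effects are decodable but far from
ceiling at the single-time-point level. What the generator deliberately
does **not** emulate: volume conduction and channel covariance (the two
channels are the same source scaled by fixed gains with independent
noise), latency jitter, slow drift and non-stationarity, and the
deviant response that would physically occur in the second half of a
"standard-preceding-deviant" trial (trials are realised from their
condition template, matching the description of standard trials as two
repeated standard responses). Passing tests therefore show the
*methods* behave correctly on data with this structure, not that real
recordings would yield the same numbers.

## Stimulus representation

Tone waveforms are synthesised at 100 kHz over the trial window with
peak amplitude $10^{(L-80)/20}$ for level $L$ (80 dB ↦ 1), zero phase
and no on/off ramps (the source description specifies none). The model
input is the short-time Fourier transform magnitude on Hann windows of
200 samples with 100-sample overlap: 101 one-sided bins from 0 to
50 kHz in 0.5 kHz steps. The 1000 Hz frame sequence is down-sampled to
100 Hz by plain subsampling (bit-exactly reproducible, and the frame
centres then align with the 111-sample trial grid at −0.1, −0.09, …,
1.0 s); edge frames are zero-padded; no normalisation constant is
applied to the magnitudes — any fixed scaling would be absorbed by the
first-layer weights.

## Decoding and statistics

`timewise_decode()` trains a linear soft-margin SVM (fixed C = 1) on
the two channel amplitudes at each time point, per animal: the larger
class is randomly under-sampled to equality, 10-fold stratified
cross-validation is repeated 5 times with fresh under-sampling and fold
allocation, features are standardised with training-fold statistics
(making accuracy exactly invariant to common amplitude rescaling), and
accuracy is the mean over all folds and repeats.
`temporal_generalization()` evaluates each time-t classifier at every
test time. Seeds follow a ladder (master → per animal/contrast/repeat),
so animals are independent and every map is reproducible.

`cluster_permutation()` performs the group-level one-sample test
against chance: per-point t statistics across animals, two-sided
cluster-forming threshold at α = 0.05, contiguous clusters (1-D
neighbours; 4-connectivity on the train × test grid), cluster mass =
summed t, and a maximal-statistic sign-flip null (default 1000
permutations, both signs pooled) with the +1-corrected p-value
$(1+\#\{\text{null} \ge |\text{mass}|\})/(1+n_{perm})$. The
cluster-forming threshold and permutation count are declared defaults,
not values inherited from the source analysis, which does not state
them. Numerical edge case: columns with exactly zero variance across
animals produce infinite t under sign flips; t-maps are capped at
±10^6 so masses stay well-ordered.

## The hierarchical recurrent network

The model is a firing-rate-style network: 101 input units (one per
STFT bin) feed four layers of 64 recurrent units,
$h_t = \mathrm{relu}(W x_t + U h_{t-1} + b)$, topped by a single
*linear* recurrent output unit that emits the evoked waveform. The
rectifier is the package's choice of activation — the source never
names one, but exact-zero "zero units" are natural under a rectifier
and implausible under saturating odd functions; the linear output is
forced by signed targets. Inter-layer weights are Glorot-uniform,
recurrent weights orthogonal (QR of a normal matrix, sign-fixed; ±1
for the scalar output recurrence), biases zero, initial states zero.
Training minimises MSE against the 800 idealised trials with Adam
(lr 0.001, β₁ 0.9, β₂ 0.99, ε 10⁻⁸ — ε is unreported upstream),
batch size 32 with seeded shuffling. Full-protocol training is 500
epochs; five identically configured models are trained from distinct
seeds and the one with highest mean r² (squared Pearson correlation
between output and grand-average waveform per condition; ties broken
by lower MSE) is selected.

The compiled trainer exploits the fact that only five distinct input
sequences exist: within each minibatch, the forward/backward pass runs
once per distinct condition and per-trial losses enter through the
per-condition trial counts and mean targets. The gradients and the
recorded loss are *identical* to trial-by-trial processing (the
within-condition target spread is added back as a constant), about six
times faster.

On the default synthetic dataset the selected model reaches a mean r²
of about 0.95 after 500 epochs and about 0.93 after 150; the test
suite trains its ensemble for 150 epochs and asserts the
correspondingly relaxed bound (0.85), a deliberately scaled protocol
whose label appears in the test file. Targets are kept in raw
amplitude units, and inputs in raw magnitude units; one consequence is
that degenerate fits (e.g. all-zero targets) are judged by relative
output-power collapse rather than an absolute loss threshold, since
the loss floor scales with the input magnitude.

## Unit taxonomy, entropy and PCA

Hidden units are categorised per condition from their 111-sample
trace by a decision cascade — zero (never active), alpha (global peak
pre-stimulus, or pre-stimulus activity above mean + 3 SD of the whole
trace with post-stimulus peak below half the pre-stimulus peak), then
by peak latency: onset (stimulus-on windows 0–.1 and .55–.65 s),
offset (+50 ms), safety (+50–150 ms), danger (.25–.55 s), else other
— and a unit's modal category is the most frequent across the five
conditions, ties resolved in cascade order. Boundary samples belong to
the earlier window; the peak is the earliest global argmax. The
alpha-rule mean and SD are computed over the unit's full trace (the
source leaves this open; the pre-stimulus-only alternative changes few
assignments and none of the structural invariants).

Sample entropy uses the Richman–Moorman estimator with m = 2 and
tolerance r = 0.15 × SD of the series (the bare "r = .15" is read as
the standard SD fraction), Chebyshev distance, self-matches excluded.
Conventions: constant series → 0 (the unmodified estimator would give
ln((N−m)/(N−m−1)) ≠ 0); if no (m+1)-length matches exist the maximal
defined value −ln(1/B) is returned. The implementation is verified
against an independent brute-force double-loop oracle to 10⁻¹² in the
test suite.

The three PCA views (conditions 5 × 28 416, layers 4 × 35 520, and per
layer units 64 × 555) are feature-mean-centred and projected on two
components via `prcomp`; explained-variance fractions are reported
alongside the scores.

## Probe experiments

Probe tones are presented alone — no trailing standard — in the
standard window (the source figures show single-stimulus responses;
whether a trailing standard was included is not stated). Onset peak =
most negative output in [0, 0.15] s; offset peak = most positive in
(offset, offset + 0.1] s. The literal window "[0, 0.1 + duration]"
for the onset peak would overlap the offset response for long tones,
so the fixed 0.15 s window is used instead. The qualitative checks
assert strictly increasing offset-peak latency across the duration
sweep and non-decreasing onset-peak magnitude across the intensity
sweep; the frequency sweep is reported without assertion — the
original finding is precisely that frequency does *not* behave
proportionally.

## Problem sizes and reproducibility

Everything stochastic takes a seed; identical configuration + seed
reproduces every output byte for byte (`run_pipeline()` writes a
manifest with the master seed and a config checksum). The analysis
scripts under `analysis/` run the full protocol (14 animals, 5 repeats,
1000 permutations, 5 × 500 epochs). The test suite runs the same code
at reduced sizes chosen as its own protocol: a 3-animal cohort for
module tests, the 14-animal cohort for calibration checks (decoding
repeats = 2), 500 null datasets for the family-wise-error calibration,
and the 150-epoch ensemble. Known limitations: the generator's noise
model is white + rhythm only; the decoder is strictly linear and
two-channel; cross-validated MSE values depend on the (unpublished)
loss-reduction convention of the source and are not comparable to its
printed numbers; and unit-level findings (e.g. in which layer danger
units appear) are training-stochastic — the package logs them rather
than asserting them.
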