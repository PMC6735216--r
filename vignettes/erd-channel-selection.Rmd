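---
title: "ERD topography and individualized channel selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERD topography and individualized channel selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdtopo)
```

## The problem

When a person attempts to move a hand, the sensorimotor rhythms of the
EEG — alpha (8–13 Hz) and beta (13–30 Hz) oscillations over central
electrodes — lose power. This *event-related desynchronization* (ERD) is
the control signal of most motor brain–computer interfaces (BCIs): a
classifier watches a handful of electrodes and decides, trial by trial,
whether the user is attempting a movement or resting.

Healthy users express ERD over the contralateral primary sensorimotor
cortex (SM1), so BCIs conventionally record from fixed montages around
C3/C4. After a stroke, however, motor intention may be expressed elsewhere:
over a wide bilateral field, over the ipsilateral hemisphere, or almost
nowhere. A channel montage fixed at contralateral SM1 can then miss the
signal entirely. `erdtopo` implements the complete analysis needed to study
this problem: ERD-ratio topography estimation, three channel-selection
strategies (two fixed SM1 montages and an individualized lowest-ERD-ratio
selection), CSP + linear-SVM decoding with cross-validation, and the
repeated-measures comparison of strategies. Because clinical EEG of this
kind is rarely shareable, the package also ships a synthetic session
generator with known ERD ground truth, so the whole pipeline is testable
end to end.

## The experimental paradigm being modelled

Each session contains 40 seven-second trials in randomized order: 20 cue
trials, in which an arrow instructs a hand-opening motor attempt, and 20
blank controls in which the subject only fixates. Inter-trial intervals are
randomized between 5 and 6 s. Within a trial, the subject rests during the
fixation period (we use seconds 1–3 as the resting state) and performs the
attempt after the cue (seconds 4–7, the moving state). EEG is recorded from
64 channels of a 10/20-extended montage at 500 Hz, with an EOG channel at
position 32, CPz reference and AFz ground.

## Preprocessing

`preprocess_session()` applies, in order:

1. **EOG removal** (`drop_eog()`): channel 32 is discarded, leaving 63
   scalp channels. A 7 s epoch then holds 63 × 3500 = 220500 data points.
2. **Common average reference** (`average_reference()`): at every sample
   the mean over channels is subtracted.
3. **Zero-phase FIR band-pass 1–40 Hz** (`bandpass_fir()`): a Hamming
   windowed-sinc filter applied by FFT convolution with exact group-delay
   compensation. The design targets a 1 Hz transition at the low edge
   (~1650 taps at 500 Hz), which places the ~53 dB Hamming stop band at
   0.5 Hz and far below the 20 dB attenuation the pipeline requires at
   half the low edge and 1.5× the high edge. A longer filter would buy
   nothing those requirements need while tripling the dominant FFT cost.
4. **Epoching** (`epoch_trials()`): one 7 s epoch per trial mark; a final
   trial running past the end of the recording is dropped with a warning.
5. **Baseline removal** (`remove_baseline()`): the per-trial, per-channel
   mean over seconds 0–1 (pre-cue fixation) is subtracted. The choice of
   window matters little because all downstream quantities are variances
   or band powers.
6. **Artifact rejection** (`reject_artifact_trials()`): any trial whose
   filtered amplitude exceeds ±100 μV on any channel is removed. This
   deterministic amplitude criterion replaces interactive, ICA-assisted
   visual screening, which cannot be reproduced programmatically; it is
   transparent and testable, but it will not remove stereotyped artifacts
   (e.g. residual eye activity) that stay under the threshold.

For spectral and decoding analysis the package then reduces the sampling
rate by an integer factor (`downsample_epochs()`, default 4× → 125 Hz in
`run_pipeline()`). The 1–40 Hz band-pass acts as the anti-alias filter;
with all analysis confined below 30 Hz, a 62.5 Hz Nyquist frequency is
ample, and the wavelet and CSP stages run an order of magnitude faster.

## Time–frequency analysis and the ERD ratio

`morlet_tfr()` convolves every trial and channel with complex Morlet
wavelets on a 0.5 Hz grid across each band (alpha 8–13 Hz, beta 13–30 Hz).
The wavelet width is 7 cycles at every frequency — the conventional
compromise between temporal and spectral resolution for 8–30 Hz work: at
10 Hz this gives a ~±0.33 s temporal and ~±1.4 Hz spectral envelope.
Power maps are stored on a decimated time grid (default 25 frames/s); the
map records its own frame rate, which is the rate entering all subsequent
time integrals, so integral ratios are unaffected by the choice.
Per-epoch maps are averaged within a trial class (`average_tfr()`) before
any ratio is formed, which stabilizes the induced-power estimate.

The ERD ratio of channel $c$ compares duration-normalized time–frequency
energy between the moving and resting states:

$$
\mathrm{ERDratio}_c \;=\; \frac{E_1-S_1}{E_2-S_2}\cdot
\frac{\sum_{f=l}^{h}\sum_{t=S_2}^{E_2} \tfrac{1}{R}\,\mathrm{spe}_c(f,t)}
     {\sum_{f=l}^{h}\sum_{t=S_1}^{E_1} \tfrac{1}{R}\,\mathrm{spe}_c(f,t)}
$$

with $[S_1,E_1)$ the resting window (1–3 s), $[S_2,E_2)$ the moving window
(4–7 s), $[l,h]$ the band and $R$ the frame rate. Values below 1 mean power
dropped during movement. Any fixed PSD normalization cancels in the ratio,
so the absolute wavelet scaling is immaterial downstream. Time windows are
half-open, times are 0-based seconds within the trial.

Of the two bands, the one whose *minimum* channel ratio is lower is taken
to represent motor intention (`select_band()`; exact ties resolve to
alpha). The minimum — rather than, say, the mean of the lowest few
channels — matches the focal nature of ERD; a spatially diffuse criterion
would favour broad shallow power shifts over genuine focal
desynchronization.

### Topography patterns

`classify_pattern()` operationalizes the five clinically observed
topography groups with an explicit rule, where a channel is *active* if its
selected-band ratio falls below `theta_active` (default 0.8, i.e. at least
a 20% duration-normalized power drop):

* no active channel: **ERD-blind** if the unaffected hand's map also shows
  no ERD, else **ERD-disappearance**;
* ≥ 6 active channels spanning both hemispheres or lying predominantly
  ipsilateral: **ERD-proliferation**;
* all active channels inside the contralateral SM1 neighborhood
  ({C3, C1, C5, FC3, CP3}, mirrored for a left paretic hand): **ERD-SM1**;
* anything else: **others**.

The original grouping of patients was visual; this rule is the package's
reproducible rendering of the stated criteria (presence, laterality,
spatial extent), and the thresholds (0.8, 6 channels) are design choices,
not measured quantities.

## Channel-selection strategies and decoding

Three strategies feed the classifier (`sm1_4()`, `sm1_5()`,
`erd_lowest_k()`): the fixed contralateral montages {Cz, C1, C3, C5} and
{C1, C3, C5, FC3, CP3} (mirrored for a left paretic hand), and the
individualized selection of the `k = 4` channels with the lowest ERD ratio
in the selected band. Ties in the ratio are broken by montage label order
so the selection is deterministic and storage-order invariant. The
individualized selection uses a single representative band rather than
mixing bands across channels.

`crossval_accuracy()` decodes motor attempt vs rest (blank-control trials)
with stratified 5-fold cross-validation — 80% of trials train, 20% test in
each fold. Within each training fold only:

1. trials are restricted to the selected channels and the moving-state
   window (4–7 s) — blank controls are rest throughout, so the same window
   is a fair comparison;
2. each trial is band-filtered into alpha and beta (zero-phase
   frequency-domain mask with 2 Hz raised-cosine transitions);
3. CSP filters are fitted per band: eigenvectors of the whitened class
   covariance, from per-trial covariances normalized by their trace. All
   $n$ filters per band are kept, giving the stated feature dimension of
   $2n$ for $n$ selected channels (log-variance features of both bands
   concatenated);
4. a linear soft-margin SVM (cost 1, no class weighting) is trained on the
   training-fold features and scored on the held-out fold.

Test-fold trials never influence the filters or the classifier. A
rank-deficient composite covariance triggers logged diagonal loading;
zero-variance projections are floored before the log.

## Strategy comparison statistics

`group_summary()`, `rm_anova()` and `bonferroni_paired()` reproduce the
statistics stage from a per-subject accuracy table (the published table
ships with the package, `published_accuracies()`). The repeated-measures
ANOVA partitions the subject × strategy matrix into subject, strategy and
residual sums of squares, testing the strategy effect on
$(s-1,\,(s-1)(n-1))$ degrees of freedom. Summary spreads are sample
standard deviations ($n-1$), which is what reproduces the published
values. Post-hoc contrasts are two-sided paired t tests with Bonferroni
correction (×3, capped at 1); the source report does not state its exact
post-hoc procedure, so only the ordering and significance pattern of its
printed p-values is meaningful, and that is what the tests assert.
Sphericity corrections and effect sizes are deliberately out of scope.

## The synthetic generator

`synthesize_session()` produces sessions with known ground truth. Per
channel the signal is a sum of independent components:

* approximately 1/f *pink background* (1.5 μV RMS): a three-stage
  one-pole filter cascade (corners at 1.5, 6, 24 Hz, variance-equalized)
  driven by white noise;
* *alpha* (6 μV RMS) and *beta* (5 μV RMS) band-limited Gaussian
  oscillations: complex baseband noise synthesized spectrally at a low
  rate, upsampled, and shifted onto the band-centre carrier;
* *sensor noise* (0.5 μV RMS, white; the same white process also drives
  the pink filter, making the broadband floor one jointly filtered noise
  process);
* the EOG channel instead carries large slow activity (15 μV RMS, < 5 Hz).

ERD is realized by multiplying the truth channels' band envelope by
$\sqrt{1-d}$ during the movement window of attempt trials, with 0.2 s
raised-cosine transitions placed immediately *outside* the window. Keeping
the transitions outside means the window-averaged band power is attenuated
by exactly $1-d$, so the generator calibrates: at depth 0.5 the measured
move/rest band-power ratio on a truth channel sits within a few percent of
0.5 (the residual offset is the in-band share of the background, ~1–3% by
the amplitude choices above — this is also why the oscillation amplitudes
are several times the background: with a weaker rhythm the depth parameter
would no longer mean what it says). At depths near 1 the background floor
and the shared 13 Hz alpha/beta band edge dominate the residual ratio, so
calibration claims are only meaningful at moderate depths.

Optional neighbor mixing (`spatial_mixing`) blends each channel with its
spatial neighbors to mimic volume conduction; it is off by default so that
ground-truth channels stay exactly where they were injected.

What the generator does **not** emulate: eye-blink and muscle artifacts,
line noise, non-stationary background power, realistic volume-conduction
topographies, or any phase-locked evoked response. Tests passing on this
synthetic data therefore demonstrate the correctness of the *pipeline
mechanics* (calibration, recovery, leakage-free decoding), not performance
on clinical EEG.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds: the generator seed
  fully determines a session (schedule and noise use fixed offsets of it),
  and the cross-validation seed determines fold assignment. Identical
  seeds give bit-identical sessions and reports.
* FFT lengths are rounded up to 2-3-5-smooth sizes; FIR filtering packs
  channel pairs into complex FFTs (exact for a real impulse response).
* Wavelet convolutions are zero-padded (linear, not circular); the
  outermost ~0.7 s of each epoch shows the resulting roll-off, which is
  one reason analysis windows avoid second 0–1. The moving window does
  reach the epoch end, where roll-off suppresses power equally across
  channels and classes, so rankings and comparisons are unaffected.
* Problem sizes in the test suite are chosen to keep the full run modest:
  stochastic property checks use 20 fixed seeds, sessions of 20+20 trials
  for recovery claims and 10+10 for the depth-monotonicity sweep, and a
  125 Hz analysis rate — each stated where used.

## Known limitations

* The artifact stage is a plain amplitude threshold; it is not a
  substitute for expert screening of clinical recordings.
* The topography-pattern rule reproduces a visual grouping; boundary cases
  (e.g. bilateral SM1 activity) land in "others" by design.
* The ERD ratio uses within-trial resting windows, while decoding uses
  blank-control trials as the rest class; both readings of the paradigm
  are implemented deliberately and should not be conflated.
* Only EDF-free, package-native session files are supported; no reader for
  vendor formats is included.
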