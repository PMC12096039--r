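---
title: "Encoding models for dyadic-dance EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models for dyadic-dance EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadtrf)
```

## The scientific problem

When two people dance together to music, their EEG simultaneously reflects
auditory tracking of the music, motor control of their own movements, visual
processing of the partner's movements, and — the interesting part — tracking
of the *social coordination* between the two bodies, all buried under ocular
and muscular artifacts that are orders of magnitude larger than the brain
signals. `dyadtrf` implements the encoding-model machinery that separates
these streams: multivariate temporal response functions (mTRFs) fitted by
lagged ridge regression, with unique contributions quantified by
full-versus-reduced model comparison, plus event-related potential (ERP)
analyses that anchor the recovered model weights in classical evoked
responses.

Because the method's correctness cannot be established on real recordings
(no ground truth), the package is organized around a synthetic dyad
simulator whose generating kernels are known, so every downstream stage is
testable end to end.

## The forward and inverse model

For channel $c$, the encoding model is

$$ y_c(t) = \sum_{j} \sum_{\ell = L_{\min}}^{L_{\max}} w_{j,\ell,c}\,
   x_j(t - \ell) + b_c + \varepsilon_c(t), $$

with regressors $x_j$ (spectral flux of the music, self and partner bounce
velocity magnitude, the coordination sign product, two EOG and two EMG
controls) and lags spanning $-250$ to $+300$ ms at 100 Hz (integer lags
$-25\ldots 30$, i.e. 56 lags; negative lags capture anticipatory activity).
The design matrix (`build_design`) holds one zero-padded lagged block per
regressor plus an unpenalized intercept column. Weights are estimated by
ridge regression, $(D^\top D + \lambda I^{*})\,w = D^\top y$, with the
identity zeroed at the intercept (`ridge_fit`); $\lambda = 0$ reduces to
least squares, with a minimum-norm fallback (and a warning) when the system
is singular.

$\lambda$ is selected per trial by leave-one-trial cross-validation over the
grid $\{0\} \cup \{10^k : k = -4 \ldots 8\}$ — the unregularized option plus
13 powers of ten — maximizing the mean-over-channels Pearson correlation on
the held-out trial, with ties broken toward smaller $\lambda$
(`select_lambda`). The participant- and condition-specific TRF is the
average of the $n$ leave-one-trial fold fits (`fit_subject_trf`). Prediction
accuracy uses the *generic* approach: a participant's trials are predicted
with the average of all other participants' subject TRFs, and Pearson $r$
per channel is computed on the trial-concatenated series
(`generic_predict`); per-trial averaging is a one-line change but
concatenation is the default.

The unique contribution of a regressor is
$\Delta r = r_{\text{full}} - r_{\text{reduced}}$, where the reduced model
omits that regressor's lag block (`trf_partition` recomputes $\lambda$ by
cross-validation independently for each model, reusing cached per-trial
cross-products so reduced models are column subsets, not refitted designs).
Body-part-specific models (16 marker speeds + neck EMG, five exclusion
sets) and the velocity-sign control model for coordination follow the same
machinery (`bodypart_models`, `coordination_control`).

## The synthetic dyad generator

`make_session` builds a full session: 2 participants, 4 blocks × (2 trials
× 4 conditions) = 32 trials of 40 s at 100 Hz on a 64-channel 10-10 layout,
under the 2 × 2 design *visual contact* (yes/no) × *musical input*
(same/different). These defaults are the study conditions; tests that need
smaller problems pass explicit smaller configs rather than changing them.

**Kernels.** Each regressor drives the EEG through a ground-truth kernel
(sum of 30-ms-FWHM Gaussian lobes) and a smooth scalp topography: music
peaks at +60/+120/+200 ms (frontal, an auditory P50–N100–P200 analogue);
self-movement at −100/0/+80 ms (bilateral central, a movement-related
cortical potential analogue); partner movement at +70/+160 ms (occipital,
a visual biological-motion response); coordination at −180/−90/+30/+160 ms
(occipital). EOG/EMG kernels are zero-lag near-impulses with amplitude 100×
the neural kernels — peripheral signals leak into EEG instantaneously and
dominate it by orders of magnitude; the factor 100 is a configurable
default, not an empirical claim.

**Condition gating.** The partner-movement kernel is silenced without
visual contact; the coordination kernel has gain 1 with vision + same
music, 0.25 with vision + different music, 0 without vision. The factors
0.25 and 0 are simulator defaults chosen to produce the qualitative
vision × music interaction; real effect sizes are unknowable from group
statistics, so they are config, not constants.

**Bounce dynamics.** Each dancer's bounce velocity is a near-sinusoid at
their own beat rate with Ornstein–Uhlenbeck phase jitter (sd 0.15 rad,
τ = 1 s). When partners can see each other, dancer B's phase is attracted
(strength κ = 1.5 rad/s) toward dancer A's phase plus a target offset.
With shared music the target alternates between 0 (in-phase) and π
(anti-phase) at seeded 2–6 s intervals — deliberate coordination play on a
common beat. With different music (tempos exactly 8.5% apart) the target
stays at 0: the pair entrains at a stable ~45° offset because the
attraction exceeds the detuning, and anti-phase episodes arise from phase
slips rather than deliberate switching. This gives the session its
characteristic structure: coordination-state alternation is richest with
vision + same music. Note that the *raw* sign product chatters briefly
whenever the two zero crossings are slightly offset — this is a property of
the sign product, not a bug — so sustained states are counted on a 0.5-s
smoothed product (`coordination_episode_count`).

**Full-body kinematics.** `make_fullbody` expands a bounce velocity into a
22-marker (66-dimensional) posture series as a sum of orthonormal movement
primitives: the bounce primitive (uniform vertical displacement, ~1% of
kinematic variance, matching its small share in real dance kinematics) plus
14 band-limited-noise primitives with geometrically decaying variance
(ratio 0.7), plus 4% isotropic sensor noise. With these defaults the first
15 principal movements explain ≥95% of the variance. Near-degenerate
variance levels are a real limitation of PCA: the bounce score is recovered
cleanly only when kinematics are pooled at study scale (the tests pool
~160 s), exactly as the real pipeline pools trials and participants.

**Noise.** Channel-independent 1/f (pink) noise scaled so that the ratio of
mean neural signal variance to noise variance equals `snr` (default 0.25);
artifact contributions ride on top and are excluded from the SNR reference.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: non-stationary artifacts (ASR/ICA stages are
exposed only as a preprocessing hook), the left–right anticorrelation of
horizontal saccades (the two EOG sources are independent), volume-conduction
correlations between channels beyond smooth topographies, biomechanical
realism beyond the primitive model, and real music acoustics (stimuli are
impulse trains and tone bursts).

## Feature extraction choices

* **Spectral flux**: 128 log-spaced 4th-order gammatone bands, 100–8000 Hz,
  applied in the frequency domain (the complex response
  $(1 + i(f - f_c)/b)^{-4}$, $b = 1.019\,\mathrm{ERB}(f_c)$, multiplied
  onto the analytic spectrum so each band's inverse FFT is its envelope);
  per band the envelope derivative is half-wave rectified (config switch
  `rectify` for the signed variant), averaged across bands, resampled to
  100 Hz.
* **Resampling** (`resample_trim`) is Fourier-domain with reflection
  padding: exact for band-limited signals. The installed polyphase
  resampler showed ~5% passband ripple at 1000→100 Hz, which would have
  violated the sub-1% fidelity this pipeline needs.
* **Coordination sign product**: exact zeros inherit the previous nonzero
  sign (+1 at the start) so the series stays in {−1, +1}; velocities are
  continuous so zeros are measure-zero and any consistent rule is fine.
* **Standardization** divides each series by its participant-level SD
  pooled across trials; means are untouched.
* **PCA movements**: mean-centred `prcomp` on pooled postures, scores
  low-passed below 6 Hz (Butterworth order 2, zero-phase). No per-marker
  rescaling is applied before PCA; this is a documented deviation knob
  (`pca_movements` operates on whatever posture matrix it is given).

## Preprocessing interpretations

The cleaning criteria are stated rules, but two details are left to the
implementation by the tools they reference:

* *Interchannel correlation < 0.8*: computed as the maximum absolute
  correlation with any other channel in 5-s windows of the 1–8 Hz data,
  median across windows. This is a documented stand-in for the internal
  windowing of the referenced cleaning tools.
* *Flatline epsilon*: successive differences below $10^{-8}$ of the channel
  SD count as flat.

Amplitude outliers use plain (non-robust) z-scores of mean/SD/peak-to-peak
against the scalp distribution, per the "3 SD from the scalp average"
phrasing; note that with very few channels a 3-SD outlier is arithmetically
impossible, so the criterion is meaningful only on dense montages.
Interpolation replaces a bad channel by the mean of good channels within
20 mm, widening to the nearest good channel with a warning when the
neighborhood is empty (on an idealized spherical 10-10 layout, 20 mm is
below the typical inter-electrode distance, so the widening path is
common — the radius is a parameter).

## ERP analyses

Onsets are interior local maxima (plateaus keep their first sample);
acoustic onsets additionally require amplitude > mean + 3 SD of the trial.
Epochs span the TRF lag window (−250..300 ms). Externally evoked epochs
(music, partner movement) are baseline-corrected by the prestimulus mean
(−250..0 ms); internally initiated epochs (self movement, coordination) by
the whole-epoch mean. Intensity contrasts use the ≤20% and ≥80% amplitude
quantiles. Coordination transitions are sign flips of the coordination
series, labelled `to_inphase`/`to_antiphase` by the post-flip value and
attributed to self/other when the respective velocity changes sign within
±1 sample (10 ms) of the flip; flips matching both dancers are labelled
`both` and excluded from self/other contrasts.

The cluster-based permutation test is single-channel over time: paired t
per time point across participants, clusters formed at two-sided pointwise
p < 0.05 (df n−1) with sign coherence, cluster mass = summed t, null = max
|mass| over sign flips of participant-wise differences, corrected
p = (1 + #{null ≥ observed})/(1 + n_perm), n_perm = 1000 by default.
Events are aggregated to per-participant means before the group test
(standard two-stage ERP statistics).

A note on calibration: the run-level permutation p-value has a discrete
atom at p = 1 (runs with no suprathreshold cluster). For temporally white
epochs that atom is small (~6% for 56 time points) and the p distribution
is uniform to within Kolmogorov–Smirnov tolerance; for strongly
autocorrelated epochs the atom grows and *any* correct implementation of
this statistic departs from exact uniformity. The null-calibration tests
therefore use white epochs, which is the standard way to check the
statistic's error control.

### A note on the sign of Δr for irrelevant regressors

Full-versus-reduced generic prediction is not an unbiased estimator of
"no contribution": the weights a truly irrelevant regressor acquires in the
generic TRF are pure estimation noise, and adding noise to a prediction
always costs a little accuracy, so the expected Δr of a gated-off
regressor is slightly *negative* (with added-noise variance fraction
$\delta$ and baseline accuracy $r_0$, roughly $-r_0\,\delta/2$ — and
$r_0$ is close to 1 here because the artifact regressors explain most of
the EEG). The bias shrinks with training samples and with the number of
participants averaged into the generic model, and at full study scale it
is negligible against the gated-on effects; but it never becomes
*statistically* zero against a standard error computed over simulation
seeds, because the seed-level spread of a channel- and
participant-averaged summary shrinks faster than the bias does. The
specificity tests therefore show gated-on contributions several standard
errors above zero while the gated-off means sit a few (very small)
standard errors below it. Interpreting tiny negative Δr values as "no
contribution" — rather than as evidence of suppression — is the correct
reading in real analyses too.

## Condition statistics

Relevant electrodes per regressor are those with a positive grand-average
Δr across participants and the conditions where the process is expected
(all four conditions for music and self; the two vision conditions for
other and coordination); the grand-average reading of "exhibited a
prediction gain" was chosen over per-participant selection as the more
natural group-level interpretation. Electrode-averaged Δr values enter a
2 × 2 repeated-measures ANOVA computed from within-subject contrasts (each
effect F with df (1, n−1) equals the squared paired t on its contrast —
verified against `aov` in the tests), Bonferroni-corrected ×4 across the
regressor family. After a significant interaction, follow-ups are paired
music contrasts within each vision level (Δ, SE, p) with no further
correction beyond the family ×4. No sphericity correction is needed:
all effects have one numerator df.

## Reading peak latencies off recovered TRFs

A "deflection" of a recovered waveform is an interior local extremum whose
absolute value is at least 30% of the waveform's maximum absolute value.
The floor makes "first/last peak" well defined in the presence of
estimation noise (residual wiggles at study SNR sit near 10–25% of the main
response); genuine preset lobes all have equal unit amplitude, so 30% is
far from discarding a real deflection.

## Problem sizes and runtime choices

The kernel-recovery analyses use 10 dyads (20 participants) at the default
session size — enough for grand-average TRFs to resolve every preset lobe,
and chosen so a full recovery run completes in minutes on one core. The
specificity (gating) checks use 20 seeded two-dyad cohorts at 30 s × 16
trials; the null calibrations use 200 runs of 12 synthetic participants.
Efficiency rests on sufficient statistics: per-trial cross-products
($D^\top D$, $D^\top y$, column sums) are cached once, reduced models are
column subsets of them, and prediction accuracy is computed directly from
the cached moments ($\sum \hat y y = \mathrm{diag}(w^\top D^\top y)$ and
so on), so neither the λ search nor the generic predictions ever form a
predicted time series.

## Known limitations

* The dancers' true coupling dynamics are unknown; the phase-reset model is
  a stand-in for generating both coordination states, not a behavioral
  claim.
* ASR and ICA-based artifact removal are hooks, not implementations; the
  simulator's artifacts are stationary and fully regressable, which real
  muscle artifacts are not.
* The spherical layout is geometric, not digitized; distances are a few mm
  off published tables, which matters only for the interpolation radius.
* EDF support is minimal (plain EDF, 16-bit, one record per second), meant
  for interoperability tests and small exports.
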