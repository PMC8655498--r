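---
title: "Quantifying visual-flow-perturbation responses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying visual-flow-perturbation responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pertflow)
```

## The scientific problem

Neurons in mouse primary visual cortex (V1) respond not only to visual
features but also to violations of expected visual flow. When a drifting
grating suddenly halts for about a second (a visual-flow *perturbation*,
temporal frequency driven to 0 while contrast stays up), a large fraction
of V1 units reliably change their firing rate, and those responses are
often stronger when the animal is running. Such responses are candidate
*mismatch signals* — the difference between self-motion-predicted and
actual visual flow — but they could also be explained by ordinary
stimulus tuning (many units simply prefer static or slowly drifting
gratings).

`pertflow` implements the complete analysis chain needed to ask these
questions of extracellular recordings: reliability classification of
perturbation responses against a permutation null, modulation indices,
running-state bootstrap comparisons, orientation/direction and
temporal-frequency tuning, behavioral controls, and waveform-based cell
typing. Because the recordings this kind of study uses are not publicly
deposited, the package also contains a first-class synthetic session
generator that produces data with known ground truth and the statistical
structure the analyses assume; every stage is validated by parameter
recovery on those sessions.

## The stimulus protocol

A session is a sequence of ~7.33-s trials (440 frames at 60 Hz) of a
drifting sinusoidal grating (spatial frequency 0.04 cycles/degree,
temporal frequency 3 cycles/s, one of 8 directions at 45-degree spacing).
Contrast ramps 0 to 0.8 over the first 240 frames, holds for 100, and
falls back to 0 over the last 100. A random 25% of trials carry the
perturbation: 30-40 frames after the contrast plateau is reached the
temporal frequency is set to 0 for 60-70 frames. Inter-trial intervals
are uniform on 1-2.5 s, and a small number of zero-contrast trials
(8 by default) plus the inter-trial intervals define the baseline epoch.

Conventions: frames are 0-based at 60 frames/s; all intervals are
half-open `[start, end)` in session-clock seconds. This removes any
double-counting at epoch boundaries (the pre-perturbation second abuts
the perturbation window exactly).

Non-perturbation trials are given a *virtual* perturbation window drawn
from the same onset/duration distribution, so the trial classifier sees
identically constructed feature windows for both trial classes. The
alternative (a fixed frame position) would make the virtual windows
slightly more regular than the real ones; matched random positions avoid
that asymmetry.

A separate accelerating-grating protocol measures temporal-frequency
(TF) tuning: trials start at 1.5, 3 or 6 cycles/s, accelerate at one of
-3..3 cycles/s^2 for 0.5 or 1 s, and hold the resulting plateau TF for
1.5-2 s; the 21 (initial TF, acceleration) combinations are each shown
20 times. Plateau TFs are clamped at 0: within this protocol's stated TF
range a grating cannot drift at a negative rate, and a drift-direction
reversal is never produced by the combinations that reach 0
(only 1.5 - 3x1 and 1.5 - 3x0.5 undershoot). Off-grid plateau TFs from
0.5-s accelerations are binned to the nearest 0.5-cycles/s grid value.

## Firing-rate traces

Spike times are binned at 60 Hz (one bin per stimulus frame) and
smoothed with a Gaussian kernel of full width at half maximum 300 ms
(sigma about 127 ms, truncated at 4 sigma). A "300-ms Gaussian filter" is
a width statement, and FWHM is the most common single-number width
convention; the width is a parameter of `smooth_rate()` if a different
convention is preferred. Edges are handled by renormalizing the kernel
over its valid support rather than zero-padding, so rates near trial
starts are not biased downward.

Two versions of each trace are used deliberately:

* the **smoothed, session-max-normalized** trace feeds the trial
  classifier and the condition-averaged running-state comparisons
  (normalization by each unit's session-wide maximum makes the six
  features commensurable across units);
* **unsmoothed** binned rates are used for all window-mean statistics
  (the unit-level modulation index, tuning responses, per-trial MIs).
  A window mean over a fixed 1-s window needs no smoothing, and the
  Gaussian blur would leak rate across the perturbation onset/offset
  edges — about 9% of the step for a 1-s window at FWHM 300 ms — which
  measurably shrinks the modulation-index estimate. With raw windows the
  MI estimator recovers simulated ground truth to within a few
  hundredths.

## Perturbation-response classification

For every grating trial, six features are computed from the normalized
trace over the trial's (real or virtual) perturbation window and the
preceding second: the ratio and difference of the two window means, the
summed rate over both windows, the summed perturbation-window rate, the
depth of modulation DM = (Rpert - Rpre)/(Rpert + Rpre), and the
modulation index MI = (Rpert - Rpre)/Rpre. A logistic regression
(maximum likelihood, IRLS) is fit on all trials to predict the trial
label, and the in-sample ROC-AUC of its fitted probabilities is the
unit's reliability statistic. The trial labels are then shuffled (1000
times by default), the classifier refit each time, and the unit is
*perturbation-responsive* when its AUC exceeds the 95th percentile
(linear-interpolation quantile, strict inequality) of the shuffle null.

Fitting and evaluating in-sample inflates the AUC above 0.5, but the
null is constructed with the identical in-sample procedure, so the
optimism cancels in the comparison; simulations with null cohorts show
the rule flags very close to 5% of unmodulated units. Features are
z-scored before fitting (they span orders of magnitude; AUC is invariant
to this for a monotone model). Complete separation is tolerated by the
capped-iteration fit and flagged. A rate floor of epsilon = 0.1 spikes/s
(pre-normalization scale) guards the MI and ratio denominators; it is a
visible argument everywhere it is used.

The unit-level MI that determines the sign of a responsive unit is
computed from across-trial *mean* rates of the perturbation trials
(perturbation window vs preceding second), not as a mean of per-trial
MIs; per-trial MIs are retained separately for the behavioral
correlation analysis, which is explicitly trial-by-trial.

## Running-state analysis

A perturbation trial is a *running* trial when the mean speed over the
pre-perturbation second plus the perturbation period is at least 2 cm/s;
the boundary value counts as running, and the reducer (mean by default)
is configurable because a bare speed threshold does not by itself fix
whether it applies to the mean, minimum or every sample of the window. Sessions with
fewer than 4 trials in either state are excluded from this analysis.

Per state, the trials' normalized traces are aligned at perturbation
onset and averaged; because perturbation durations vary (60-70 frames),
the averaged window is truncated to the minimum duration across the
session's perturbation trials. The summed-rate modulation is the sum of
the averaged trace over the perturbation window minus the sum over the
preceding second. Significance uses a bootstrap: 20 trials per state
drawn with replacement, averaged, and the peak and the mean of the
averaged trace over the perturbation window compared between states; a
unit is significantly running-enhanced when running exceeds stationary
on *both* statistics in at least 95% of draws (950/1000). Both
statistics are computed on the condition-averaged trace. A unit is
*mismatch-like* when it is reliably positively modulated and its
running-state modulation is at least twice the stationary one, the
stationary value clipped at 0 to avoid sign pathologies.

## Tuning analyses

Grating responses are the mean rate over the first 3.5 s of each trial
minus the baseline rate (inter-trial intervals plus zero-contrast
trials). The 3.5-s window is a parameter; reports elsewhere sometimes
use 0-4 s, and the choice is visible in `unit_tuning()`. Orientation and
direction selectivity are the normalized lengths of the response-weighted
vector sums on doubled and plain angles respectively; responses are
rectified at 0 first so the lengths stay in [0, 1] (negative weights
would make a "normalized length" uninterpretable; rectification is the
standard convention). Orientation-tuning significance uses a one-sample
Hotelling's T-squared test on the per-trial vectors
(r cos 2 theta, r sin 2 theta) against mean (0,0), with the exact F
transform; direction significance uses a one-sided t-test of the
per-trial projections onto the preferred direction against those onto
the opposite direction ("direction dot-product" test). Both use a 0.01
significance level. These constructions follow the cited methodology
but are this package's own concrete realizations of the trial-vector
space; both are null-calibrated in the test suite.

Perturbation responses per direction use the perturbation-window mean
minus baseline. Because only ~5 perturbation trials exist per direction,
preferences are taken as the angle of maximal response (orientations
fold the two opposite directions together), with argmax ties broken
deterministically toward the lowest angle and flagged. `delta_ori` is
the absolute difference between the perturbation-preferred and
grating-preferred orientation, folded to [0, 90] degrees.

TF tuning uses the mean rate over the final second of each
accelerating-grating trial's plateau, grouped by plateau TF on the
0-8.5 cycles/s grid; the preferred TF is the grid value with maximal
response (ties toward the lowest TF, flagged).

## The synthetic session generator

Each unit's instantaneous rate is

    lambda(t) = baseline + contrast(t) x ori(direction) x tf(TF(t)) x gain(t)

with the contrast drive normalized to its 0.8 plateau (so `evoked_rate`
is the plateau evoked rate at the preferred stimulus), von Mises
orientation tuning on doubled angles times a direction-asymmetry factor
(equal to 1 at the preferred direction and `direction_ratio` at the
opposite one — the minimal parametric family that realizes both
orientation and direction selectivity), log-Gaussian TF tuning on the
octave scale, and a multiplicative locomotion gain on the evoked drive
whenever speed >= 2 cm/s. TF = 0 (a static grating) is mapped half an
octave below the lowest tested nonzero TF (0.5 cycles/s) so that "prefers
static gratings" is expressible as a valid tuning argument. During a
perturbation epoch the rate steps to

    lambda_pre x (1 + MI x ori(direction) x running_pert_gain(t))

where `lambda_pre` is the unit's mean rate over the preceding second, so
the expected modulation index at the preferred orientation of a
stationary animal equals the unit's ground-truth `perturbation_mi`
exactly, the response follows the unit's orientation preference, and
running multiplies it by `running_pert_gain`. A step change matches the
sustained ~1-s responses this paradigm elicits. Rates are clipped at 0.

Spikes are drawn as an inhomogeneous Poisson process by thinning.
Poisson spiking (no refractoriness) is the simplest noise model
consistent with every statistic the pipeline tests; an absolute
refractory option exists but is off by default (it slightly deflates
rates, which would bias the MI recovery checks). The running trace
alternates exponentially distributed stationary and running bouts
(default mean 20 s each — conventional values for head-fixed mice on a
wheel), with gamma
running-bout speeds above the 2 cm/s threshold, jitter, and a 0.5-s
box smoothing; defaults give at least 4 running and 4 stationary
perturbation trials in ~95% of sessions. Cohort defaults: log-normal
baseline (median 5 spikes/s) and evoked (median 8 spikes/s) rates,
uniform preferred orientations, gamma orientation concentration, a
bimodal low/high preferred-TF mixture, a mixture of positively (35%),
negatively (30%) and un-modulated units, and a running perturbation
gain of median 2. When `couple_tf_mi` is on (the default,
"coupled" condition), positively modulated units draw their
preferred TF from the low mode and negatively modulated ones from the
high mode, which is the structure the TF-preference analysis is meant
to detect.

What the generator deliberately does **not** emulate: spike-sorting
artifacts, bursting and refractory structure, slow drift and
non-stationarity, correlated noise across units, eye movements, and any
closed-loop coupling of the stimulus to running. Passing tests therefore
show that the *statistics are implemented correctly and are calibrated
under the assumed model*, not that real V1 data satisfy that model.

## Numerical choices and degenerate inputs

* Epoch windows are half-open and frame-aligned; window means use bins
  whose left edge lies in the window.
* Quantiles of the shuffle null use R's default linear interpolation
  (type 7); "greater than 95%" is a strict inequality.
* Argmax ties (preferred angle, preferred TF) break toward the lowest
  value and are flagged rather than randomized, keeping reports
  deterministic.
* Silent units (zero session maximum) are flagged and left at zero by
  the normalization; zero-rate MI is 0 by convention; singular
  covariance in Hotelling's test yields p = 1 (or p = 0 when the mean is
  nonzero along the degenerate axis) with a degeneracy flag.
* Waveform clustering uses a deterministic farthest-point initialization
  for the 2-means step, and waveforms are resampled to a common 30-kHz
  grid, aligned at the trough and normalized to trough depth 1 before
  PCA — the preprocessing that makes the partition depend on waveform
  shape, not amplitude.

## Problem sizes used in the checks

The automated checks run the full machinery at sizes chosen to give
tight Monte-Carlo error while staying fast on a single core: null
calibration uses 440 null units at 200 shuffles (the 5% +/- 2%
acceptance band is ~7 Monte-Carlo standard errors wide at that n; the
full 1000-shuffle variant is the same code with `n_shuffles = 1000`),
MI recovery uses 30 units at baseline 10 spikes/s with 40 perturbation
trials each, orientation recovery 30 units at kappa 2.5, TF recovery 20
high-SNR units on a 420-trial protocol, the population-level checks one
100-unit cohort, and the running-gain and bootstrap-specificity checks
120-unit cohorts with 200 bootstrap draws (threshold ceiling(0.95 x
n_boot)).

## Known limitations

* The in-sample AUC is not an out-of-sample decoding accuracy; it is
  only meaningful relative to its matched shuffle null.
* The Eq.-based modulation statistic for running comparisons sums
  unequal-length windows when perturbation durations differ; we truncate
  aligned averages to the common minimum duration, which discards up to
  10 frames of the longest perturbations.
* With ~5 perturbation trials per direction, perturbation-preferred
  angles are max-based and noisy; `delta_ori` is best interpreted at the
  population level (against a shuffled pairing), which is how the
  acceptance checks use it.
* The behavioral analysis treats speed like a rate trace; its MI floor
  (0.5 cm/s) is on a different physical scale than the neural floor and
  both are configurable.
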