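# pertflow

Analysis of neural responses to visual-flow perturbations in
extracellular recordings from mouse primary visual cortex (V1), with a
ground-truth synthetic session generator for validating every stage.

## The problem

Head-fixed mice on a running wheel view full-field drifting gratings
(~7.33-s trials, 8 directions, contrast ramping to 0.8). In a random 25%
of trials the grating suddenly halts for about one second (temporal
frequency driven to 0 — a *visual-flow perturbation*) while contrast
stays up. Many V1 units respond reliably to this halt, and responses are
often larger during locomotion — the signature expected of *visuomotor
mismatch* signals, but also compatible with ordinary stimulus tuning if
a unit simply prefers static or slow gratings. `pertflow` implements the
full analysis chain a lab would run on such recordings:

* **Perturbation reliability** — six windowed features per trial (rate
  ratio, difference, window sums, and the two indices below) feed an
  in-sample logistic trial classifier; the ROC-AUC is compared against a
  1000-fold label-shuffle null, and a unit is *perturbation-responsive*
  when its AUC exceeds the null's 95th percentile.
* **Modulation indices** — depth of modulation
  `DM = (R_pert − R_pre) / (R_pert + R_pre)` and modulation index
  `MI = (R_pert − R_pre) / R_pre`, where `R_pert` and `R_pre` are mean
  rates in the perturbation window and the preceding second.
* **Running-state comparison** — perturbation trials split at 2 cm/s
  (mean speed over the pre+perturbation window); per state the
  summed-rate modulation `Σ R̄(t)` over the perturbation window minus the
  preceding second; significance by a 20-trial, 1000-draw bootstrap
  requiring the running state to win on both the peak and the mean in
  ≥ 950/1000 draws. Units that are positively modulated and at least
  twice as strong when running are flagged *mismatch-like*.
* **Tuning** — vector-sum selectivity
  `L_ori = |Σ_k R(θ_k) e^{2iθ_k}| / Σ_k R(θ_k)` (and `L_dir` with
  un-doubled angles), Hotelling's T² and a direction dot-product test
  for significance; perturbation-response tuning by maximal response
  with `ΔOri` folded to [0°, 90°]; temporal-frequency tuning from an
  accelerating-grating protocol (21 initial-TF × acceleration
  combinations, preferred TF by maximal plateau response).
* **Behavioral control** — the same classifier machinery applied to the
  running-speed trace, and per-unit Pearson correlation between
  trial-by-trial neural and speed MIs.
* **Waveform typing** — trough-to-peak duration and PCA + 2-means
  clustering into putative regular- and fast-spiking units.

Because recordings of this kind are not publicly deposited, the package
ships a first-class synthetic session generator (`generate_session()`):
inhomogeneous-Poisson units with von-Mises orientation tuning,
log-Gaussian TF tuning, a target perturbation MI realized exactly in the
rate model, locomotion gains, a bout-structured running trace and
class-templated waveforms — with the ground truth returned as a separate
sidecar so parameter recovery can be tested end to end.

## Worked example

The `analysis/` directory is a numbered workflow over the package
functions. `analysis/01_simulate.R` builds the study session,
`02`–`05` run the stages, `06` produces the cohort report:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_perturbation_detection.R
```

```
session: 40 units, 1530 s
grating trials: 160 (40 perturbation, 25%), blank trials: 8
perturbation trials by state: 19 running, 21 stationary

reliable (perturbation-responsive): 13/40 units (32%)
  positively modulated: 6, negatively modulated: 7
detection rate by ground-truth modulation:
(-0.01,0.01]   (0.01,0.5]      (0.5,1]      (1,Inf]
   0.0000000    0.4000000    0.5000000    0.6666667
```

Units simulated with no perturbation response (|MI| ≤ 0.01) are never
flagged, and detection rises with the simulated effect size. The later
stages print, for the same session:

```
significantly running-enhanced: 6/40 units
mismatch-like (positive, >= 2x stronger when running): 4/40
median preferred TF: positive-MI 0.25 vs negative-MI 5.50 cycles/s
speed-change classifier: AUC 0.622 (null p95 0.677) -> no reliable speed changes
waveform typing: 28 regular, 12 fast (3 PCs explain 94% variance)
```

i.e. positively modulated units prefer near-static gratings while
negatively modulated ones prefer fast drift, the running-speed trace
itself carries no reliable perturbation signal, and waveform typing
recovers the generator's classes. Per-unit tables land in `results/`.

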