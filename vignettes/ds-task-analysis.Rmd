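---
title: "Analyzing cue-evoked spiking in DS reward tasks with cuephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing cue-evoked spiking in DS reward tasks with cuephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuephys)
```

`cuephys` analyzes extracellular recordings from discriminative-stimulus
(DS) reward tasks: on each trial a tone announces either a rewarded (DS+)
or an unrewarded (DS−) lever that extends 3 s after tone onset; sessions
contain 50 trials of each type in pseudorandom order with a 30 s
intertrial interval. This vignette documents the model behind each stage,
the tunable parameters and their defaults, the numerical conventions, and
what the simulator-based tests do and do not establish.

## Alignment and z-scoring

All analyses run on a fixed peri-event grid: 100 half-open 50 ms bins
from −1 to +4 s around cue onset (`bin_grid()`), so cue onset is the left
edge of bin 21 and the lever appears at the left edge of bin 81. Spike
counts are tabulated per trial and bin (`align_and_bin()`); rates are
counts divided by the bin width.

Responsiveness works on the trial-averaged rate trace of one unit and cue
type. The trace is normalized as a z-score against its own baseline:
\(z_b = (r_b - \mu)/\sigma\), with \(\mu\) and \(\sigma\) taken over the
baseline bins *of the trial-averaged trace*. Two conventions required a
decision:

* **Reference window** (`z_mode`). The classification criterion is
  explicitly baseline-relative, so the default references \(\mu,\sigma\)
  to the epoch's baseline bins; `z_mode = "full_trace"` normalizes
  against all 100 bins instead for users who prefer a whole-trace
  z-score.
* **SD convention** (`sd_type`). Population SD (divide by \(n\)) is the
  default; the sample-SD alternative is a config flag. Over 20 baseline
  bins the two differ by 2.6%, well below any decision threshold in
  practice, but the choice is fixed and documented.

A flat baseline (\(\sigma = 0\), e.g. a silent unit) makes the z-score
undefined; such units are flagged *degenerate*, excluded from
classification, and counted as non-responsive in proportion tables.

## Epochs and the sliding-window criterion

Three epochs are analyzed relative to cue onset: the rapid tone response
(0–0.4 s), the sustained tone response (0.5–3 s), and the lever response
(3–3.4 s). The first two use the pre-cue baseline (−1–0 s); the lever
epoch is re-referenced to the late-tone window (2–3 s), so a unit already
elevated throughout the tone is not re-counted as lever-responsive unless
its rate changes again at lever onset.

The z trace is scanned with 200 ms windows (4 bins) advancing in 50 ms
steps. Only windows lying entirely inside an epoch count toward it — 5
windows for the rapid-tone and lever epochs, 47 for the sustained epoch —
which prevents a response from leaking across epoch boundaries. A unit is
*activated* if at least `m` windows have mean z above 2 (`m` = 1, 6, 1
for the three epochs; the long sustained epoch demands a sustained
elevation, not a single excursion), *inhibited* symmetrically below −2.
When both criteria fire, the direction with more significant windows
wins; an exact tie is labelled *ambiguous* and counted in neither
column — the underlying data cannot distinguish the two readings, and
conflating them with either direction would bias the proportion tables.

## Cell typing

VTA units are typed from basal rate (mean −1–0 s rate over all trials)
and action-potential waveform duration: putative dopamine (DA) units have
rate < 12 Hz and a wide waveform. The duration criterion's direction is
configurable (`da_duration_rule`): the default `"ge"` labels ≥ 1.2 ms
waveforms DA, matching the optogenetically tagged DA phenotype in this
literature (DA neurons have wide spikes); `"lt"` provides the opposite
convention. Units without a measured waveform — including all dmPFC
units — stay untyped.

## auROC selectivity

Per-bin DS+/DS− discrimination is the area under the ROC curve computed
as the normalized Mann–Whitney pair statistic with 0.5 credit for ties;
this equals threshold-sweep ROC integration exactly and is invariant
under strictly increasing rate transforms. A unit is *selective* in an
epoch when its epoch-mean auROC deviates from the baseline-bin mean by
more than 2 baseline-bin SDs — the same normalization logic as the
z-score criterion, applied to the auROC trace (the lever epoch again uses
the 2–3 s baseline). An alternative null for the proportion of selective
units comes from shuffling the DS+/DS− labels across trials (class sizes
preserved) and re-running the whole selectivity pipeline 10 times; the
observed count is compared with the mean shuffled count by chi-square, or
Fisher's exact test when any cell is below 5.

## Population decoding

Each trial contributes one row of 100 features: the per-bin population
average of the session's simultaneously recorded units, each unit
normalized by its own single-trial baseline z (so high-rate units do not
dominate; `normalization = "raw"` disables this). Rows are stacked across
animals of one (area, group, session) cell; labels are 1 for DS+, 0 for
DS−.

One decoding repeat draws a stratified 80/20 train/test split,
standardizes features on the training split only, and fits an
L1-penalized logistic regression over a 30-value log-spaced penalty path.
The penalty is chosen by stratified 5-fold cross-validated accuracy
within the training set with the **one-SE rule**: the strongest penalty
whose CV accuracy is within one fold-SE of the maximum. On a noisy CV
curve a strict argmax essentially never ties, so "break ties toward the
stronger penalty" is only meaningful with a tolerance; the one-SE rule is
the standard formalization and drives label-permuted data to the
intercept-only model. The model is refit on the full training set at the
chosen penalty; held-out accuracy and the nonzero-coefficient features
are recorded. This repeats 100 times with seeds derived from the master
seed.

Per-epoch accuracies (`accuracy_mode`) deserve care:

* `"epoch"` (default): the repeated LASSO is run again with features
  restricted to the epoch's bins (tone: bins 21–80; lever: 81–100), and
  those decoders' held-out accuracies are reported, along with the 10
  most frequently selected features per mask. All selection happens
  inside training splits, so the procedure is unbiased: on label-permuted
  data it decodes at 50%.
* `"top_k_refit"`: a plain logistic model on the 10 features most
  frequently selected *across all repeats* is refit per repeat. Because
  the frequency tally has seen every split, this estimate is
  optimistically biased under the null (we measure 59–69% "accuracy" on
  pure noise, the selection bias of the top order statistics of ~60
  chance correlations); it is retained for comparison with analyses that
  used it, not for inference.
* `"global"`: the unrestricted model's accuracy, identical for both
  epochs.

Group comparisons use the independent two-sample t (pooled variance,
df = 2·100 − 2 = 198) on per-repeat accuracies, with Cohen's d. Repeats
share one dataset, so these t values measure separation of the two
repeat distributions, not independent-sample evidence — the convention of
the analyses this package mirrors.

## Group statistics

Pearson chi-square is computed without continuity correction; with
correction the worked contingency examples in the test suite do not
reproduce. Fisher's exact test covers small counts (n < 5). The phi
effect size is \(\sqrt{\chi^2/D}\) with two denominators: the standard
total N, and the *responsive-unit* count (all counts outside the
non-responsive column), which is the convention required to reproduce the
published effect sizes this package's examples check against
(\(\sqrt{11.95/20} = 0.77\)); the latter is the default, both are
available. t tests come in independent (pooled), Welch (Satterthwaite
df) and paired flavors with Cohen's d (pooled SD, or mean-difference SD
when paired). Zero-variance comparisons of identical samples return
t = 0, d = 0 rather than an error.

## The session simulator

`simulate_session()` generates the test bed: inhomogeneous-Poisson units
whose rate is a baseline multiplied by an epoch- and cue-dependent gain,
constant within each epoch. Defaults encode the study conditions the
package is calibrated to:

* trial structure: 50 DS+ + 50 DS− trials, pseudorandom with at most 3
  consecutive same-cue trials, 3 s tone-to-lever, 30 s ITI; press
  latencies ~0.9 s (DS+) and ~3.8 s (DS−) with omission probabilities
  0.035 and 0.73;
* baseline rates: lognormal with mean 6 Hz (dmPFC); VTA is a 75/25
  DA/non-DA mixture with means 3.8 and 6.4 Hz and a bimodal waveform
  mixture (1.5 vs 0.8 ms);
* responsive fractions per epoch (DS+ trials): the control preset uses
  the observed control proportions of each area (dmPFC 10/13/11%
  activated for rapid tone/sustained tone/lever; VTA 34/22/84%);
* gains: activated units multiply their baseline by 2.5 (with 10%
  lognormal jitter), inhibited units drop to 0.2; DS− gains are
  attenuated per epoch (`ds_contrast`), strongly for the sustained and
  lever epochs and barely for the rapid tone, mirroring the observed
  DS+/DS− proportion patterns;
* presets: `isd_day1` lowers dmPFC fractions/gains and raises VTA ones;
  `isd_day15` lowers both, VTA strongly. The day-15 dmPFC preset was
  calibrated so the simulated sustained-tone population effect matches
  the reported effect size for that comparison (Cohen's d ≈ 0.27); day-15
  responsive fractions are otherwise not published, so they are the
  package's own choice.

Two deliberate simplifications: spikes are generated only within a
padded −1.5…+4.5 s peri-trial window (the event schedule still honors the
30 s ITI; no analysis stage reads outside the window), and gains switch
instantaneously at epoch edges with no refractory period — the analyses
operate on 50 ms counts, so sub-bin structure is irrelevant to what is
tested. Units are statistically independent given their gains; real
populations carry correlated noise, so passing parameter-recovery tests
here shows the pipeline recovers planted effects under independence, not
that it is robust to correlated variability. Likewise the Poisson
assumption understates the dispersion of real spike counts; thresholds
that calibrate exactly here may be slightly liberal on overdispersed
data.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; `simulate_cohort()`
derives per-animal seeds from a master seed, `repeated_decoding()`
derives per-repeat seeds, and `run_pipeline()` fans one seed out to all
stages, making end-to-end runs bit-reproducible. The test suite exercises
the pipeline at deliberately modest sizes — cohorts of 2–7 animals with
6–15 units each, decoders with 15–100 repeats, 10-replicate directional
suites — chosen so the whole suite runs comfortably on a laptop while
keeping each test's statistical power explicit in its tolerances
(binomial CIs, 3-SE bands). The directional preset checks use the study
scale itself (7 dmPFC / 6 VTA animals per group).

## Known limitations

* The pipeline analyzes one session bundle at a time and assumes cue
  onsets are spaced further apart than the 5 s analysis window.
* Omission trials are retained in neural averages by default
  (`include_omissions`); excluding them is a config switch, and with the
  default DS− omission rate exclusion would thin DS− trials
  considerably.
* The ambiguous (tied activated/inhibited) label is this package's
  convention; published tables that force every responsive unit into one
  column may differ by a unit or two.
* The `top_k_refit` accuracy mode is biased under the null, as measured
  and documented above; it exists for comparability only.
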