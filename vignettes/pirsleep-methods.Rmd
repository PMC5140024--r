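---
title: "Scoring sleep and circadian rhythms from passive-infrared home-cage data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep and circadian rhythms from passive-infrared home-cage data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirsleep)
```

## The measurement problem

A passive-infrared (PIR) motion sensor mounted over a singly housed mouse
cage is polled every 100 ms; the fraction of polls that trip within a fixed
10-s epoch gives a percent-activation value, stored with an ISO8601 UTC
timestamp alongside one reading from a light-dependent resistor (LDR).
Such traces are cheap, small, and can run for months, which makes them
attractive for longitudinal phenotyping of two coupled but distinct
processes: the circadian rhythm of locomotor activity, and sleep.

Sleep cannot be observed directly without EEG/EMG, but in mice extended
behavioural immobility is a well-validated proxy: any period of at least
40 s with zero detected movement is scored as sleep. `pirsleep` implements
this scoring, the standard circadian statistics applied to such traces, the
method-agreement analysis used to validate the proxy against EEG-scored
hypnograms, and a behavioural simulator that generates PIR traces and
matched hypnograms with shared ground truth.

## Immobility-defined sleep

With 10-s epochs the 40-s criterion is four consecutive zero-activity
epochs. Two conventions exist and differ in a way worth being explicit
about:

* **run mode** (default): every epoch inside a maximal zero-activity run of
  length >= 4 is asleep. A 60-s immobile period contributes 60 s of sleep.
  This matches how video-based immobility scoring treats a qualifying
  immobile period.
* **window mode**: epoch *i* is asleep iff the rolling window of 4 epochs
  ending at *i* is all zero — the literal one-line spreadsheet rule
  (`IF(SUM(last 4 bins)=0,1,0)`). The first three epochs of each immobile
  run can never complete a window, so each qualifying run scores 30 s less
  than in run mode, exactly `threshold_bins - 1` epochs per run.

Both are exposed because published analyses use both; totals differ by
30 s per sleep bout. The scorer treats *any* nonzero activation (even 1%)
as movement; a configurable noise floor exists but defaults to 0. Missing
epochs break immobility runs by default and propagate `NA` flags. The
threshold is implemented as ">= 4 bins", i.e. >= 40 s of immobility.

## Chi-squared periodogram

Rhythmicity is quantified with the Sokolove–Bushell statistic on 10-min
mean-binned activity. For each candidate period `P` (every integer number
of bins between 20 h and 28 h by default) the series is folded into `K`
complete cycles (`N = K P` bins used) and

    Q_P = K * N * sum_h (M_h - M)^2 / sum_i (x_i - M)^2

with `M_h` the column (phase) means and `M` the grand mean. Under the null
hypothesis of no rhythm `Q_P ~ chi-square(P - 1)`, giving a per-period
significance line at the `1 - alpha` quantile; `alpha` defaults to 0.001
(the conventional choice for this statistic; it is a parameter). The peak
period is the candidate with the largest excess of `Q_P` over its
significance line; constant input is an explicit "no rhythm detectable"
error rather than `NaN`, and fewer than two complete cycles of the longest
candidate is an error.

`Q_P` is invariant to affine rescaling of the activity values, so sensor
gain does not affect period estimation. The candidate grid is one bin
(10 min) wide; period estimates are therefore quantised to 10 min, and on
10-day records the statistical uncertainty of the peak is itself of that
order — period differences smaller than one bin should not be
over-interpreted.

## Actograms, onsets, and nonparametric statistics

`actogram_matrix` folds binned activity at any period (24 h default) into a
days-by-bins matrix, optionally double-plotted (day *d* next to day
*d + 1*, right half of the last row missing). Rows of the single-plotted
matrix sum to daily totals.

`activity_onset` implements a stated convention (no standard definition
exists): the onset is the first bin exceeding `mean + k * sd` of the
preceding 6-h baseline window (`k = 2`), whose following 30 min of
activity stays above the threshold *on average*. The window-mean form of
the sustain condition tolerates single-bin dips from brief sleep bouts
just after onset. Over a dead-quiet rest phase `mean + k * sd` is
near zero and any small ultradian bout crosses it; the optional
`floor_frac` argument floors the threshold at a fraction of the profile
maximum (0.25 is a good choice) for robustness on such data. Days without
a qualifying bin return `NA`, not an error. Per-day onsets on realistic
(fragmented) behaviour jitter by tens of minutes; onsets measured on
multi-day mean profiles are considerably more stable and are what the
package's own tests use when checking phase alignment.

Interdaily stability and intradaily variability use the standard
nonparametric definitions,

    IS = n * sum_h (xbar_h - xbar)^2 / (p * sum_i (x_i - xbar)^2)
    IV = n * sum_i (x_i - x_{i-1})^2 / ((n - 1) * sum_i (x_i - xbar)^2)

over `p` period-bins and `n` total bins: IS is 1 for a perfectly repeated
daily profile, IV is about 2 for white noise and near 0 for a smooth
rhythm.

`infer_light_schedule` thresholds the LDR channel (automatic threshold:
midpoint of a 2-means split, refused when the two modes are separated by
less than twice the within-mode spread), absorbs phase runs shorter than
10 min (sensor glitches), and classifies the regime as LD / DD / LL /
irregular; LD periods come from full light + dark run lengths.

## Validating the proxy: agreement with EEG

`sleep_agreement` bins PIR-scored sleep and hypnogram sleep (NREM + REM)
into minutes per 30-min bin, aligns them on their common time range, and
reports the Pearson correlation and a Bland–Altman analysis: bias =
mean(PIR − EEG) and 95% limits of agreement = bias ± 1.96 sd of the
differences (sample sd). Reports of this design sometimes label the limits
"95% confidence intervals"; they are limits of agreement — the interval
expected to contain 95% of individual differences — not a confidence
interval for the mean, and the package names them accordingly. When a
light schedule is available the analysis is repeated per phase, with bins
straddling a transition assigned by their start time; with lights-on
aligned to bin edges no straddling occurs.

Two systematic effects are worth knowing when reading these numbers.
Sleep bouts shorter than 40 s are invisible to the PIR criterion (a small
negative bias), while quiet wakefulness — awake but motionless — is scored
as sleep (a positive bias). Because mice show quiet wakefulness mainly in
the light phase, light-phase agreement is worse than dark-phase agreement,
with PIR overestimating sleep in the light.

## Daily profiles and cohort clustering

`daily_profile` folds a binned series into complete days and returns
per-bin mean and SEM (sd over days divided by sqrt of days; a single day
yields SEM 0 with a warning). `cluster_profiles` clusters an
animals-by-bins matrix with Euclidean distance and average linkage — the
plotting-package defaults such figures are usually made with; nothing in
the method is specific to that choice and both are arguments. Per-animal
z-scoring is the default so that clustering reflects the timing of
activity rather than its amplitude; raw profiles (`normalise = FALSE`)
are supported and are the right choice when amplitude *is* the phenotype
(e.g. weak vs strong movers under identical sensors). A constant profile
cannot be z-scored and is refused naming the animal. Rows are sorted by
label before clustering so leaf order is deterministic and invariant to
input row order.

Activity-based and sleep-based clusterings need not agree: immobility
scoring is blind to movement amplitude, so animals that differ mainly in
how vigorously they move (or how sensitively the sensor sees them) group
differently under the two views — sleep is not simply the absence of
activity.

## The simulator

`simulate_mouse` samples a semi-Markov alternation of wake and sleep bouts
with exponentially distributed dwell times whose means depend on circadian
phase, then emits per-epoch percent activation. It exists to provide
ground truth for every analysis above: the true state sequence yields the
reference hypnogram, the configured light cycle yields the reference
schedule, and all parameters are known.

Key defaults, chosen once to reproduce the canonical C57BL/6J phenotype
(each is a `sim_config` argument):

| parameter | default | why |
|---|---|---|
| `epoch_s` | 10 s | acquisition epoch of the PIR system |
| `active_dwell_s` | 240 s | mean active-bout length in the rest phase |
| `active_dark_mult` | 4 | nocturnal consolidation; gives a day/night activity ratio near 4 and ~75–80% of activity in the dark |
| `sleep_dwell_s` | 420 s | mean sleep-bout length at night |
| `sleep_light_mult` | 2.5 | longer day-time sleep bouts; total sleep ~13–14 h/day |
| `p_quiet_light` / `p_quiet_dark` | 0.30 / 0.08 | probability a wake bout is quiet wakefulness; concentrated in the light phase, which produces the light-phase PIR overestimation |
| `quiet_move_prob` | 0.1 | per-epoch chance of a small detectable movement during quiet wake |
| `artifact_prob` | 0.001 | per-epoch spurious activation during sleep |
| `tau_s` | 23.7 h (DD), 24.6 h (LL) | free-running period shortens in constant dark and lengthens in constant light |
| `min_sleep_bout_s` | 0 | optional floor on sleep-bout length; setting 40 makes every bout scoreable, which is how the exact-fidelity tests isolate the quiet-wake confound |

Emission choices that matter for exactness: an ACTIVE epoch always
registers at least 1% activation (a locomoting mouse trips at least one of
the 100 polls), so with quiet wakefulness and artifacts disabled and all
sleep bouts >= 40 s, run-mode PIR sleep equals hypnogram sleep *exactly* —
the package's tests rely on this to separate sensor physics from scoring
convention. Activation values are integers in [0, 100], like the real
system's poll counts.

`simulate_cohort` derives per-animal seeds deterministically from a master
seed, applies optional Gaussian jitter to named parameters, and accepts
per-animal overrides — chronotype phenotypes are expressed through
`phase_offset_s`, which shifts the animal's subjective clock without
moving the light channel.

What the simulator does **not** emulate: REM (all simulated sleep is
labelled NREM — the validation compares total sleep only); consolidated
rest-phase architecture beyond exponential dwells (real mice nap in longer
clustered episodes, so simulated per-day onset jitter is larger than in
very well-entrained animals); explicit ultradian oscillators (ultradian
structure emerges from bout alternation only); PIR dwell-time
autocorrelation and cage-geometry effects; and masking of activity by
light pulses. Passing tests on simulated data therefore demonstrate
correctness of the algorithms under a realistic null model, not
performance on any particular real colony.

## Numerical conventions and degenerate inputs

* All intervals are half-open `[start, start + width)` and labelled by
  their start; all times are UTC. This makes aggregation unambiguous.
* Gaps are explicit: missing epochs are `NA` rows, writers omit them,
  readers reconstruct them, and every downstream operation documents
  whether it skips (resampling, sleep binning) or refuses (periodogram,
  IS/IV) them.
* Degenerate inputs raise typed errors naming the offending lines, tokens
  or animals: non-monotone or unparseable timestamps, activity outside
  [0, 100], unknown hypnogram tokens, constant vectors where a statistic
  is undefined (correlation, periodogram, IS/IV, z-scoring).
* Resampling by `sum` conserves grand totals exactly; `mean` equals
  sum/count per bin; trailing partial bins are flagged.

## Problem sizes used by the package's own checks

The test-suite and the acceptance script size their simulations as the
package's own choice of demonstration scale: a 14-day LD recording for the
agreement statistics (672 thirty-minute bins), 10-day DD and LL recordings
for period recovery (1440 ten-minute bins), 1000 random vectors of up to
10,000 epochs for the scoring oracle, 50 seeds for the bias-asymmetry
Monte Carlo, and 100 simulated 24-animal, 3-day cohorts for clustering
recovery.

## Known limitations

Immobility-based scoring cannot stage sleep and will misread phenotypes
whose sleep begins without preceding immobility (e.g. narcolepsy-like
sudden onsets); quiet wakefulness inflates light-phase totals by design of
the proxy, not as a bug in the implementation; and period estimates are
quantised to the 10-min candidate grid. For anything beyond total sleep
and its timing, EEG remains the reference.
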