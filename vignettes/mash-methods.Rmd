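---
title: "Harmonizing hip-accelerometer activity and wrist-actigraph sleep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing hip-accelerometer activity and wrist-actigraph sleep: methods and design notes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological studies of 24-hour time-use increasingly ask participants to
wear two devices at once: a hip accelerometer that quantifies waking movement
behavior (sedentary time and light/moderate-to-vigorous physical activity)
and a wrist actigraph that scores sleep. The two streams disagree
systematically. The hip device is removed at night, so the Choi non-wear
algorithm cannot distinguish "device off on the nightstand" from "asleep";
worse, when a participant keeps the hip device on in bed, an entire night of
near-zero counts is classified as *sedentary behavior*. The wrist device, in
turn, has nights with malfunctions, removals, or unusable sleep scores.
Without reconciliation, daily behavior totals double-count sleep as sedentary
time and wake intervals cannot be bounded consistently.

`mash` builds, for every participant-day, a coherent
night(t−1)–day(t)–night(t) composition: a sleep interval
`[onset(t−1), offset(t))` followed by a waking interval
`[offset(t), onset(t))`, with the waking interval partitioned into
SB/LLPA/HLPA/MVPA and within-wake non-wear minutes. The resulting dataset is
bi-directional: sleep–wake and wake–sleep views use the same bounds.

## The two-tier engine

**Tier 1 (scored sleep).** When valid scored sleep surrounds a day — a valid
onset the previous evening, a valid offset the current morning, and a valid
onset the current evening — the waking interval is bounded directly by those
clock times.

**Tier 2 (CNN).** Otherwise a one-dimensional convolutional network assigns
each 60-s epoch a probability of lying *within the waking interval*,
evaluating a centered 101-epoch window around the epoch. Two variants exist:
a dual-device model (hip axes 1–3, watch activity, watch lux) and a hip-only
model (axes 1–3) for days whose watch data are missing or invalid. Routing
between them uses the watch coverage of the day's prediction span (20:00 of
the previous day through 06:00 of the next): at least 90% coverage routes to
the dual model. We use a coverage rule rather than "any watch data present"
because a night-long watch outage leaves plenty of daytime watch data while
the boundary region the model must resolve has none; the hip-only model is
the appropriate tool there.

Epoch probabilities become one interval per day by binarizing at the model's
cutoff, forming maximal supra-cutoff runs, merging runs separated by
sub-cutoff gaps shorter than `merge_gap` (default 120 min; configurable),
and selecting the merged cluster with the largest summed probability. The
summed-probability score favors long, confident waking runs over short
spurious ones; a duration-based score behaves almost identically on
simulated days but is less robust to isolated high-probability blips. Days
with no supra-cutoff epoch are unresolvable and excluded with their own
ledger reason.

## Upstream building blocks

* **Choi non-wear** on the hip vector magnitude: non-wear is a run of at
  least 90 min of zero counts, tolerating up to 2 consecutive nonzero
  minutes flanked by at least 30 min of zeros on both sides. All three
  parameters are configurable; missing counts are treated as zero during
  detection. The implementation is cross-checked against a brute-force
  state-machine scan in the test suite.
* **Evenson intensity bands** (60-s vector-magnitude counts/min):
  SB < 76 ≤ LLPA < 903 ≤ HLPA < 2075 ≤ MVPA, exclusive upper edges, applied
  verbatim. Adherence screening: a day is adherent at ≥ 600 wear minutes; a
  participant at ≥ 4 adherent days, not necessarily consecutive.
* **Sleep scoring** re-implements the default wrist-scorer behavior: the
  weighted five-epoch activity score (0.04/0.20/1.00/0.20/0.04) against a
  40 counts/min wake threshold; onset/offset as the start of the first and
  the end of the last run of 10 consecutive immobile minutes inside a rest
  window anchored by event markers, then diary, then a lowest-activity
  6-hour fallback window (flagged low-confidence); and validity screening
  (malfunction, no qualifying run, under 60 min of scored sleep).
  "Immobile" defaults to a zero count; the exact numeric immobility
  threshold of the commercial scorer is not published, so it is exposed as
  `immobile_count_max`.

All modules share one epoch convention: timestamps mark the epoch start,
intervals are half-open `[start, end)`, and timestamps are timezone-naive
local clock times (a repeated-hour pattern is rejected rather than silently
double-counted; no clock-drift correction between devices is applied).

## Exclusions and their order

Three day-level rules are applied in order, first match recorded: (1) each
participant's first day of data collection (a partial day starting at device
placement), (2) days with no sleep data preceding the waking interval,
(3) days whose preceding sleep is under 60 minutes (exactly 60 is kept).
Two additional dispositions are this package's own: CNN-unresolvable days,
and trailing days whose evening onset lies beyond the data grid.

## The CNN: training and cutoff contract

Labels come only from days with valid scored sleep on both sides: epochs in
`[offset(t), onset(t))` are 1, the rest of the night-to-night span 0, and
the half-open convention puts the epoch at the offset at 1 and the epoch at
the onset at 0. On simulated cohorts at the default wake fraction this
yields the expected ≈ 66/33 class split. Splits are by participant, never
by day; the default fractions mirror a 625/278/209 partition of 1112
participants.

The default architecture is two convolution blocks (32 filters of kernel 7
and 64 of kernel 5, each ReLU + max-pool 2) followed by a 64-unit dense
ReLU layer and a sigmoid output. Channels are `log1p`-transformed and
z-scored with training-split statistics that are frozen into the bundle;
edge windows are zero-padded and a validity-mask channel marks padding, so
days at stream edges still receive predictions. Training is Adam on mean
binary cross-entropy with early stopping on validation loss; everything is
seeded and single-threaded for reproducibility. The classification cutoff
is chosen on the test split by Youden's J (sensitivity + specificity − 1,
equal misclassification costs), with ties broken toward the higher cutoff.
The cutoff, its J, and the split statistics that produced it travel with
the model bundle. Published cutoffs from the original models are treated as
reported values of *those* trained models, not as constants; this package
computes its own.

The engine is written in base-R matrix algebra (im2col convolutions, so
each layer is one BLAS product) and is verified against finite-difference
gradients in the test suite. Desk-scale runs in the tests and the
acceptance script use a reduced network (16/32 filters, 32 dense units),
~6,000 training windows and 5 epochs — sizes chosen so a full pipeline run
completes in minutes on one CPU while still reaching held-out ROC-AUC
above 0.98 on simulated cohorts.

## The removal-gap correction

People remove the hip device when they get into bed, on average some tens
of minutes before falling asleep. A wake-interval bound predicted from hip
data therefore tends to sit at device removal rather than sleep onset,
inflating the sleep interval. The correction models this gap: from valid
scored nights with an observable removal (the hip is in Choi non-wear
during the minute before scored onset, with a wear-to-non-wear transition
in the preceding six hours), it collects pairs of (preceding wake-interval
length, scored onset − end of last hip wear), clamps both variables into
bounds — observed minima below, an imposed 200 min above — and represents
the bivariate density by a Gaussian product kernel over the fitted sample
with Silverman plug-in bandwidths and boundary reflection. Worn-to-bed
nights have no removal before onset and are skipped, so the fitted gap
marginal tracks the removal lag itself. Correcting a CNN onset draws ten
gaps conditional on the interval's length (kernel-weighted slice at the
length), averages them, and shifts the predicted onset later by that
average; morning (offset) bounds are never corrected. Degenerate samples
(all gaps equal) collapse to a near-zero bandwidth, so the correction
reduces to the observed constant; with too few usable records the fit
aborts and a constant-gap fallback is available.

Note that the 200-min upper bound applies to *both* variables, including
wake-interval length, although real wake intervals run ~960 min; lengths
are clamped into the support before conditioning, which makes the
conditional slice effectively the gap marginal for typical days. The gap
marginal is what drives the correction, and the bounds are configurable.

## The synthetic cohort generator

The generator exists so every stage is testable with known ground truth.
Per participant it lays out `n_days` nights across `n_days + 1` calendar
days: sleep onset near 23:00 (SD 40 min) and duration
`(1 − wake_fraction) · 24 h` (default wake fraction 0.66, giving the
≈ 66/33 epoch split), a first partial day starting at device placement
mid-morning, and a trailing half day. Waking time is a bout process over
SB/LLPA/HLPA/MVPA with geometric dwell times and SB-heavy occupancy;
per-state hip counts are lognormal with means placed inside the Evenson
bands (SB 20, LLPA 400, HLPA 1400, MVPA 3500 counts/min — simulator
conventions, not empirical claims). Watch counts during sleep are zero
runs punctuated by brief geometric arousal bursts, so the
10-immobile-minute rule has realistic structure; lux follows a day/night
profile with evening decay; event markers are pressed with 80% nightly
compliance and a diary is always available.

Each night draws a hip-removal lag from a truncated normal on
`[0, 200]` min whose *post-truncation* mean is 44.4 min (the location
parameter is solved numerically); the SD default 51.9 min places the
200-min bound roughly three SDs above the mean. During the lag the
participant is quietly awake in bed (sedentary state) with the hip device
already off. Night-level missingness is drawn independently per night:
watch malfunction (6%, wipes watch channels 18:00–10:00), watch removal
(4%, wipes noon-to-noon), and hip-worn-to-bed (10%, hip counts continue at
near-sedentary lognormal mean 8 counts/min through sleep, putting > 95% of
those minutes under the 76-count sedentary cut — the mislabeling failure
mode the harmonizer corrects). Real Table-2-style missingness is strongly
dependent across nights; the independent rates are a convention, and the
printed flow counts are reproduced exactly only through the deterministic
day-level fixture, not through simulation.

What the generator does *not* emulate: napping, split-night sleep,
sub-minute acceleration, device clock drift, diary errors, seasonal or
weekday structure, and realistic between-participant heterogeneity of
activity levels. Passing tests on simulation therefore demonstrate the
pipeline's internal correctness and its behavior under the stated
conditions, not field performance on cohort data.

## Numerical choices

* Quantiles/IQRs use type-7 (linear interpolation); the paired t-tests are
  standard and flagged as degenerate when differences have zero variance.
* Trapezoidal AUCs with tie-grouping, so the ROC area equals pairwise
  concordance with half credit for ties (asserted against an O(n²) oracle).
* The PR baseline equals positive prevalence.
* Youden ties break toward the higher cutoff; the classification rule is
  `probability >= cutoff`.
* Adherence days are calendar days (midnight boundary) — adherence is a
  screening step, distinct from the dynamic night-to-night day definition
  of the compositions.
* Composition closure is exact by construction: unclassifiable wake
  minutes (non-wear or missing hip data) are tallied as within-wake
  non-wear, so sleep + behaviors + non-wear always equals the
  onset-to-onset span. Sleep-onset latency inside the scored sleep
  interval is reported as a separate diagnostic column
  (`latency_min`), never as waking behavior.

## Known limitations and an honest finding

On simulated data, a competently trained hip-only CNN does **not**
reproduce the removal-onset confusion the gap correction is designed to
fix. Because training labels include the in-bed gap (epochs between
removal and onset are labeled wake), the network learns the gap
statistically: its supra-cutoff run ends a near-constant ≈ 41 min after
removal, uncorrelated with each night's true lag. Raw CNN onsets are then
already nearly unbiased (mean signed error ≈ −9 min on simulation), and
adding the fitted mean gap on top overshoots by roughly that amount. In
other words, the external correction and the network's internal hedge are
two estimates of the same quantity, and applying both double-counts. The
correction remains valuable for systems whose predictions stop at removal
— the regime the original method was built for — and the package applies
it as specified; the corresponding acceptance check on simulation is
expected to show the raw predictor winning, and the test suite records
this honestly rather than weakening the assertion. Users applying the
tier-2 path to real data should inspect the signed onset errors of their
own trained models (e.g., against scored nights) before enabling the
correction.

Other limitations: the main sleep interval only (no naps); waking non-wear
is reported, never imputed; tier-1 requires the evening onset of the
current night, so the final partial day of a wear period yields no
composition.
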