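---
title: "Winter torpor from skin-temperature biologging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winter torpor from skin-temperature biologging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(batbouts)
```

## The problem

Hibernating bats alternate multiday torpor bouts — skin temperature (Tsk)
falling to within a degree or two of the roost — with brief, energetically
expensive normothermic arousals. Field studies of cave-roosting bats record
Tsk with external temperature-sensitive radio transmitters whose pulse
interval encodes temperature; receiver stations log a detection about every
10 minutes while the bat is in range. From those logs one wants, per bat:
when each torpor bout started and ended, when arousals happened relative to
sunset, how long normothermic periods lasted, and how these respond to the
nightly weather outside the cave. `batbouts` implements that pipeline as
composable tibble-in/tibble-out functions, plus a ground-truthed synthetic
generator so every stage can be tested without field data.

## Calibration and decoding

Each transmitter is calibrated in a water bath at five temperatures between
5 and 40 °C; `fit_calibration()` fits an ordinary least-squares cubic of
temperature on pulse interval (fitted on the centred interval for
conditioning, reported in the raw basis). Cubics on five points can be
non-monotone over the calibrated range; the fit warns rather than fails,
because a wiggle in an unused part of the range is harmless while a refusal
would discard a usable transmitter.

`decode_trace()` snaps detections onto a regular 10-minute grid: nearest
slot, ties to the earlier slot, duplicates within a slot averaged (the field
protocol does not specify how duplicate detections within a logging cycle
were treated; averaging is this package's choice). Missing slots are kept
explicit because the segmentation rules below reason about gap lengths.
Pulse intervals outside the calibrated range are decoded by extrapolation
and flagged; winter Tsk stays inside the 5–40 °C calibration in practice.
Decoded values outside −10…45 °C are treated as noise and dropped.

Some transmitters drift over a deployment. `flag_drift()` regresses the
daily median of stable torpid-plateau samples on the day number and flags
the trace when the fitted change across the deployment exceeds 1 °C
(default). Flagged traces keep their bout *timing* — onset and arousal are
step changes that survive a slow bias — but their torpid temperature
summaries should be suppressed.

## The torpor-onset threshold

Torpor onset is defined by a published linear predictor of onset skin
temperature (its lower, minus-one-standard-error form):

$$T_{onset} = 0.041\,BM + 0.040\,T_a + 31.083$$

with body mass $BM$ in grams and ambient (roost) temperature $T_a$ in °C.
Evaluated at the two study sites' mean tagged masses and stable cave
temperatures (15.6 g at 10.6 °C; 15.0 g at 16.1 °C) and averaged,
`species_threshold()` gives the single species-level threshold of 32.2 °C
used for all bats, keeping bout definitions comparable across sites and
years. Both the coefficients and the threshold are overridable.

## Segmentation rules

A bat is in torpor when Tsk is below threshold for *more than* 10 min —
at 10-minute sampling, at least three consecutive below-threshold samples;
a run of exactly two samples is not a bout. Bouts are half-open
`[onset, end)`: the onset is the first below-threshold sample, the end the
first above-threshold sample, so a 48-hour cold plateau yields a 48.0 h
bout. Where the convention was genuinely open we chose and documented:

* **Gaps inside a bout.** Telemetry gaps of at most `gap_limit` samples
  (default 3, i.e. 30 min) flanked by torpid samples are bridged. Longer
  gaps split the record and censor the bout, unless the tail was rising.
* **Out-of-range arousals.** Rewarming bats often fly out of receiver range
  before Tsk crosses the threshold. If the signal is lost for more than
  `gap_limit` samples while the last two observed steps each rose by more
  than 0.5 °C, the bout ends at the last detection and that instant counts
  as the arousal. The 0.5 °C/step floor is far below a genuine rewarming
  step (~5 °C at 0.5 °C/min) and far above plateau noise.
* **Blips.** A single above-threshold sample ends a bout by default
  (`min_arousal_samples = 1`); the shortest recorded bouts (~0.3 h) argue
  against smoothing, but `min_arousal_samples = 2` restores it.
* **Edges.** Bouts truncated by the deployment end (or by an unexplained
  long gap) are emitted with a `censored` flag and excluded from duration
  summaries, arousal products and model frames — never dropped silently.
* A terminal gap of any length is treated like a long gap: the signal never
  returns, so the same rising-tail rule decides last-detection versus
  censoring.

Every non-censored bout emits an arousal event; normothermia spans an
arousal to the next torpor onset and is kept for analysis only if it starts
or ends inside a sunset-to-sunrise night window. The segmentation is
checked sample-for-sample against an independent brute-force scanner on
randomly generated traces.

## Night windows and nightly weather

Sunset and sunrise come from the NOAA solar-position equations (zenith
90.833°), implemented directly and verified to within 2 minutes of an
independent almanac computation; the analysis night of date *d* is
`[sunset(d), sunrise(d+1))`, half-open. All arithmetic runs in the site's
Olson timezone, so the early-spring daylight-saving transition is handled
by the timezone database, not by hand. Latitudes beyond ±60° (polar
day/night) are rejected.

`nightly_aggregate()` reduces a 30-minute station series to the five
covariates used downstream: mean air temperature, mean absolute humidity,
mean wind speed, total rain, and the overnight barometric-pressure change
ΔBP. Absolute humidity uses the Magnus saturation form (6.112 hPa, 17.67,
243.5 °C) and is converted per sample *then* averaged — the conversion is
nonlinear, so this differs from converting the nightly means, and the
per-sample order is the contract. ΔBP is pressure nearest sunrise minus
pressure nearest sunset (≤ 45 min away, else missing); the sign convention
(sunrise − sunset, so falling pressure is negative) is fixed here because
the source analyses interpret "falling barometric pressure". Nights with
under 70 % of expected samples get missing covariates rather than biased
means.

## Arousal timing and circular statistics

Arousal time relative to sunset uses a noon-to-noon civil day: a 02:00
arousal belongs to the previous evening's sunset (+9 h), and 9 minutes
after sunset is +0.15 h. `rayleigh_test()` maps hours onto the 24-h circle
and reports the mean resultant length $\bar r$, $z = n\bar r^2$, and the
standard series p-value approximation; published analyses of these data
print "z" values (0.63, 0.29) that are more consistent with $\bar r$ than
with $n\bar r^2$, so the result object carries both and the reader chooses.
`circular_mode()` is the argmax of a von Mises kernel density (default
κ = 25, ~45 min kernel SD) reported to 0.01 h, with a warning when
$\bar r < 0.1$ and the mode is not meaningful.

## Model frames, not model fits

The downstream inference in this literature fits penalised-spline mixed
models (gamma/log for bout duration, binomial for nightly arousal, Gaussian
on √duration for normothermia). Fitting those well is a modelling exercise
of its own, so this package exports *analysis-ready frames* instead —
bit-stable CSVs keyed by bout or bat-night with the nightly covariates and
day-of-year attached — plus distribution-free Spearman sign diagnostics
(`frame_sign_diagnostics()`) as a sanity check on effect directions.

The arousal frame has one row per night a bat was in torpor. A bout's
nights run from the civil night of its onset to the last night whose sunset
precedes the bout's end; `days_in_torpor` counts from 0 on the onset night,
and `aroused = 1` on the final night (a last-detection end counts as an
arousal). Censored bouts contribute no rows: their missing ends would
otherwise fabricate aroused-or-not outcomes.

## The synthetic generator

`simulate_cohort()` produces weather, night windows, truth schedules,
traces, calibration points and body-mass records under one seeded RNG
stream (same config ⇒ byte-identical output). It emulates:

* **Weather** — seasonal + diel sinusoids, a 30-min AR(1) anomaly, *and a
  multi-day synoptic component* (default 3 °C amplitude, 10-day period).
  The synoptic term matters: without multi-day persistence, nightly mean
  temperatures are serially independent and the onset-night temperature
  could not carry any signal about bout duration, which real cold spells
  do. RH is anticorrelated with temperature; pressure is a slow sinusoid
  plus AR(1); rain is Bernoulli–gamma; wind lognormal.
* **Arousal decisions** — each night in torpor,
  $\mathrm{logit}\,p = \beta_0 + \beta_{ta}\,T_a + \beta_{days}\,d$.
  Coefficients are configuration, not scientific claims; the defaults
  (cold: −0.75, 0.25, 0.45) were chosen so the embedded positive
  temperature and days-in-torpor effects are unambiguous at the default
  cohort size (20 bats × 90 days), mirroring a study system in which both
  effects were statistically significant.
* **Arousal timing** — von Mises around sunset plus a site offset (0.15 h
  cold, 0.28 h warm), with pre-sunset deviations shrunk by a factor 0.25.
  A symmetric von Mises puts nearly half the arousals before sunset, which
  neither matches field data (arousals cluster after sunset with a tail
  into the night) nor the night-keyed frame; the compression is a
  deliberate asymmetry. The cold preset consequently overshoots observed
  nocturnality (~97 % vs ~81 % of arousals at night) — a known gap between
  emulation and data.
* **Short warm-site bouts** — warm-roost bats average ~7 h per bout, which
  a purely nightly hazard cannot produce (its shortest cycle is ~14 h). The
  warm preset therefore splits the daily torpor interval into
  1 + Poisson(1.3) sub-bouts separated by brief (~0.9 h) normothermic
  interruptions; the nightly hazard still sets the night of the final,
  sunset-anchored arousal. The cold preset uses one bout per interval.
* **Thermal dynamics** — Newtonian cooling toward the cave temperature
  ($k$ = 0.8 /h cold, 1.0 /h warm) and linear rewarming at 0.5 °C/min
  (within the realistic 0.5–1 °C/min range for small bats; the slower end
  guarantees the 10-min grid sees at least two rising below-threshold
  samples during rewarming, so the last-detection rule is exercised
  deterministically). Truth records both behavioural instants and the
  threshold-crossing instants segmentation can actually see.
* **Degradation** — `encode_and_degrade()` inverts the fitted calibration
  cubic numerically (grid + Newton refinement), then applies per-sample
  Bernoulli dropout, optional linear calibration drift, and rewarm loss:
  with configured probability an arousing bat vanishes from the log the
  moment it reaches the threshold, for a 3 h foraging gap.
* **Body mass** — Gaussian draws (SD 0.5 g, the within-group residual for
  a 13–18 g bat after conditioning on site, sex and timepoint) around
  (site, sex, timepoint) means encoding stronger pre-winter fattening at
  the cold site, heavier cold-site females in early winter, and faster
  female mass loss.

Default cohorts land near the observed site means (~34 h cold vs ~31 h
printed; ~8 h warm vs ~7 h) — the tuning constants are all plain fields of
`sim_config()`. What passing the recovery tests shows is that the
*pipeline* is correct on data whose generating process is known; it does
not validate the generator against real bats, and features the generator
lacks (behavioural clustering beyond the hazard, cave micro-climate,
roost-switching, transmitter battery decay) limit that claim accordingly.

## Problem sizes and numerical choices

The test suite runs the brute-force segmentation oracle on 1,000 random
traces of up to 500 samples, full encode–decode–segment recovery on
noise-free cohorts of 10 (cold) and 6 (warm) bats, a 10,000-replicate
Monte-Carlo check that the Rayleigh p-approximation holds its 5 % type-I
error at n = 50, and hazard-sign recovery over 100 seeded replicates of the
default cold cohort — sizes chosen to exercise each property well past its
edge cases while keeping a full run to minutes on a laptop. Tolerances:
calibration round-trips to 10⁻⁸ °C on exact inputs and 0.01 °C through
encode/decode; solar events to 2 min of the almanac; boundary recovery to
1 sample. Ties in grid snapping go to the earlier slot; rounding follows
the reporting precision of the field (0.1 h durations, 0.1 °C thresholds,
0.1 g masses) and model frames are exported at full precision.

## Known limitations

* The segmentation boundary conventions (half-open bouts, first-above
  sample as end) shift all durations by at most one sampling step relative
  to the alternatives; both are configurable but only the defaults are
  calibrated against the tests.
* `flag_drift()` detects monotone plateau trends; oscillating or step
  drift will pass undetected.
* The Rayleigh p-value is a series approximation — excellent by n = 50,
  crude below n ≈ 10.
* Real-data idiosyncrasies (receiver interference, double detections from
  neighbouring transmitters, clock skew between stations) are out of the
  generator's scope and must be handled upstream of `decode_trace()`.
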