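# batbouts

Winter torpor analysis for skin-temperature biologging of cave-roosting
bats. Field crews tag bats with external temperature-sensitive radio
transmitters whose pulse interval encodes skin temperature (Tsk); receiver
stations log a detection roughly every 10 minutes. `batbouts` turns those
logs into the quantities hibernation ecologists analyse — torpor bouts,
arousal events, normothermia bouts, their timing relative to sunset, and
nightly weather covariates — and ships a ground-truthed synthetic
biologging generator so the whole pipeline is testable end to end.

## What it computes

* **Calibration & decoding** — per-transmitter cubic fits of water-bath
  calibration points (`fit_calibration()`), decoding of pulse logs onto a
  regular 10-min grid with explicit gaps (`decode_trace()`), and
  calibration-drift flagging (`flag_drift()`).
* **Torpor-onset threshold** — the linear predictor
  `T_onset = 0.041·BM + 0.040·Ta + 31.083` (°C; body mass in g, roost
  temperature in °C), and the species-level threshold averaged over sites:
  `species_threshold(study_sites())` gives **32.2 °C**.
* **Segmentation** (`segment_trace()`) — a bat is in torpor when Tsk stays
  below threshold for more than two consecutive samples; bouts are
  half-open `[onset, end)`; short telemetry gaps are bridged; a long gap
  after a rising tail ends the bout at the last detection (the bat rewarmed
  and flew out of range); deployment-edge bouts are censored, not dropped.
* **Night windows & weather** — NOAA-equation sunset/sunrise
  (`night_window()`), and sunset-to-sunrise aggregation of 30-min station
  series (`nightly_aggregate()`): mean air temperature, mean absolute
  humidity (Magnus form, converted per sample then averaged), mean wind,
  total rain, and the overnight pressure change ΔBP (sunrise − sunset).
* **Circular statistics** — Rayleigh uniformity test (mean resultant
  length r̄, z = n·r̄², series p-value) and a von Mises kernel mode of
  arousal time after sunset.
* **Summaries & frames** — per-site bout summaries (`bout_summaries()`),
  body-mass change tables (`body_mass_changes()`), and three
  analysis-ready model frames (bout duration, nightly arousal probability
  with days-in-torpor, normothermia duration) for external GAMM/GLMM
  fitting, with Spearman sign diagnostics in-package.
* **Synthetic data** (`simulate_cohort()`) — weather with synoptic cold
  spells, logistic nightly arousal hazards, Newtonian cooling / linear
  rewarming traces, calibration-encoded pulse logs with dropouts and
  out-of-range losses, and site/sex-structured body-mass records, all with
  recorded ground truth (`match_truth()` scores recovery).
* **Orchestration** — `run_pipeline()` runs calibrate → decode → segment →
  weather → summaries/frames from one YAML config and writes deterministic
  CSVs plus a manifest with row counts and checksums.

## Worked example

Simulate a small cold-site cohort, segment it at the species threshold, and
summarise:

```r
library(batbouts)

cfg <- sim_config("cold", n_bats = 5, days = 30, seed = 42)
co  <- simulate_cohort(cfg)
seg <- segment_traces(co$traces, species_threshold(study_sites()),
                      nights = co$nights)
seg
#> <torpor_segmentation> threshold 32.2 degC
#>   92 bout(s) (5 censored), 87 arousal(s), 87 normothermia bout(s)

bout_summaries(seg$bouts, seg$arousals, seg$normothermia)
#> # A tibble: 2 × 12
#>   site  n_bouts n_individuals mean_duration_h sd_duration_h ...
#> 1 cold       87             5            31.3          21.6
#> 2 all        87             5            31.3          21.6
```

Five bats over 30 mid-winter days produced 87 completed torpor bouts (5
more were cut off by the deployment end and are censored), averaging
31.3 ± 21.6 h — multiday torpor typical of a cold hibernaculum; 40.2 % of
bouts exceeded 24 h. Arousal timing is strongly sunset-anchored:

```r
rayleigh_test(seg$arousals$rel_sunset_h)
#> Rayleigh test of uniformity: n = 87, rbar = 0.940, z = 76.891, p < 0.001
circular_mode(seg$arousals$rel_sunset_h)
#> [1] 0.82   # hours after sunset
```

and the exported arousal frame recovers the effects the generator embeds —
arousal probability rising with nights already spent in torpor
(ρ = 0.61, p ≈ 5e-24 here) and with nightly air temperature:

```r
nightly <- nightly_aggregate(co$weather, co$nights)
fr <- build_model_frames(seg, nightly, co$nights)
frame_sign_diagnostics(fr$arousal, "aroused")
```

`plot_trace(co$traces, seg)` draws the Tsk series with detected bouts
shaded; `plot_arousal_clock(seg$arousals)` shows the arousal clock. The
study's own field data are deposited at
<https://zenodo.org/records/15803803>; point `run_pipeline()` at its CSVs
(plus a site config) to reproduce the published descriptive summaries.

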