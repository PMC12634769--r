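# End-to-end orchestration: calibrate -> decode -> segment -> nightly
# weather -> summaries and model frames, from a single configuration.

#' Run the full torpor analysis pipeline
#'
#' Reads the per-site input files, fits per-transmitter calibrations,
#' decodes pulse logs into traces, computes night windows and nightly
#' weather covariates, segments every trace at the configured (or
#' species-level) threshold, and writes bout/arousal/normothermia tables,
#' nightly weather, per-site summaries, circular arousal-timing statistics,
#' body-mass change tables and the three model frames, plus a manifest JSON
#' with row counts and file checksums. Two runs on identical inputs produce
#' byte-identical outputs.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Required structure:
#' \preformatted{
#' sites:              # one entry per site
#'   - name: cold
#'     lat: -33.8
#'     lon: 150.0
#'     tz: Australia/Sydney
#'     cave_temp_C: 10.6
#'     mean_mass_g: 15.6
#'     calibration: calibration.csv
#'     pulses: pulses.csv
#'     deployments: deployments.csv   # bat_id, transmitter_id [, cave]
#'     weather: weather.csv
#' bodymass: bodymass.csv             # optional, shared across sites
#' threshold: 32.2                    # optional override, degC
#' gap_limit: 3
#' min_arousal_samples: 1
#' sampling_interval: 10
#' outdir: out/
#' }
#' @param outdir Output directory (overrides the config entry).
#' @return (Invisibly) the manifest: effective threshold, output files with
#'   row counts and MD5 checksums, and processing notes.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$sites) || length(config$sites) == 0) {
    abort("pipeline config needs at least one `sites` entry")
  }
  outdir <- outdir %||% config$outdir %||% abort("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  threshold <- config$threshold
  if (!is.null(threshold) && (threshold <= 25 || threshold >= 40)) {
    abort("threshold override must lie in (25, 40) degC")
  }
  if (is.null(threshold)) {
    profiles <- purrr::map_dfr(config$sites, function(s) {
      tibble(mean_mass_g = s$mean_mass_g, roost_temp_C = s$cave_temp_C)
    })
    threshold <- species_threshold(profiles)
  }
  gap_limit <- config$gap_limit %||% 3
  min_ar <- config$min_arousal_samples %||% 1
  interval <- config$sampling_interval %||% 10
  notes <- character()

  per_site <- purrr::map(config$sites, function(s) {
    cal <- read_calibration_csv(file.path_or_abs(s$calibration))
    pulses <- read_pulse_csv(file.path_or_abs(s$pulses), tz = s$tz)
    dep <- read_csv_quiet(file.path_or_abs(s$deployments))
    assert_cols(dep, c("bat_id", "transmitter_id"), s$deployments)
    weather <- read_weather_csv(file.path_or_abs(s$weather), tz = s$tz)

    curves <- fit_calibrations(cal)
    span <- range(pulses$timestamp)
    dates <- seq(as.Date(span[1], tz = s$tz) - 1,
                 as.Date(span[2], tz = s$tz) + 1, by = "day")
    nights <- night_window(s$lat, s$lon, s$tz, dates, site = s$name)
    nightly <- nightly_aggregate(weather, nights)

    traces <- purrr::pmap(dep, function(bat_id, transmitter_id, ...) {
      extra <- list(...)
      row <- which(curves$transmitter_id == transmitter_id)
      if (length(row) == 0) {
        abort(sprintf("no calibration for transmitter %s", transmitter_id))
      }
      decode_trace(pulses, curves$curve[[row]], sampling_interval = interval,
                   bat_id = bat_id, site = s$name,
                   cave = extra$cave %||% NA_character_)
    })
    seg <- segment_traces(traces, threshold = threshold, nights = nights,
                          gap_limit = gap_limit,
                          min_arousal_samples = min_ar)
    list(site = s$name, nights = nights, nightly = nightly, seg = seg)
  })

  nights <- bind_rows(purrr::map(per_site, "nights"))
  nightly <- bind_rows(purrr::map(per_site, "nightly"))
  seg <- segmentation_result(
    bind_rows(purrr::map(per_site, ~ .x$seg$bouts)),
    bind_rows(purrr::map(per_site, ~ .x$seg$arousals)),
    bind_rows(purrr::map(per_site, ~ .x$seg$normothermia)),
    threshold, gap_limit, min_ar, 0.5)
  notes <- c(notes, sprintf("censored bouts: %d", sum(seg$bouts$censored)))

  summaries <- bout_summaries(seg$bouts, seg$arousals, seg$normothermia)
  frames <- purrr::map(per_site, function(ps) {
    build_model_frames(ps$seg, ps$nightly, ps$nights)
  })
  frames <- list(
    tbd = bind_rows(purrr::map(frames, "tbd")),
    arousal = bind_rows(purrr::map(frames, "arousal")),
    nd = bind_rows(purrr::map(frames, "nd"))
  )

  circular_report <- purrr::map(per_site, function(ps) {
    ar <- ps$seg$arousals
    rs <- ar$rel_sunset_h[is.finite(ar$rel_sunset_h)]
    if (length(rs) < 5) {
      return(list(site = ps$site, n = length(rs)))
    }
    rt <- rayleigh_test(rs)
    list(site = ps$site, n = rt$n, rbar = rt$rbar, z = rt$z,
         p_value = rt$p_value, mode_h_after_sunset = circular_mode(rs))
  })

  outputs <- list(
    bouts = seg$bouts,
    arousals = seg$arousals,
    normothermia = seg$normothermia,
    nightly_weather = nightly,
    summaries = summaries,
    frame_tbd = frames$tbd,
    frame_arousal = frames$arousal,
    frame_nd = frames$nd
  )
  if (!is.null(config$bodymass)) {
    records <- read_bodymass_csv(file.path_or_abs(config$bodymass))
    outputs$bodymass_changes <- bind_rows(
      body_mass_changes(records, "late_summer", "early_winter", by = "site"),
      body_mass_changes(records, "early_winter", "late_winter", by = "site"),
      body_mass_changes(records, "early_winter", "late_winter",
                        by = c("site", "sex"))
    )
  }

  written <- purrr::imap(outputs, function(df, nm) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    write_output_csv(df, path)
    list(file = paste0(nm, ".csv"), rows = nrow(df),
         md5 = digest::digest(path, algo = "md5", file = TRUE))
  })
  report_path <- file.path(outdir, "circular_report.json")
  jsonlite::write_json(circular_report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written$circular_report <- list(
    file = "circular_report.json", rows = length(circular_report),
    md5 = digest::digest(report_path, algo = "md5", file = TRUE))

  manifest <- list(threshold_C = threshold, gap_limit = gap_limit,
                   min_arousal_samples = min_ar,
                   outputs = unname(written), notes = notes)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Paths in a config are taken as given (absolute or relative to the working
# directory).
file.path_or_abs <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  path
}

#' Write a simulated cohort as a pipeline-ready dataset
#'
#' Encodes every simulated trace through its transmitter's fitted
#' calibration curve (with the configured dropout profile), and writes the
#' calibration, pulse, deployment, weather and body-mass CSVs, the truth
#' schedule JSON, and a ready-to-run pipeline YAML config.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @param p_dropout,rewarm_loss_p Dropout profile; defaults from the
#'   cohort's configuration.
#' @return The path of the written pipeline config YAML.
#' @export
write_sim_dataset <- function(cohort, dir,
                              p_dropout = cohort$config$dropout$p_dropout,
                              rewarm_loss_p =
                                cohort$config$dropout$rewarm_loss_p) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::local_seed(cohort$config$seed + 1L)
  cfg <- cohort$config
  dp <- cfg$dropout
  curves <- fit_calibrations(cohort$calibration)
  bat_ids <- unique(cohort$traces$bat_id)
  pulses <- purrr::map_dfr(seq_along(bat_ids), function(i) {
    tr <- cohort$traces[cohort$traces$bat_id == bat_ids[i], ]
    encode_and_degrade(tr, curves$curve[[i]], p_dropout = p_dropout,
                       rewarm_loss_p = rewarm_loss_p,
                       forage_gap_h = dp$forage_gap_h,
                       departure_C = dp$departure_C,
                       drift_C_per_day = dp$drift_C_per_day)
  })
  dep <- tibble(bat_id = bat_ids,
                transmitter_id = curves$transmitter_id[seq_along(bat_ids)],
                cave = NA_character_)
  write_output_csv(cohort$calibration, file.path(dir, "calibration.csv"))
  write_output_csv(pulses, file.path(dir, "pulses.csv"))
  write_output_csv(dep, file.path(dir, "deployments.csv"))
  write_output_csv(cohort$weather, file.path(dir, "weather.csv"))
  write_output_csv(cohort$bodymass, file.path(dir, "bodymass.csv"))
  jsonlite::write_json(
    dplyr::mutate(cohort$truth, dplyr::across(
      dplyr::where(lubridate::is.POSIXct), format_iso8601)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  config <- list(
    sites = list(list(
      name = cfg$site$name, lat = cfg$site$lat, lon = cfg$site$lon,
      tz = cfg$site$tz, cave_temp_C = cfg$site$cave_temp_C,
      mean_mass_g = cfg$site$mean_mass_g,
      calibration = file.path(dir, "calibration.csv"),
      pulses = file.path(dir, "pulses.csv"),
      deployments = file.path(dir, "deployments.csv"),
      weather = file.path(dir, "weather.csv")
    )),
    bodymass = file.path(dir, "bodymass.csv"),
    outdir = file.path(dir, "out")
  )
  cfg_path <- file.path(dir, "pipeline.yml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
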