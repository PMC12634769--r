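# Torpor-onset threshold: a linear predictor of onset skin temperature from
# body mass and ambient (roost) temperature, and the species-level threshold
# averaged over study sites.

#' Threshold model coefficients
#'
#' Coefficients of the torpor-onset skin-temperature predictor
#' `T_onset = slope_bm * BM + slope_ta * Ta + intercept`, the published
#' lower (minus one standard error) bound for torpor onset in
#' vespertilionoid bats. Defaults are the printed values; override in a
#' configuration if a different calibration is wanted.
#'
#' @param slope_bm degC per gram of body mass (default 0.041).
#' @param slope_ta degC per degC of ambient temperature (default 0.040).
#' @param intercept degC (default 31.083).
#' @return A named list of the three coefficients.
#' @export
threshold_params <- function(slope_bm = 0.041, slope_ta = 0.040,
                             intercept = 31.083) {
  stopifnot(is.finite(slope_bm), is.finite(slope_ta), is.finite(intercept))
  list(slope_bm = slope_bm, slope_ta = slope_ta, intercept = intercept)
}

#' Torpor onset threshold for an individual
#'
#' @param bm_g Body mass in grams, in (0, 100].
#' @param ta_C Ambient temperature near the roosting bat in degC,
#'   in (-10, 40).
#' @param params Coefficients from [threshold_params()].
#' @return Onset threshold skin temperature in degC.
#' @examples
#' torpor_onset_threshold(15.6, 10.6) # cold-site inputs -> 32.1466
#' @export
torpor_onset_threshold <- function(bm_g, ta_C, params = threshold_params()) {
  if (any(!is.finite(bm_g)) || any(bm_g <= 0) || any(bm_g > 100)) {
    abort("`bm_g` must be in (0, 100] grams")
  }
  if (any(!is.finite(ta_C)) || any(ta_C <= -10) || any(ta_C >= 40)) {
    abort("`ta_C` must be in (-10, 40) degC")
  }
  params$slope_bm * bm_g + params$slope_ta * ta_C + params$intercept
}

#' Species-level torpor onset threshold across sites
#'
#' Evaluates the onset predictor at each site's mean tagged body mass and
#' stable roost temperature, averages across sites, and rounds to 0.1 degC.
#' This single species-level threshold keeps bout definitions consistent
#' across sites and deployment years.
#'
#' @param site_profiles Data frame with columns `mean_mass_g` and
#'   `roost_temp_C`, one row per site (see [study_sites()]).
#' @param params Coefficients from [threshold_params()].
#' @param digits Rounding precision in decimal places (default 1).
#' @return The species threshold in degC.
#' @examples
#' species_threshold(study_sites()) # 32.2
#' @export
species_threshold <- function(site_profiles, params = threshold_params(),
                              digits = 1) {
  assert_cols(site_profiles, c("mean_mass_g", "roost_temp_C"),
              "site_profiles")
  if (nrow(site_profiles) < 1) {
    abort("`site_profiles` needs at least one site")
  }
  per_site <- torpor_onset_threshold(site_profiles$mean_mass_g,
                                     site_profiles$roost_temp_C, params)
  round(mean(per_site), digits)
}

#' Study-site profiles
#'
#' The two monitored hibernacula: a cold high-elevation karst site and a
#' warm coastal site, with the roost (cave) temperature where tagged bats
#' spent most time and the site-mean body mass of tagged individuals.
#'
#' @return A tibble with columns `site`, `lat`, `lon`, `tz`, `cave`,
#'   `mean_mass_g` and `roost_temp_C`.
#' @export
study_sites <- function() {
  tibble(
    site = c("cold", "warm"),
    lat = c(-33.8, -31.1),
    lon = c(150.0, 152.7),
    tz = c("Australia/Sydney", "Australia/Sydney"),
    cave = c("Mammoth", "Yessabah"),
    mean_mass_g = c(15.6, 15.0),
    roost_temp_C = c(10.6, 16.1)
  )
}
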