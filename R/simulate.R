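#' Configuration for the stochastic daily-weather generator
#'
#' Daily mean temperature is a seasonal cosine plus AR(1) noise (persistence
#' produces realistic multi-day extreme runs); rainfall is an independent
#' Bernoulli occurrence times a gamma amount. Defaults are set for a
#' central-England-like temperate series: annual mean 9.7 deg C, seasonal
#' amplitude 6.6 deg C peaking in late July, lag-1 autocorrelation 0.7 with
#' innovation SD 2.2 deg C, and rain on half of days with gamma(0.7, 6.5)
#' amounts.
#'
#' @param years Integer vector of calendar years to simulate.
#' @param mean_c Annual mean temperature, deg C.
#' @param amplitude_c Seasonal half-range, deg C.
#' @param peak_doy Day of year of the temperature peak.
#' @param ar1 AR(1) coefficient of the temperature noise, in `[0, 1)`.
#' @param innovation_sd_c Innovation SD of the AR(1) noise, deg C.
#' @param rain_prob Daily probability of any rain.
#' @param rain_shape,rain_scale_mm Gamma parameters of wet-day amounts.
#' @return A list of class `climate_sim_config`.
#' @export
climate_sim_config <- function(years = 1965:2024, mean_c = 9.7,
                               amplitude_c = 6.6, peak_doy = 203,
                               ar1 = 0.7, innovation_sd_c = 2.2,
                               rain_prob = 0.5, rain_shape = 0.7,
                               rain_scale_mm = 6.5) {
  stopifnot(ar1 >= 0, ar1 < 1, rain_prob >= 0, rain_prob <= 1,
            rain_shape > 0, rain_scale_mm > 0, innovation_sd_c >= 0)
  structure(
    list(years = as.integer(years), mean_c = mean_c, amplitude_c = amplitude_c,
         peak_doy = peak_doy, ar1 = ar1, innovation_sd_c = innovation_sd_c,
         rain_prob = rain_prob, rain_shape = rain_shape,
         rain_scale_mm = rain_scale_mm),
    class = "climate_sim_config"
  )
}

#' Simulate a daily climate series
#'
#' @param config A [climate_sim_config()].
#' @param seed Integer seed; identical seeds give identical series.
#' @return A validated climate tibble (`date, tmean_c, rain_mm`).
#' @export
simulate_climate <- function(config = climate_sim_config(), seed = 20240101) {
  stopifnot(inherits(config, "climate_sim_config"))
  set.seed(seed)
  dates <- seq(as.Date(paste0(min(config$years), "-01-01")),
               as.Date(paste0(max(config$years), "-12-31")), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$mean_c +
    config$amplitude_c * cos(2 * pi * (doy - config$peak_doy) / 365.25)
  if (config$innovation_sd_c > 0) {
    sd_stat <- config$innovation_sd_c / sqrt(1 - config$ar1^2)
    innov <- rnorm(n, 0, config$innovation_sd_c)
    noise <- as.numeric(stats::filter(innov, config$ar1, method = "recursive",
                                      init = rnorm(1, 0, sd_stat)))
  } else {
    noise <- numeric(n)
  }
  wet <- rbinom(n, 1, config$rain_prob)
  amount <- rgamma(n, shape = config$rain_shape, scale = config$rain_scale_mm)
  validate_climate(tibble(
    date = dates,
    tmean_c = seasonal + noise,
    rain_mm = wet * amount
  ))
}

#' Configuration for the breeding-data generator
#'
#' Emulates a long-term nestbox study: each year a fixed number of first
#' clutches with normally distributed lay dates (optionally trending across
#' years, emulating a population-level shift to earlier laying), a fixed
#' lay-to-hatch lag, shifted-Poisson clutch sizes, and mothers/nestboxes
#' sampled from finite pools so identities recur across years.
#'
#' @param broods_per_year Number of first clutches per year.
#' @param lay_mean_doy Mean lay day-of-year in the first simulated year.
#' @param lay_sd Within-year SD of lay date, days.
#' @param lay_trend Trend in mean lay date, days per year (negative =
#'   advancing).
#' @param hatch_lag Days from first egg to hatch (laying + incubation).
#' @param clutch_lambda Clutch size is `1 + Poisson(clutch_lambda)`.
#' @param n_mothers,n_nestboxes Pool sizes; `NULL` picks pools giving
#'   realistic reuse (about 2.5 broods per mother, 3 per nestbox). Must be at
#'   least `broods_per_year`.
#' @return A list of class `breeding_sim_config`.
#' @export
breeding_sim_config <- function(broods_per_year = 50, lay_mean_doy = 115,
                                lay_sd = 9, lay_trend = 0, hatch_lag = 19,
                                clutch_lambda = 7.6, n_mothers = NULL,
                                n_nestboxes = NULL) {
  stopifnot(broods_per_year >= 1, lay_sd >= 0, hatch_lag >= 1,
            clutch_lambda > 0)
  structure(
    list(broods_per_year = as.integer(broods_per_year),
         lay_mean_doy = lay_mean_doy, lay_sd = lay_sd, lay_trend = lay_trend,
         hatch_lag = as.integer(hatch_lag), clutch_lambda = clutch_lambda,
         n_mothers = n_mothers, n_nestboxes = n_nestboxes),
    class = "breeding_sim_config"
  )
}

#' Simulate broods and chick skeletons
#'
#' Generates brood phenology and structure over the years covered by the
#' climate series; chicks are returned without outcomes (mass and
#' recruitment are filled in by [simulate_outcomes()] from exposure records
#' computed by the production exposure code).
#'
#' @param config A [breeding_sim_config()].
#' @param climate A climate tibble spanning the simulated breeding seasons.
#' @param seed Integer seed.
#' @return A list with `broods` and `chicks` tibbles.
#' @export
simulate_broods <- function(config = breeding_sim_config(), climate,
                            seed = 20240101) {
  stopifnot(inherits(config, "breeding_sim_config"))
  set.seed(seed)
  years <- sort(unique(as.integer(format(climate$date, "%Y"))))
  n_total <- length(years) * config$broods_per_year
  n_mothers <- config$n_mothers %||%
    max(config$broods_per_year, round(n_total / 2.5))
  n_nestboxes <- config$n_nestboxes %||%
    max(config$broods_per_year, round(n_total / 3))
  if (n_mothers < config$broods_per_year ||
      n_nestboxes < config$broods_per_year) {
    abort("mother and nestbox pools must hold at least broods_per_year ids")
  }
  mother_pool <- sprintf("f%04d", seq_len(n_mothers))
  box_pool <- sprintf("nb%04d", seq_len(n_nestboxes))

  broods <- purrr::map(seq_along(years), function(i) {
    yr <- years[i]
    mu <- config$lay_mean_doy + config$lay_trend * (yr - years[1])
    # truncate into the April-June breeding season (first clutches)
    lay <- as.integer(pmin(pmax(
      round(rnorm(config$broods_per_year, mu, config$lay_sd)), 91L), 181L))
    tibble(
      brood_id = sprintf("b%d_%03d", yr, seq_len(config$broods_per_year)),
      year = yr,
      lay_doy = lay,
      hatch_date = as.Date(paste0(yr, "-01-01")) + lay - 1L + config$hatch_lag,
      clutch_size = 1L + rpois(config$broods_per_year, config$clutch_lambda),
      mother_id = sample(mother_pool, config$broods_per_year),
      nestbox_id = sample(box_pool, config$broods_per_year)
    )
  }) |> bind_rows()

  if (min(broods$hatch_date) < min(climate$date) ||
      max(broods$hatch_date) + 15 > max(climate$date)) {
    abort("simulated brood windows fall outside the climate series span")
  }
  chicks <- broods |>
    select("brood_id", "clutch_size") |>
    tidyr::uncount(.data$clutch_size, .id = ".k") |>
    mutate(chick_id = paste0(.data$brood_id, "_c", .data$.k),
           mass_d15_g = NA_real_, recruited = NA_real_) |>
    select("chick_id", "brood_id", "mass_d15_g", "recruited")
  list(broods = broods, chicks = chicks)
}

#' Generating truth for synthetic outcomes
#'
#' Standardized fixed-effect coefficients, random-intercept SDs and noise
#' scales used by [simulate_outcomes()]. Coefficients are in SD units (per
#' SD of the predictor, in SDs of the latent mass scale); `mass_scale_g`
#' converts the latent scale to grams. Defaults are parameterised near
#' published effect magnitudes for this system (rain-event effect about
#' -0.14 SD, lay-date effect about -0.22 SD, baseline recruitment about 9%)
#' so synthetic outputs sit on a plausible scale, while remaining arbitrary
#' configuration values.
#'
#' @param mass_intercept_g Mean fledging mass at average covariates, grams.
#' @param mass_scale_g Grams per latent SD unit.
#' @param mass_beta Named vector of standardized mass coefficients; names are
#'   analysis-table columns.
#' @param mass_ranef_sd Named random-intercept SDs (latent SD units) for
#'   `year`, `brood_id`, `mother_id`, `nestbox_id`.
#' @param mass_resid_sd Residual SD, latent units.
#' @param recruit_base_rate Target marginal (population-average) recruitment
#'   fraction; the conditional logit intercept is derived from it with the
#'   standard logistic-normal mean correction for the latent variance.
#' @param recruit_beta Named vector of standardized logit coefficients.
#' @param recruit_ranef_sd Named random-intercept SDs on the logit scale.
#' @return A list of class `outcome_truth`.
#' @export
outcome_truth <- function(
    mass_intercept_g = 18.5, mass_scale_g = 1.4,
    mass_beta = c(hatchling_n_cold = -0.10, nestling_n_rain = -0.143,
                  nestling_mean_temp = 0.10, rel_lay_date = -0.223,
                  clutch_size = 0.05),
    mass_ranef_sd = c(year = 0.30, brood_id = 0.45, mother_id = 0.30,
                      nestbox_id = 0.15),
    mass_resid_sd = 0.70,
    recruit_base_rate = 0.091,
    recruit_beta = c(hatchling_n_cold = -0.20, rel_lay_date = -0.30),
    recruit_ranef_sd = c(year = 0.30, brood_id = 0.40)) {
  stopifnot(all(is.finite(mass_beta)), all(mass_ranef_sd >= 0),
            mass_resid_sd >= 0, all(recruit_ranef_sd >= 0),
            mass_scale_g > 0, recruit_base_rate > 0, recruit_base_rate < 1)
  structure(
    list(mass_intercept_g = mass_intercept_g, mass_scale_g = mass_scale_g,
         mass_beta = mass_beta, mass_ranef_sd = mass_ranef_sd,
         mass_resid_sd = mass_resid_sd,
         recruit_base_rate = recruit_base_rate,
         recruit_beta = recruit_beta, recruit_ranef_sd = recruit_ranef_sd),
    class = "outcome_truth"
  )
}

# draw one random intercept per level of `ids`, return per-row contribution
ranef_draw <- function(ids, sd) {
  lev <- unique(ids)
  u <- rnorm(length(lev), 0, sd)
  u[match(ids, lev)]
}

#' Simulate chick outcomes from exposure records
#'
#' Completes chick records with day-15 mass and recruitment, generated from
#' the same linear predictors the inference module fits: standardized
#' predictors (realized sample moments, so generator and fitter agree on
#' scale) times the truth coefficients, plus crossed random intercepts and
#' residual noise. Exposure records must come from the production exposure
#' code ([brood_exposure()]); the generator does not re-derive them.
#'
#' @param broods,chicks Output of [simulate_broods()].
#' @param exposures Output of [brood_exposure()] on the same broods.
#' @param truth An [outcome_truth()].
#' @param seed Integer seed.
#' @return The chick tibble with `mass_d15_g` and `recruited` filled in.
#' @export
simulate_outcomes <- function(broods, chicks, exposures,
                              truth = outcome_truth(), seed = 20240101) {
  stopifnot(inherits(truth, "outcome_truth"))
  set.seed(seed)
  at <- build_analysis_table(broods, chicks, exposures,
                             drop_gap_flagged = FALSE)
  at <- at[match(chicks$chick_id, at$chick_id), ]
  pred_cols <- union(names(truth$mass_beta), names(truth$recruit_beta))
  missing <- setdiff(pred_cols, names(at))
  if (length(missing) > 0) {
    abort(glue::glue("exposure/analysis table lacks predictor(s): {toString(missing)}"))
  }
  z <- standardize(at[, pred_cols, drop = FALSE], pred_cols)

  eta_mass <- drop(as.matrix(z[, names(truth$mass_beta)]) %*% truth$mass_beta)
  for (g in names(truth$mass_ranef_sd)) {
    eta_mass <- eta_mass + ranef_draw(at[[g]], truth$mass_ranef_sd[[g]])
  }
  eta_mass <- eta_mass + rnorm(nrow(at), 0, truth$mass_resid_sd)
  mass <- truth$mass_intercept_g + truth$mass_scale_g * eta_mass

  # conditional intercept from the target marginal rate: logistic-normal
  # mean approximation E[plogis(mu + s Z)] ~ plogis(mu / sqrt(1 + c^2 s^2)),
  # with c = 16 sqrt(3) / (15 pi)
  eta_rec_fixed <- drop(as.matrix(z[, names(truth$recruit_beta)]) %*%
                          truth$recruit_beta)
  latent_var <- var(eta_rec_fixed) + sum(truth$recruit_ranef_sd^2)
  c2 <- (16 * sqrt(3) / (15 * pi))^2
  eta_rec <- qlogis(truth$recruit_base_rate) * sqrt(1 + c2 * latent_var) +
    eta_rec_fixed
  for (g in names(truth$recruit_ranef_sd)) {
    eta_rec <- eta_rec + ranef_draw(at[[g]], truth$recruit_ranef_sd[[g]])
  }
  recruit_draw <- rbinom(nrow(at), 1, plogis(eta_rec))

  mutate(chicks, mass_d15_g = .env$mass, recruited = as.numeric(.env$recruit_draw))
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generative pipeline: weather, monthly baseline and
#' deviations, threshold calibration, day flags, brood structure, exposure
#' (through the production exposure code), outcomes, and the final per-chick
#' analysis table. Everything is reproducible from `seed`.
#'
#' @param seed Integer seed (sub-stage seeds are derived from it).
#' @param n_years Number of simulated years.
#' @param broods_per_year First clutches per year.
#' @param climate_config,breeding_config Optional config overrides; the
#'   year span of `climate_config` wins over `n_years` when supplied.
#' @param truth An [outcome_truth()].
#' @param tail_prob Tail probability for threshold calibration.
#' @param baseline_mode Monthly baseline mode.
#' @param windows Stage windows.
#' @return A list with `climate`, `baseline`, `deviations`, `thresholds`,
#'   `flags`, `broods`, `chicks`, `exposures`, `analysis`, `truth`.
#' @export
simulate_study <- function(seed = 20240101, n_years = 20,
                           broods_per_year = 50,
                           climate_config = NULL, breeding_config = NULL,
                           truth = outcome_truth(), tail_prob = 0.05,
                           baseline_mode = "calendar_month_longterm",
                           windows = stage_windows()) {
  climate_config <- climate_config %||%
    climate_sim_config(years = 2000 + seq_len(n_years))
  breeding_config <- breeding_config %||%
    breeding_sim_config(broods_per_year = broods_per_year)
  climate <- simulate_climate(climate_config, seed = seed)
  baseline <- compute_monthly_baseline(climate, mode = baseline_mode)
  deviations <- compute_deviations(climate, baseline)
  thresholds <- calibrate_thresholds(deviations, tail_prob = tail_prob)
  flags <- classify_days(deviations, thresholds)
  bc <- simulate_broods(breeding_config, climate, seed = seed + 1L)
  exposures <- brood_exposure(bc$broods, flags, climate, windows = windows)
  chicks <- simulate_outcomes(bc$broods, bc$chicks, exposures,
                              truth = truth, seed = seed + 2L)
  analysis <- build_analysis_table(bc$broods, chicks, exposures)
  list(climate = climate, baseline = baseline, deviations = deviations,
       thresholds = thresholds, flags = flags, broods = bc$broods,
       chicks = chicks, exposures = exposures, analysis = analysis,
       truth = truth)
}
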