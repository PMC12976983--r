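#' Parameter-recovery harness for the fledging-mass model
#'
#' Replicates the full synthetic pipeline (weather -> deviations ->
#' thresholds -> exposure -> outcomes) and refits the nestling-stage
#' rain-event mass model (rain-event count + stage mean temperature +
#' relative lay date + clutch size, crossed random intercepts for year,
#' brood, mother and nestbox) on each replicate, returning the standardized
#' estimates, Wald 95% CIs, truth-coverage indicators and estimated variance
#' proportions. Estimates are mapped back to latent SD units through the
#' generator's gram scale, so they are directly comparable with the truth
#' coefficients.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param n_years,broods_per_year Scale of each replicate.
#' @param truth Generating truth; the default matches the fitted model's
#'   predictor set with a rain-event effect of -0.14 SD.
#' @param null_component Optional name of a random component whose
#'   generating SD is forced to zero (e.g. `"mother_id"`), for checking that
#'   absent components are estimated near zero.
#' @return A list: `coefs` (one row per replicate x fixed term, SD units)
#'   and `varprops` (per replicate x component, share of total variance).
#' @export
recover_mass_model <- function(n_reps = 50, seed = 20240101, n_years = 20,
                               broods_per_year = 50,
                               truth = NULL, null_component = NULL) {
  truth <- truth %||% outcome_truth(
    mass_beta = c(nestling_n_rain = -0.14, nestling_mean_temp = 0.10,
                  rel_lay_date = -0.223, clutch_size = 0.05)
  )
  if (!is.null(null_component)) {
    truth$mass_ranef_sd[[null_component]] <- 0
  }
  spec <- design_spec(
    "mass_d15_g", "gaussian",
    fixed = purrr::map(names(truth$mass_beta), term_linear),
    random = c("year", "brood_id", "mother_id", "nestbox_id")
  )
  res <- purrr::map(seq_len(n_reps), function(r) {
    study <- simulate_study(seed = seed + 13L * r, n_years = n_years,
                            broods_per_year = broods_per_year, truth = truth)
    fit <- fit_lmm(study$analysis, spec)
    sc <- truth$mass_scale_g
    coefs <- fit$coefficients |>
      filter(.data$term != "(Intercept)") |>
      mutate(replicate = r,
             estimate_sd = .data$estimate / sc,
             conf.low_sd = .data$conf.low / sc,
             conf.high_sd = .data$conf.high / sc,
             truth = unname(truth$mass_beta[.data$term]),
             covers = .data$conf.low_sd <= .data$truth &
               .data$truth <= .data$conf.high_sd) |>
      select("replicate", "term", "estimate_sd", "conf.low_sd",
             "conf.high_sd", "truth", "covers")
    varprops <- fit$varcomp |>
      mutate(replicate = r, prop = .data$variance / sum(.data$variance)) |>
      select("replicate", "group", "prop")
    list(coefs = coefs, varprops = varprops)
  })
  list(coefs = bind_rows(purrr::map(res, "coefs")),
       varprops = bind_rows(purrr::map(res, "varprops")))
}

#' Parameter-recovery harness for the categorical-ECE recruitment model
#'
#' Each replicate simulates weather, broods and exposure through the
#' production pipeline, groups hatchling cold-event counts into categories,
#' draws recruitment from a logistic model with known per-level log-odds
#' plus year and brood random intercepts, and refits the same categorical
#' GLMM. Returns per-replicate level estimates with truth and a
#' within-2-SE indicator.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param n_years,broods_per_year Scale of each replicate.
#' @param level_logodds Named true log-odds contrasts against the zero-event
#'   level, by category label.
#' @param intercept_logit True intercept (logit of baseline recruitment).
#' @param ranef_sd Named SDs of the year and brood random intercepts.
#' @param cap Pooling cap for [categorize_ece_counts()].
#' @return A tibble, one row per replicate x category level.
#' @export
recover_recruit_model <- function(n_reps = 50, seed = 20240101, n_years = 10,
                                  broods_per_year = 40,
                                  level_logodds = c("1" = -0.24, "2+" = -0.30),
                                  intercept_logit = qlogis(0.091),
                                  ranef_sd = c(year = 0.3, brood_id = 0.4),
                                  cap = 2L) {
  spec <- design_spec("recruited", "binomial",
                      fixed = list(term_categorical("ece_cat")),
                      random = names(ranef_sd), standardize = FALSE)
  purrr::map(seq_len(n_reps), function(r) {
    set.seed(seed + 37L * r)
    study_seed <- sample.int(2^30, 1)
    study <- simulate_study(seed = study_seed, n_years = n_years,
                            broods_per_year = broods_per_year)
    at <- study$analysis
    at$ece_cat <- categorize_ece_counts(at$hatchling_n_cold, cap = cap)
    eta <- intercept_logit +
      unname(c("0" = 0, level_logodds)[as.character(at$ece_cat)])
    for (g in names(ranef_sd)) eta <- eta + ranef_draw(at[[g]], ranef_sd[[g]])
    at$recruited <- rbinom(nrow(at), 1, plogis(eta))
    fit <- fit_glmm_binomial(at, spec)
    fit$coefficients |>
      filter(stringr::str_detect(.data$term, "^ece_cat")) |>
      mutate(replicate = r,
             level = stringr::str_remove(.data$term, "^ece_cat"),
             truth = unname(level_logodds[.data$level]),
             within_2se = abs(.data$estimate - .data$truth) <=
               2 * .data$std.error) |>
      select("replicate", "level", "estimate", "std.error", "truth",
             "within_2se")
  }) |> bind_rows()
}
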