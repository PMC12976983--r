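#' The standard model roster
#'
#' Named [design_spec()] presets covering every model family of the
#' analysis: ambient-weather spline/linear models, ECE count and binary
#' models, ECE-by-ambient and ECE-by-relative-lay-date interaction models
#' (including the quadratic rain interaction), and categorical-ECE
#' recruitment models, each per developmental stage and event type. Hot and
#' cold events never enter one model together (their counts are collinear).
#' The `path_laydate` entry is the path-analysis decomposition and is run
#' through [fit_path_model()] rather than a mixed model.
#'
#' @param ece_cap Pooling cap for categorical recruitment models.
#' @param include_lay_in_recruitment Also adjust recruitment models for lay
#'   date (the models are fitted both ways in the source analysis).
#' @return A named list of presets; each mixed-model entry has `spec` (a
#'   [design_spec()]) and `prep` (a function deriving any needed columns).
#' @export
model_presets <- function(ece_cap = 4L, include_lay_in_recruitment = FALSE) {
  stages <- c("hatchling", "nestling")
  types <- c("hot", "cold", "rain")
  identity_prep <- function(data) data
  presets <- list()
  ranef <- c("year", "brood_id", "mother_id", "nestbox_id")

  for (s in stages) {
    presets[[paste0("ambient_temp_spline_", s)]] <- list(
      kind = "lmm",
      spec = design_spec("mass_d15_g", "gaussian",
                         fixed = list(term_spline(paste0(s, "_mean_temp"), 5L),
                                      term_linear("lay_doy"),
                                      term_linear("clutch_size")),
                         random = ranef),
      prep = identity_prep
    )
    presets[[paste0("ambient_rain_", s)]] <- list(
      kind = "lmm",
      spec = design_spec("mass_d15_g", "gaussian",
                         fixed = list(term_linear(paste0(s, "_mean_rain")),
                                      term_linear("lay_doy"),
                                      term_linear("clutch_size")),
                         random = ranef),
      prep = identity_prep
    )
    for (t in types) {
      presets[[paste0("ece_count_", t, "_", s)]] <- list(
        kind = "lmm",
        spec = design_spec("mass_d15_g", "gaussian",
                           fixed = list(term_linear(paste0(s, "_n_", t)),
                                        term_linear(paste0(s, "_mean_temp")),
                                        term_linear("lay_doy"),
                                        term_linear("clutch_size")),
                           random = ranef),
        prep = identity_prep
      )
      presets[[paste0("ece_binary_", t, "_", s)]] <- list(
        kind = "lmm",
        spec = design_spec("mass_d15_g", "gaussian",
                           fixed = list(term_linear(paste0(s, "_any_", t)),
                                        term_linear(paste0(s, "_mean_temp")),
                                        term_linear("lay_doy"),
                                        term_linear("clutch_size")),
                           random = ranef),
        prep = local({
          col <- paste0(s, "_any_", t)
          function(data) {
            data[[col]] <- as.numeric(data[[col]])
            data
          }
        })
      )
      presets[[paste0("recruitment_", t, "_", s)]] <- list(
        kind = "glmm",
        spec = design_spec(
          "recruited", "binomial",
          fixed = c(list(term_categorical(paste0(s, "_ece_cat_", t)),
                         term_linear(paste0(s, "_mean_temp")),
                         term_linear("clutch_size")),
                    if (include_lay_in_recruitment) list(term_linear("lay_doy"))),
          random = ranef
        ),
        prep = local({
          count_col <- paste0(s, "_n_", t)
          cat_col <- paste0(s, "_ece_cat_", t)
          cap <- ece_cap
          function(data) {
            data[[cat_col]] <- categorize_ece_counts(data[[count_col]], cap)
            data
          }
        })
      )
    }
    presets[[paste0("interaction_hot_x_rain_", s)]] <- list(
      kind = "lmm",
      spec = design_spec("mass_d15_g", "gaussian",
                         fixed = list(term_linear(paste0(s, "_n_hot")),
                                      term_linear(paste0(s, "_mean_rain")),
                                      term_interaction(paste0(s, "_n_hot"),
                                                       paste0(s, "_mean_rain")),
                                      term_linear("lay_doy"),
                                      term_linear("clutch_size")),
                         random = ranef),
      prep = identity_prep
    )
    presets[[paste0("interaction_rain_x_temp_", s)]] <- list(
      kind = "lmm",
      spec = design_spec("mass_d15_g", "gaussian",
                         fixed = list(term_linear(paste0(s, "_n_rain")),
                                      term_linear(paste0(s, "_mean_temp")),
                                      term_interaction(paste0(s, "_n_rain"),
                                                       paste0(s, "_mean_temp")),
                                      term_linear("lay_doy"),
                                      term_linear("clutch_size")),
                         random = ranef),
      prep = identity_prep
    )
    presets[[paste0("rellay_x_hot_", s)]] <- list(
      kind = "lmm",
      spec = design_spec("mass_d15_g", "gaussian",
                         fixed = list(term_linear(paste0(s, "_n_hot")),
                                      term_linear("rel_lay_date"),
                                      term_interaction(paste0(s, "_n_hot"),
                                                       "rel_lay_date"),
                                      term_linear(paste0(s, "_mean_temp")),
                                      term_linear("clutch_size")),
                         random = ranef),
      prep = identity_prep
    )
    presets[[paste0("rellay_x_rain_", s)]] <- list(
      kind = "lmm",
      spec = design_spec("mass_d15_g", "gaussian",
                         fixed = list(term_linear(paste0(s, "_n_rain")),
                                      term_linear("rel_lay_date"),
                                      term_interaction(paste0(s, "_n_rain"),
                                                       "rel_lay_date"),
                                      term_quadratic_interaction(
                                        paste0(s, "_n_rain"), "rel_lay_date"),
                                      term_linear(paste0(s, "_mean_temp")),
                                      term_linear("clutch_size")),
                         random = ranef),
      prep = identity_prep
    )
  }
  presets[["ece_spline_hot_nestling"]] <- list(
    kind = "lmm",
    spec = design_spec("mass_d15_g", "gaussian",
                       fixed = list(term_spline("nestling_n_hot", 3L),
                                    term_linear("nestling_mean_temp"),
                                    term_linear("lay_doy"),
                                    term_linear("clutch_size")),
                       random = ranef),
    prep = identity_prep
  )
  presets[["path_laydate"]] <- list(
    kind = "path",
    exposure = "rel_lay_date",
    mediators = c("nestling_mean_temp", "nestling_n_hot"),
    outcome = "mass_d15_g"
  )
  presets
}

#' Fit one preset on an analysis table
#'
#' @param data An analysis table.
#' @param preset One entry of [model_presets()] (or its name).
#' @param ... Passed to [model_presets()] when `preset` is a name.
#' @return An `ece_fit` (mixed-model presets) or an `ece_path`.
#' @export
fit_preset <- function(data, preset, ...) {
  if (is.character(preset)) {
    roster <- model_presets(...)
    if (!preset %in% names(roster)) {
      abort(glue::glue("unknown preset '{preset}'"))
    }
    preset <- roster[[preset]]
  }
  switch(preset$kind,
    lmm = fit_lmm(preset$prep(data), preset$spec),
    glmm = fit_glmm_binomial(preset$prep(data), preset$spec),
    path = fit_path_model(data, exposure = preset$exposure,
                          mediators = preset$mediators,
                          outcome = preset$outcome)
  )
}
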