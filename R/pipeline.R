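#' Dataset descriptors
#'
#' Headline descriptors of an analysis table: sample sizes, the fledging
#' mass median and interquartile range, and the overall recruitment
#' fraction.
#'
#' @param analysis An analysis table (see [build_analysis_table()]).
#' @return A one-row tibble.
#' @export
summarize_dataset <- function(analysis) {
  tibble(
    n_chicks = nrow(analysis),
    n_broods = dplyr::n_distinct(analysis$brood_id),
    n_years = dplyr::n_distinct(analysis$year),
    mass_median_g = median(analysis$mass_d15_g, na.rm = TRUE),
    mass_q25_g = unname(quantile(analysis$mass_d15_g, 0.25, na.rm = TRUE)),
    mass_q75_g = unname(quantile(analysis$mass_d15_g, 0.75, na.rm = TRUE)),
    recruitment_fraction = mean(analysis$recruited, na.rm = TRUE)
  )
}

#' Ambient conditions during event exposure by seasonal timing
#'
#' Documents the absolute temperature (hot/cold events) or rainfall (rain
#' events) experienced at each event frequency, split by the within-year
#' seasonal percentile group (early / mid / late broods).
#'
#' @param analysis An analysis table with `lay_group` labels.
#' @param type Event type: `"hot"`, `"cold"` or `"rain"`.
#' @param stage `"hatchling"` or `"nestling"`.
#' @return A tibble `lay_group, n_events, mean_value, n_broods`.
#' @export
condition_by_timing <- function(analysis, type = c("hot", "cold", "rain"),
                                stage = c("hatchling", "nestling")) {
  type <- match.arg(type)
  stage <- match.arg(stage)
  count_col <- paste0(stage, "_n_", type)
  value_col <- paste0(stage, if (type == "rain") "_mean_rain" else "_mean_temp")
  analysis |>
    distinct(.data$brood_id, .keep_all = TRUE) |>
    group_by(.data$lay_group, n_events = .data[[count_col]]) |>
    summarise(mean_value = mean(.data[[value_col]]),
              n_broods = dplyr::n(), .groups = "drop")
}

#' Pipeline configuration
#'
#' Bundles every setting of a full analysis run. Inputs may be given as
#' file paths (read with the package readers) or as in-memory tibbles.
#'
#' @param climate Climate CSV path or tibble.
#' @param broods,chicks Brood/chick CSV paths or tibbles.
#' @param out_dir Run directory to create.
#' @param baseline_mode Monthly baseline mode.
#' @param tail_probs Tail probabilities; the first is used for exposure and
#'   models, all are calibrated and exported.
#' @param windows Stage windows.
#' @param presets Names of roster presets to fit (default: all).
#' @param ece_cap Pooling cap for recruitment models.
#' @param include_lay_in_recruitment Adjust recruitment models for lay date.
#' @param carry_over_zero Optional carry-over filter (see
#'   [build_analysis_table()]).
#' @param dialect Climate file dialect.
#' @param seed Integer seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(climate, broods, chicks, out_dir,
                            baseline_mode = "calendar_month_longterm",
                            tail_probs = c(0.05, 0.01),
                            windows = stage_windows(),
                            presets = NULL, ece_cap = 4L,
                            include_lay_in_recruitment = FALSE,
                            carry_over_zero = NULL,
                            dialect = climate_dialect(),
                            seed = 20240101) {
  structure(
    list(climate = climate, broods = broods, chicks = chicks,
         out_dir = out_dir, baseline_mode = baseline_mode,
         tail_probs = tail_probs, windows = windows, presets = presets,
         ece_cap = ece_cap,
         include_lay_in_recruitment = include_lay_in_recruitment,
         carry_over_zero = carry_over_zero, dialect = dialect, seed = seed),
    class = "pipeline_config"
  )
}

fit_to_list <- function(fit, name) {
  if (inherits(fit, "ece_path")) {
    return(list(
      preset = name, kind = "path",
      paths = as.data.frame(fit$paths),
      direct = fit$effects$direct,
      indirect = as.data.frame(fit$effects$indirect),
      total = fit$effects$total, n = fit$n
    ))
  }
  list(
    preset = name, kind = fit$spec$family,
    formula = deparse(spec_formula(fit$spec)),
    coefficients = as.data.frame(fit$coefficients),
    varcomp = as.data.frame(fit$varcomp),
    glance = as.data.frame(glance(fit)),
    scaling = if (!is.null(fit$scaling)) as.data.frame(fit$scaling),
    converged = fit$converged, notes = fit$notes
  )
}

#' Run the full analysis pipeline
#'
#' Calibrate -> classify -> expose -> join -> fit -> report, writing a
#' self-describing run directory: threshold JSONs per tail, the exposure
#' and analysis CSVs, one JSON per fitted preset, dataset descriptors, a
#' config snapshot and a log. A stage failure writes a `FAILED` marker
#' (retaining partial outputs) and aborts with a stage-named message.
#' Reruns with the same config and inputs reproduce identical estimates.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `thresholds`, `exposures`, `analysis`,
#'   `summary` and `fits`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "fits"), showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    inform(line)
  }
  stage <- "setup"
  result <- tryCatch({
    set.seed(config$seed)

    stage <- "read"
    climate <- if (is.character(config$climate)) {
      read_daily_climate(config$climate, config$dialect)
    } else validate_climate(config$climate)
    if (is.character(config$broods)) {
      bt <- read_brood_table(config$broods, config$chicks)
      broods <- bt$broods; chicks <- bt$chicks
    } else {
      broods <- config$broods; chicks <- config$chicks
      validate_breeding(broods, chicks)
    }
    gaps <- climate_gaps(climate)
    log_line(stage, glue::glue(
      "{nrow(climate)} climate days ({nrow(gaps)} gaps), ",
      "{nrow(broods)} broods, {nrow(chicks)} chicks"))

    stage <- "calibrate"
    baseline <- compute_monthly_baseline(climate, config$baseline_mode)
    deviations <- compute_deviations(climate, baseline)
    thresholds <- purrr::map(config$tail_probs, function(p) {
      th <- calibrate_thresholds(deviations, p)
      pct <- formatC(100 * p, format = "g")
      jsonlite::write_json(
        as.list(tidy(th)),
        file.path(config$out_dir, glue::glue("thresholds_{pct}pct.json")),
        auto_unbox = TRUE, digits = NA)
      log_line(stage, glue::glue(
        "tail {p}: hot {round(th$hot_cut, 2)} / cold {round(th$cold_cut, 2)} ",
        "/ rain {round(th$rain_cut, 2)}"))
      th
    })
    names(thresholds) <- paste0("tail_", config$tail_probs)

    stage <- "expose"
    flags <- classify_days(deviations, thresholds[[1]])
    exposures <- brood_exposure(broods, flags, climate,
                                windows = config$windows)
    readr::write_csv(exposures, file.path(config$out_dir, "exposures.csv"))
    n_flagged <- sum(exposures$gap_excluded)
    log_line(stage, glue::glue(
      "{nrow(exposures)} brood-stage records; {n_flagged} gap-flagged"))

    stage <- "build-table"
    analysis <- build_analysis_table(broods, chicks, exposures,
                                     carry_over_zero = config$carry_over_zero)
    readr::write_csv(analysis, file.path(config$out_dir, "analysis_table.csv"))
    excl <- attr(analysis, "exclusions")
    if (nrow(excl) > 0) {
      purrr::pwalk(excl, function(brood_id, reason) {
        log_line(stage, glue::glue("EXCLUDED brood {brood_id}: {reason}"))
      })
    }
    summary_row <- summarize_dataset(analysis)
    jsonlite::write_json(as.list(summary_row),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(stage, glue::glue(
      "{nrow(analysis)} chicks; mass median {round(summary_row$mass_median_g, 2)} g; ",
      "recruitment {round(100 * summary_row$recruitment_fraction, 1)}%"))

    stage <- "fit"
    roster <- model_presets(ece_cap = config$ece_cap,
                            include_lay_in_recruitment = config$include_lay_in_recruitment)
    wanted <- config$presets %||% names(roster)
    unknown <- setdiff(wanted, names(roster))
    if (length(unknown) > 0) {
      abort(glue::glue("unknown preset(s): {toString(unknown)}"))
    }
    fits <- purrr::map(wanted, function(nm) {
      fit <- fit_preset(analysis, roster[[nm]])
      jsonlite::write_json(fit_to_list(fit, nm),
                           file.path(config$out_dir, "fits",
                                     paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      conv <- if (inherits(fit, "ece_fit") && !fit$converged) {
        " [NOT CONVERGED]"
      } else ""
      log_line(stage, paste0("fitted ", nm, conv))
      fit
    })
    names(fits) <- wanted

    stage <- "snapshot"
    snap <- config
    for (f in c("climate", "broods", "chicks")) {
      if (!is.character(snap[[f]])) snap[[f]] <- "<in-memory tibble>"
    }
    snap$windows <- as.data.frame(snap$windows)
    snap$dialect <- unclass(snap$dialect)
    yaml::write_yaml(unclass(snap),
                     file.path(config$out_dir, "config_snapshot.yaml"))
    log_line("done", "pipeline complete")
    list(thresholds = thresholds, exposures = exposures,
         analysis = analysis, summary = summary_row, fits = fits)
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    abort(glue::glue("pipeline failed at stage '{stage}': {conditionMessage(e)}"),
          parent = e)
  })
  invisible(result)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] fields (file-path
#'   inputs).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  windows <- if (!is.null(y$windows)) {
    stage_windows(
      hatchling = c(y$windows$hatchling[[1]], y$windows$hatchling[[2]]),
      nestling = c(y$windows$nestling[[1]], y$windows$nestling[[2]])
    )
  } else stage_windows()
  dialect <- if (!is.null(y$dialect)) do.call(climate_dialect, y$dialect)
  else climate_dialect()
  pipeline_config(
    climate = y$climate, broods = y$broods, chicks = y$chicks,
    out_dir = y$out_dir %||% "ecenest_run",
    baseline_mode = y$baseline_mode %||% "calendar_month_longterm",
    tail_probs = unlist(y$tail_probs) %||% c(0.05, 0.01),
    windows = windows,
    presets = unlist(y$presets),
    ece_cap = y$ece_cap %||% 4L,
    include_lay_in_recruitment = isTRUE(y$include_lay_in_recruitment),
    carry_over_zero = y$carry_over_zero,
    dialect = dialect,
    seed = y$seed %||% 20240101
  )
}
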