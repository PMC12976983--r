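#' Calibrate extreme-climatic-event thresholds
#'
#' Computes percentile-tail cutoffs from a deviation series: the hot cutoff is
#' the upper `1 - tail_prob` quantile of the temperature deviations, the cold
#' cutoff the lower `tail_prob` quantile, and the rain cutoff the upper
#' `1 - tail_prob` quantile of the rainfall deviations. Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7), and
#' the convention is recorded in the result so printed thresholds are
#' interpretable.
#'
#' @param deviations Output of [compute_deviations()] (or a compatible tibble
#'   with `tdev_c` and `raindev_mm`).
#' @param tail_prob Tail probability in (0, 0.5); 0.05 flags the extreme 5%
#'   tails, 0.01 the extreme 1% tails.
#'
#' @return An object of class `ece_thresholds`: a list with `tail_prob`,
#'   `hot_cut`, `cold_cut` (signed, negative), `rain_cut`, `calibration_span`,
#'   `baseline_mode`, `quantile_rule` and `n_days`.
#' @export
calibrate_thresholds <- function(deviations, tail_prob = 0.05) {
  if (!is.numeric(tail_prob) || tail_prob <= 0 || tail_prob >= 0.5) {
    abort("`tail_prob` must lie strictly between 0 and 0.5")
  }
  tdev <- deviations$tdev_c
  rdev <- deviations$raindev_mm
  if (any(is.infinite(tdev)) || any(is.infinite(rdev))) {
    abort("non-finite deviations; validate the input series")
  }
  n_ok <- sum(!is.na(tdev))
  if (n_ok < 100) {
    abort(glue::glue("calibration needs >= 100 non-missing days, got {n_ok}"))
  }
  structure(
    list(
      tail_prob = tail_prob,
      hot_cut = unname(quantile(tdev, 1 - tail_prob, na.rm = TRUE, type = 7)),
      cold_cut = unname(quantile(tdev, tail_prob, na.rm = TRUE, type = 7)),
      rain_cut = unname(quantile(rdev, 1 - tail_prob, na.rm = TRUE, type = 7)),
      calibration_span = range(deviations$date),
      baseline_mode = attr(deviations, "baseline_mode") %||% "unknown",
      quantile_rule = "linear_interpolation_type7",
      n_days = n_ok
    ),
    class = "ece_thresholds"
  )
}

#' @export
print.ece_thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("ECE thresholds (%.0f%% tails, %s baseline, %d days %s..%s)\n",
           "  hot  >= %+.2f C   cold <= %+.2f C   rain >= %+.2f mm\n"),
    100 * x$tail_prob, x$baseline_mode, x$n_days,
    x$calibration_span[1], x$calibration_span[2],
    x$hot_cut, x$cold_cut, x$rain_cut
  ))
  invisible(x)
}

#' @method tidy ece_thresholds
#' @export
tidy.ece_thresholds <- function(x, ...) {
  tibble(
    tail_prob = x$tail_prob, hot_cut = x$hot_cut, cold_cut = x$cold_cut,
    rain_cut = x$rain_cut, baseline_mode = x$baseline_mode,
    quantile_rule = x$quantile_rule, n_days = x$n_days,
    span_start = x$calibration_span[1], span_end = x$calibration_span[2]
  )
}

#' Flag extreme days
#'
#' Marks each day of a deviation series as hot (temperature deviation at or
#' above the hot cutoff), cold (at or below the cold cutoff) and/or rain
#' (rainfall deviation at or above the rain cutoff). All comparisons are
#' inclusive. Days with missing deviations carry `NA` flags, never `FALSE`.
#'
#' @param deviations Output of [compute_deviations()].
#' @param thresholds An [calibrate_thresholds()] object.
#' @return A tibble `date, is_hot, is_cold, is_rain` with the thresholds in
#'   the `thresholds` attribute.
#' @export
classify_days <- function(deviations, thresholds) {
  stopifnot(inherits(thresholds, "ece_thresholds"))
  dev_mode <- attr(deviations, "baseline_mode") %||% "unknown"
  if (!identical(dev_mode, thresholds$baseline_mode)) {
    warn(glue::glue(
      "deviation baseline mode '{dev_mode}' differs from the mode the ",
      "thresholds were calibrated on ('{thresholds$baseline_mode}')"
    ))
  }
  out <- tibble(
    date = deviations$date,
    is_hot = deviations$tdev_c >= thresholds$hot_cut,
    is_cold = deviations$tdev_c <= thresholds$cold_cut,
    is_rain = deviations$raindev_mm >= thresholds$rain_cut
  )
  attr(out, "thresholds") <- thresholds
  out
}

#' Developmental stage windows
#'
#' Day offsets relative to hatch (hatch day = day 0), endpoints inclusive.
#' Defaults follow the two classic great-tit windows: the hatchling stage
#' (days 0-7, before homeothermy) and the nestling stage (days 8-15, peak
#' energetic demand, ending at the day-15 weighing).
#'
#' @param hatchling,nestling Length-2 integer vectors `c(start, end)`.
#' @return A tibble `stage, start_offset, end_offset`.
#' @export
stage_windows <- function(hatchling = c(0L, 7L), nestling = c(8L, 15L)) {
  out <- tibble(
    stage = c("hatchling", "nestling"),
    start_offset = as.integer(c(hatchling[1], nestling[1])),
    end_offset = as.integer(c(hatchling[2], nestling[2]))
  )
  if (any(out$start_offset > out$end_offset)) {
    abort("window start offset must be <= end offset")
  }
  out
}

#' Exposure of one brood window to extreme events
#'
#' Counts flagged days and averages ambient conditions over the window
#' `[hatch_date + start_offset, hatch_date + end_offset]` (inclusive). Runs of
#' consecutive extreme days count one event per day. Days absent from the
#' climate series (or with missing flags) are gap days: excluded from counts
#' and means and reported in `n_gap_days`.
#'
#' @param flags Output of [classify_days()].
#' @param climate The climate tibble the flags were derived from.
#' @param hatch_date Hatch date (Date).
#' @param window One row of [stage_windows()] (or a list with `stage`,
#'   `start_offset`, `end_offset`).
#' @return A one-row tibble: `stage, n_days, n_hot, n_cold, n_rain, any_hot,
#'   any_cold, any_rain, mean_temp, mean_rain, n_gap_days`.
#' @export
window_exposure <- function(flags, climate, hatch_date, window) {
  days <- seq(hatch_date + window$start_offset,
              hatch_date + window$end_offset, by = "day")
  f <- flags[match(days, flags$date), ]
  cl <- climate[match(days, climate$date), ]
  gap <- is.na(f$is_hot) | is.na(cl$tmean_c)
  if (all(gap)) {
    abort(glue::glue(
      "window {window$stage} starting {days[1]} lies entirely outside the climate series"
    ))
  }
  n_hot <- sum(f$is_hot[!gap])
  n_cold <- sum(f$is_cold[!gap])
  n_rain <- sum(f$is_rain[!gap])
  tibble(
    stage = window$stage, n_days = length(days),
    n_hot = n_hot, n_cold = n_cold, n_rain = n_rain,
    any_hot = n_hot >= 1, any_cold = n_cold >= 1, any_rain = n_rain >= 1,
    mean_temp = mean(cl$tmean_c[!gap]), mean_rain = mean(cl$rain_mm[!gap]),
    n_gap_days = sum(gap)
  )
}

#' Per-brood, per-stage exposure table
#'
#' Vectorised exposure for a whole brood table: one output row per brood and
#' stage window, with event counts, binary presence, ambient means over
#' non-gap days, and the gap count. Broods whose window has more than
#' `max_gap_frac` gap days are flagged (`gap_excluded`) for exclusion.
#'
#' @param broods A brood tibble with `brood_id` and `hatch_date` columns.
#' @param flags Output of [classify_days()].
#' @param climate The climate tibble the flags were derived from.
#' @param windows A [stage_windows()] tibble.
#' @param max_gap_frac Maximal tolerated fraction of gap days per window.
#' @return A tibble with one row per brood x stage.
#' @export
brood_exposure <- function(broods, flags, climate, windows = stage_windows(),
                           max_gap_frac = 0.25) {
  stopifnot(all(c("brood_id", "hatch_date") %in% names(broods)))
  per_day <- tidyr::expand_grid(
    broods[, c("brood_id", "hatch_date")],
    windows
  ) |>
    mutate(.win_len = .data$end_offset - .data$start_offset + 1L) |>
    tidyr::uncount(.data$.win_len, .id = ".day") |>
    mutate(date = .data$hatch_date + .data$start_offset + .data$.day - 1L) |>
    left_join(flags, by = "date") |>
    left_join(climate[, c("date", "tmean_c", "rain_mm")], by = "date") |>
    mutate(gap = is.na(.data$is_hot) | is.na(.data$tmean_c))

  out <- per_day |>
    group_by(.data$brood_id, .data$stage) |>
    summarise(
      n_days = dplyr::n(),
      n_hot = sum(.data$is_hot[!.data$gap]),
      n_cold = sum(.data$is_cold[!.data$gap]),
      n_rain = sum(.data$is_rain[!.data$gap]),
      mean_temp = mean(.data$tmean_c[!.data$gap]),
      mean_rain = mean(.data$rain_mm[!.data$gap]),
      n_gap_days = sum(.data$gap),
      .groups = "drop"
    ) |>
    mutate(
      any_hot = .data$n_hot >= 1, any_cold = .data$n_cold >= 1,
      any_rain = .data$n_rain >= 1,
      gap_excluded = .data$n_gap_days / .data$n_days > max_gap_frac
    ) |>
    select("brood_id", "stage", "n_days", "n_hot", "n_cold", "n_rain",
           "any_hot", "any_cold", "any_rain", "mean_temp", "mean_rain",
           "n_gap_days", "gap_excluded")
  dead <- out |>
    group_by(.data$brood_id) |>
    summarise(all_gap = any(.data$n_gap_days == .data$n_days), .groups = "drop") |>
    filter(.data$all_gap)
  if (nrow(dead) > 0) {
    abort(glue::glue(
      "brood(s) with a fully-gapped window: {toString(head(dead$brood_id, 5))}"
    ))
  }
  attr(out, "thresholds") <- attr(flags, "thresholds")
  out
}

#' Brood-specific window deviations
#'
#' Sensitivity-analysis variant of the deviation calculation: instead of the
#' calendar-month baseline, each brood's temperature baseline is the long-term
#' mean over its own developmental window extended by `halfwidth` days on each
#' side, taken at the same calendar days (day-of-year) in every year of the
#' series. Window-day deviations are then computed against that scalar.
#'
#' @param climate A validated climate tibble.
#' @param hatch_date Hatch date (Date).
#' @param window One row of [stage_windows()].
#' @param halfwidth Days added on each side of the window (default 15).
#' @return A tibble `date, tmean_c, tdev_c` for the window days; the scalar
#'   baseline is stored in the `baseline` attribute.
#' @export
brood_specific_deviations <- function(climate, hatch_date, window,
                                      halfwidth = 15L) {
  win_days <- seq(hatch_date + window$start_offset,
                  hatch_date + window$end_offset, by = "day")
  ext_days <- seq(min(win_days) - halfwidth, max(win_days) + halfwidth,
                  by = "day")
  doys <- unique(as.integer(format(ext_days, "%j")))
  in_ext <- as.integer(format(climate$date, "%j")) %in% doys
  if (!any(in_ext)) abort("climate series does not cover the extended window")
  n_years <- length(unique(format(climate$date[in_ext], "%Y")))
  if (sum(in_ext) < n_years) {
    abort("insufficient span for a brood-specific baseline")
  }
  baseline <- mean(climate$tmean_c[in_ext])
  idx <- match(win_days, climate$date)
  out <- tibble(
    date = win_days,
    tmean_c = climate$tmean_c[idx],
    tdev_c = climate$tmean_c[idx] - baseline
  )
  attr(out, "baseline") <- baseline
  attr(out, "method") <- "brood_specific"
  out
}

#' Per-brood temperature-event counts under brood-specific baselines
#'
#' Applies the calibrated hot/cold cutoffs to brood-specific deviations
#' (see [brood_specific_deviations()]) for every brood and stage. By default
#' only temperature events are recomputed under this variant; rainfall events
#' keep the monthly-baseline definition.
#'
#' @inheritParams brood_exposure
#' @param thresholds An [calibrate_thresholds()] object supplying the cutoffs.
#' @param halfwidth Days added on each side of each window.
#' @return A tibble `brood_id, stage, n_hot, n_cold, baseline_c`.
#' @export
brood_specific_exposure <- function(broods, climate, thresholds,
                                    windows = stage_windows(),
                                    halfwidth = 15L) {
  stopifnot(inherits(thresholds, "ece_thresholds"))
  # precompute per-day-of-year sums so each brood baseline is an exact mean
  doy_all <- as.integer(format(climate$date, "%j"))
  doy_sum <- tapply(climate$tmean_c, doy_all, sum)
  doy_n <- tapply(climate$tmean_c, doy_all, length)
  lookup_sum <- rep(0, 366); lookup_n <- rep(0, 366)
  lookup_sum[as.integer(names(doy_sum))] <- doy_sum
  lookup_n[as.integer(names(doy_n))] <- doy_n

  rows <- tidyr::expand_grid(broods[, c("brood_id", "hatch_date")], windows)
  res <- purrr::pmap(rows, function(brood_id, hatch_date, stage,
                                    start_offset, end_offset) {
    win <- seq(hatch_date + start_offset, hatch_date + end_offset, by = "day")
    ext <- seq(min(win) - halfwidth, max(win) + halfwidth, by = "day")
    doys <- unique(as.integer(format(ext, "%j")))
    n_days <- sum(lookup_n[doys])
    if (n_days == 0) abort(glue::glue("no climate data for brood {brood_id}"))
    baseline <- sum(lookup_sum[doys]) / n_days
    tdev <- climate$tmean_c[match(win, climate$date)] - baseline
    tibble(
      brood_id = brood_id, stage = stage,
      n_hot = sum(tdev >= thresholds$hot_cut, na.rm = TRUE),
      n_cold = sum(tdev <= thresholds$cold_cut, na.rm = TRUE),
      baseline_c = baseline
    )
  })
  bind_rows(res)
}
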