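#' Read a brood/chick life-history table
#'
#' Reads the two-file breeding schema: a brood file
#' (`brood_id,year,lay_doy,hatch_date,clutch_size,mother_id,nestbox_id`) and a
#' chick file (`chick_id,brood_id,mass_d15_g,recruited`). Records are
#' validated: recruitment must be 0/1, chicks must reference a known brood,
#' clutch sizes must be positive and hatch must follow lay. Broods with a
#' missing hatch date are excluded with a warning and listed in the
#' `excluded` attribute of the brood tibble. If the brood file carries a
#' `first_clutch` column, only first clutches are retained.
#'
#' @param brood_path,chick_path Paths to the two delimited files.
#' @return A list with elements `broods` and `chicks` (tibbles).
#' @export
read_brood_table <- function(brood_path, chick_path) {
  broods <- readr::read_csv(brood_path, show_col_types = FALSE, progress = FALSE)
  chicks <- readr::read_csv(chick_path, show_col_types = FALSE, progress = FALSE)
  need_b <- c("brood_id", "year", "lay_doy", "hatch_date", "clutch_size",
              "mother_id", "nestbox_id")
  need_c <- c("chick_id", "brood_id", "mass_d15_g", "recruited")
  if (!all(need_b %in% names(broods))) {
    abort(glue::glue("brood file missing column(s): {toString(setdiff(need_b, names(broods)))}"))
  }
  if (!all(need_c %in% names(chicks))) {
    abort(glue::glue("chick file missing column(s): {toString(setdiff(need_c, names(chicks)))}"))
  }
  if ("first_clutch" %in% names(broods)) {
    broods <- filter(broods, .data$first_clutch %in% c(1, TRUE))
  }
  broods$hatch_date <- as.Date(broods$hatch_date)
  excluded <- filter(broods, is.na(.data$hatch_date))
  if (nrow(excluded) > 0) {
    warn(glue::glue(
      "{nrow(excluded)} brood(s) excluded for missing hatch date: ",
      "{toString(head(excluded$brood_id, 5))}"
    ))
    broods <- filter(broods, !is.na(.data$hatch_date))
  }
  validate_breeding(broods, chicks)
  attr(broods, "excluded") <- excluded
  list(broods = as_tibble(broods), chicks = as_tibble(chicks))
}

#' Validate brood and chick records
#'
#' @param broods,chicks Brood and chick tibbles in the package schema.
#' @return Invisibly `TRUE`; aborts on an invariant violation.
#' @export
validate_breeding <- function(broods, chicks) {
  if (anyDuplicated(broods$brood_id)) abort("duplicate brood_id")
  if (any(broods$clutch_size < 1, na.rm = TRUE)) abort("clutch_size must be >= 1")
  hatch_doy <- as.integer(format(broods$hatch_date, "%j"))
  if (any(hatch_doy <= broods$lay_doy, na.rm = TRUE)) {
    abort("hatch_date must fall after lay_doy within the season")
  }
  # breeding season plausibility: April-June lay dates (DOY 91-181)
  if (any(broods$lay_doy < 80 | broods$lay_doy > 190, na.rm = TRUE)) {
    warn("lay dates outside the April-June breeding season")
  }
  rec <- chicks$recruited[!is.na(chicks$recruited)]
  if (!all(rec %in% c(0, 1))) {
    abort("`recruited` must be 0 or 1 where present")
  }
  if (any(chicks$mass_d15_g <= 0, na.rm = TRUE)) {
    abort("mass_d15_g must be positive when present")
  }
  orphans <- setdiff(chicks$brood_id, broods$brood_id)
  if (length(orphans) > 0) {
    abort(glue::glue("chick(s) reference unknown brood(s): {toString(head(orphans, 5))}"))
  }
  invisible(TRUE)
}

#' Write brood and chick tables in the package schema
#'
#' @param broods,chicks Tibbles in the package schema.
#' @param brood_path,chick_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_brood_table <- function(broods, chicks, brood_path, chick_path) {
  readr::write_csv(broods, brood_path)
  readr::write_csv(chicks, chick_path)
  invisible(c(brood_path, chick_path))
}

#' Relative lay date within cohort year
#'
#' Adds `rel_lay_date`: each brood's lay day-of-year minus the population
#' average lay date of its cohort year (unweighted over included broods;
#' lay date is a brood property). Negative values are clutches laid earlier
#' than the year's average.
#'
#' @param broods A brood tibble with `year` and `lay_doy`.
#' @param center `"mean"` (default) or `"median"` population average.
#' @return `broods` with an added `rel_lay_date` column.
#' @export
relative_lay_date <- function(broods, center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else median
  broods |>
    group_by(.data$year) |>
    mutate(rel_lay_date = .data$lay_doy - fun(.data$lay_doy)) |>
    ungroup()
}

#' Early/mid/late seasonal percentile groups
#'
#' Labels each brood by its within-year relative lay date: `early` at or
#' below the `low` percentile, `late` at or above the `high` percentile
#' (both cutoffs inclusive; a brood satisfying both is labelled early, and a
#' warning notes the tie). Percentiles use linear interpolation between order
#' statistics. Years with fewer than 3 broods are labelled `mid` with a
#' warning.
#'
#' @param broods A brood tibble; `rel_lay_date` is computed if absent.
#' @param low,high Percentile cutoffs as fractions (defaults 0.15 and 0.85).
#' @return `broods` with an added `lay_group` factor (`early`, `mid`, `late`).
#' @export
percentile_lay_groups <- function(broods, low = 0.15, high = 0.85) {
  if (!"rel_lay_date" %in% names(broods)) {
    broods <- relative_lay_date(broods)
  }
  tiny_years <- broods |> count(.data$year) |> filter(.data$n < 3)
  if (nrow(tiny_years) > 0) {
    warn(glue::glue(
      "year(s) with < 3 broods labelled 'mid': {toString(tiny_years$year)}"
    ))
  }
  out <- broods |>
    group_by(.data$year) |>
    mutate(
      .q_low = quantile(.data$rel_lay_date, low, type = 7),
      .q_high = quantile(.data$rel_lay_date, high, type = 7),
      lay_group = dplyr::case_when(
        dplyr::n() < 3 ~ "mid",
        .data$rel_lay_date <= .data$.q_low ~ "early",
        .data$rel_lay_date >= .data$.q_high ~ "late",
        TRUE ~ "mid"
      ),
      .tied = dplyr::n() >= 3 & .data$rel_lay_date <= .data$.q_low &
        .data$rel_lay_date >= .data$.q_high
    ) |>
    ungroup()
  if (any(out$.tied)) {
    warn(glue::glue(
      "{sum(out$.tied)} brood(s) satisfied both percentile cutoffs; labelled 'early'"
    ))
  }
  out |>
    mutate(lay_group = factor(.data$lay_group, levels = c("early", "mid", "late"))) |>
    select(-".q_low", -".q_high", -".tied")
}

#' Assemble the per-chick analysis table
#'
#' Joins chicks to their broods, attaches both stage windows' exposure
#' records as prefixed columns (`hatchling_n_hot`, ..., `nestling_mean_rain`),
#' and adds relative lay date and seasonal percentile group. No rows are
#' dropped silently: every exclusion (gap-flagged brood, carry-over filter)
#' is recorded in the `exclusions` attribute.
#'
#' @param broods,chicks Brood and chick tibbles.
#' @param exposures Output of [brood_exposure()].
#' @param carry_over_zero Optional event type (`"hot"`, `"cold"`, `"rain"`):
#'   keep only chicks whose brood had zero hatchling-stage events of that
#'   type (the carry-over sensitivity analysis).
#' @param drop_gap_flagged Drop broods whose exposure was gap-flagged.
#' @param center Passed to [relative_lay_date()].
#' @param low,high Passed to [percentile_lay_groups()].
#' @return A per-chick tibble with brood covariates, stage-prefixed exposure
#'   columns, `rel_lay_date` and `lay_group`; exclusions in the `exclusions`
#'   attribute.
#' @export
build_analysis_table <- function(broods, chicks, exposures,
                                 carry_over_zero = NULL,
                                 drop_gap_flagged = TRUE,
                                 center = "mean", low = 0.15, high = 0.85) {
  validate_breeding(broods, chicks)
  missing_exp <- broods |>
    anti_join(distinct(exposures, .data$brood_id), by = "brood_id")
  if (nrow(missing_exp) > 0) {
    abort(glue::glue(
      "no exposure records for brood(s): {toString(head(missing_exp$brood_id, 5))}"
    ))
  }
  stages <- unique(exposures$stage)
  if (!all(c("hatchling", "nestling") %in% stages)) {
    abort("exposures must cover both the hatchling and nestling stages")
  }
  exclusions <- tibble(brood_id = character(), reason = character())

  wide <- exposures |>
    select("brood_id", "stage", "n_hot", "n_cold", "n_rain",
           "any_hot", "any_cold", "any_rain", "mean_temp", "mean_rain",
           "n_gap_days") |>
    tidyr::pivot_wider(
      names_from = "stage",
      values_from = dplyr::all_of(c("n_hot", "n_cold", "n_rain", "any_hot",
                                    "any_cold", "any_rain", "mean_temp",
                                    "mean_rain", "n_gap_days")),
      names_glue = "{stage}_{.value}"
    )
  if (drop_gap_flagged && "gap_excluded" %in% names(exposures)) {
    bad <- unique(exposures$brood_id[exposures$gap_excluded])
    if (length(bad) > 0) {
      exclusions <- bind_rows(exclusions,
                              tibble(brood_id = as.character(bad),
                                     reason = "window gap fraction too high"))
      wide <- filter(wide, !.data$brood_id %in% bad)
    }
  }
  broods_aug <- broods |>
    relative_lay_date(center = center) |>
    percentile_lay_groups(low = low, high = high)
  out <- chicks |>
    inner_join(broods_aug, by = "brood_id") |>
    inner_join(wide, by = "brood_id")
  if (!is.null(carry_over_zero)) {
    carry_over_zero <- match.arg(carry_over_zero, c("hot", "cold", "rain"))
    col <- paste0("hatchling_n_", carry_over_zero)
    dropped <- unique(out$brood_id[out[[col]] > 0])
    if (length(dropped) > 0) {
      exclusions <- bind_rows(exclusions,
                              tibble(brood_id = as.character(dropped),
                                     reason = glue::glue("hatchling {carry_over_zero} carry-over filter")))
    }
    out <- filter(out, .data[[col]] == 0)
  }
  attr(out, "exclusions") <- exclusions
  out
}
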