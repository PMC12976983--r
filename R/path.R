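#' Path-analysis decomposition of a total effect
#'
#' Decomposes the total association between an exposure (lay date) and an
#' outcome (fledging mass) into a direct path and indirect paths carried by
#' mediators (stage temperature, ECE counts), using one least-squares
#' structural equation per endogenous variable on standardized variables:
#' each mediator is regressed on the exposure (path `a`), and the outcome on
#' the exposure plus all mediators (direct path and paths `b`). The indirect
#' effect through a mediator is `a * b`; the total effect is the direct
#' effect plus the sum of indirect effects, and equals the coefficient of
#' the reduced-form regression of outcome on exposure exactly (OLS algebra).
#'
#' @param data A data frame.
#' @param exposure Exposure column name (e.g. `"rel_lay_date"`).
#' @param mediators Character vector of mediator column names.
#' @param outcome Outcome column name (e.g. `"mass_d15_g"`).
#' @return An object of class `ece_path` with elements `paths` (tibble of
#'   standardized coefficients with SEs), `effects` (direct, per-mediator
#'   indirect, total) and `total_reduced` (reduced-form check).
#' @export
fit_path_model <- function(data, exposure, mediators, outcome) {
  vars <- c(exposure, mediators, outcome)
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    abort(glue::glue("data is missing column(s): {toString(missing)}"))
  }
  d <- data[complete.cases(data[, vars]), vars]
  if (any(!purrr::map_lgl(d, is.numeric))) abort("all path variables must be numeric")
  if (any(!is.finite(as.matrix(d)))) abort("non-finite values in path design")
  d <- standardize(as_tibble(d), vars)

  path_row <- function(fit, coef_name, from, to) {
    s <- summary(fit)$coefficients
    tibble(from = from, to = to,
           estimate = s[coef_name, 1], std.error = s[coef_name, 2],
           statistic = s[coef_name, 3], p.value = s[coef_name, 4])
  }

  a_paths <- purrr::map(mediators, function(m) {
    f <- lm(stats::reformulate(exposure, m), data = d)
    path_row(f, exposure, exposure, m)
  }) |> bind_rows()

  out_fit <- lm(stats::reformulate(c(exposure, mediators), outcome), data = d)
  b_paths <- purrr::map(mediators, function(m) {
    path_row(out_fit, m, m, outcome)
  }) |> bind_rows()
  direct <- path_row(out_fit, exposure, exposure, outcome)

  reduced <- lm(stats::reformulate(exposure, outcome), data = d)
  total_reduced <- unname(coef(reduced)[exposure])

  indirect <- tibble(
    mediator = mediators,
    indirect = a_paths$estimate * b_paths$estimate
  )
  total <- direct$estimate + sum(indirect$indirect)

  structure(
    list(
      paths = bind_rows(a_paths, b_paths, direct),
      effects = list(direct = direct$estimate, indirect = indirect,
                     total = total),
      total_reduced = total_reduced,
      exposure = exposure, mediators = mediators, outcome = outcome,
      n = nrow(d)
    ),
    class = "ece_path"
  )
}

#' @export
print.ece_path <- function(x, ...) {
  cat(glue::glue(
    "<ece_path> {x$exposure} -> {x$outcome} via {toString(x$mediators)} (n = {x$n})"
  ), "\n")
  cat(sprintf("  direct %.4f | indirect %s | total %.4f (reduced-form %.4f)\n",
              x$effects$direct,
              paste(sprintf("%.4f", x$effects$indirect$indirect), collapse = ", "),
              x$effects$total, x$total_reduced))
  invisible(x)
}

#' Tidy standardized path coefficients
#'
#' @param x An `ece_path`.
#' @param ... Unused.
#' @return A tibble of the structural-equation paths plus derived indirect
#'   and total effects (derived rows carry `NA` uncertainty columns).
#' @method tidy ece_path
#' @export
tidy.ece_path <- function(x, ...) {
  derived <- bind_rows(
    tibble(from = x$exposure, to = x$outcome,
           estimate = x$effects$indirect$indirect,
           path = paste0("indirect_", x$effects$indirect$mediator)),
    tibble(from = x$exposure, to = x$outcome, estimate = x$effects$total,
           path = "total")
  )
  bind_rows(
    mutate(x$paths, path = "structural"),
    derived
  )
}
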