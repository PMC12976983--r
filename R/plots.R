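#' Coefficient plot for a mixed-model fit
#'
#' Forest plot of the fixed effects (Wald 95% intervals), intercept omitted.
#'
#' @param object An `ece_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ece_fit
#' @export
autoplot.ece_fit <- function(object, ...) {
  d <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = if (isTRUE(object$spec$standardize)) "Estimate (per SD of predictor)"
          else "Estimate",
      y = NULL,
      title = glue::glue("{object$spec$response} ({object$spec$family})")
    ) +
    ggplot2::theme_minimal()
}

#' Predicted response curve over one predictor
#'
#' Population-level predictions with a 95% ribbon across the observed range
#' of one numeric predictor, other covariates held at their means.
#'
#' @param fit An `ece_fit`.
#' @param predictor Column name of a numeric model predictor.
#' @param n Grid size.
#' @return A ggplot object.
#' @export
plot_exposure_response <- function(fit, predictor, n = 50) {
  sc <- fit$scaling
  frame <- stats::model.frame(fit$model, fixed.only = TRUE)
  if (!is.null(sc) && predictor %in% sc$column) {
    i <- match(predictor, sc$column)
    rng <- range(frame[[predictor]], na.rm = TRUE) * sc$sd[i] + sc$mean[i]
  } else if (predictor %in% names(frame)) {
    rng <- range(frame[[predictor]], na.rm = TRUE)
  } else {
    abort(glue::glue("'{predictor}' is not a model predictor"))
  }
  grid <- tibble(!!predictor := seq(rng[1], rng[2], length.out = n))
  pred <- predict_response(fit, grid)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data[[predictor]], y = .data$.fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.lower, ymax = .data$.upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = predictor,
                  y = if (fit$spec$family == "binomial") "Predicted probability"
                      else fit$spec$response) +
    ggplot2::theme_minimal()
}

#' Effect-decomposition plot for a path analysis
#'
#' Bars for the direct, per-mediator indirect and total standardized
#' effects of the exposure on the outcome.
#'
#' @param object An `ece_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ece_path
#' @export
autoplot.ece_path <- function(object, ...) {
  d <- bind_rows(
    tibble(component = "direct", estimate = object$effects$direct),
    tibble(component = paste0("via ", object$effects$indirect$mediator),
           estimate = object$effects$indirect$indirect),
    tibble(component = "total", estimate = object$effects$total)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = NULL, y = "Standardized effect",
      title = glue::glue("{object$exposure} -> {object$outcome}")
    ) +
    ggplot2::theme_minimal()
}
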