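#' Centre and scale predictor columns
#'
#' Scales each named column to mean 0 and sample standard deviation 1
#' (denominator n - 1), recording the means and SDs in the `scaling`
#' attribute so estimates and predictions can be mapped back to natural
#' units.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric, non-constant columns.
#' @return `data` with the columns scaled; scaling metadata in the
#'   `scaling` attribute (a tibble `column, mean, sd`).
#' @export
standardize <- function(data, columns) {
  meta <- purrr::map(columns, function(col) {
    x <- data[[col]]
    if (is.null(x)) abort(glue::glue("column '{col}' not found"))
    if (!is.numeric(x)) abort(glue::glue("column '{col}' is not numeric"))
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(glue::glue("column '{col}' is constant; cannot standardize"))
    }
    tibble(column = col, mean = mean(x, na.rm = TRUE), sd = s)
  }) |> bind_rows()
  for (i in seq_len(nrow(meta))) {
    col <- meta$column[i]
    data[[col]] <- (data[[col]] - meta$mean[i]) / meta$sd[i]
  }
  attr(data, "scaling") <- meta
  data
}

#' Invert a standardization
#'
#' @param data Output of [standardize()] (or any data frame plus an explicit
#'   `scaling` tibble).
#' @param scaling Scaling metadata; defaults to the attribute on `data`.
#' @return The data frame on the original scale.
#' @export
unstandardize <- function(data, scaling = attr(data, "scaling")) {
  if (is.null(scaling)) abort("no scaling metadata found")
  for (i in seq_len(nrow(scaling))) {
    col <- scaling$column[i]
    data[[col]] <- data[[col]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(data, "scaling") <- NULL
  data
}

#' Natural cubic spline basis
#'
#' Restricted (natural) cubic spline basis with boundary knots at the range
#' of `x` and `df - 1` interior knots at equally spaced quantiles, as used
#' for the ambient-temperature terms. Fitted combinations are linear beyond
#' the boundary knots.
#'
#' @param x Numeric vector.
#' @param df Number of basis columns (>= 3).
#' @return An `n x df` basis matrix with knot attributes.
#' @export
natural_spline_basis <- function(x, df = 5L) {
  if (df < 3) abort("spline df must be >= 3")
  if (length(unique(x[!is.na(x)])) < df) {
    abort(glue::glue("need at least {df} distinct values for a df={df} spline"))
  }
  splines::ns(x, df = df)
}

# ---- model term constructors ------------------------------------------------

#' Model term constructors
#'
#' Build the fixed-effect term list of a [design_spec()]. `term_linear()` is
#' a plain slope; `term_spline()` a natural cubic spline (see
#' [natural_spline_basis()]); `term_categorical()` a factor (e.g. grouped ECE
#' counts, reference level first); `term_interaction()` a product of two
#' columns; `term_quadratic_interaction()` the product of one column squared
#' with another (used for the accelerating rain-by-lay-date response).
#' Interaction terms contribute the product only; list the main effects
#' separately.
#'
#' @param column,a,b Column names in the analysis table.
#' @param df Spline degrees of freedom.
#' @return A term object (internal list).
#' @name model-terms
NULL

#' @rdname model-terms
#' @export
term_linear <- function(column) {
  structure(list(kind = "linear", column = column), class = "ece_term")
}

#' @rdname model-terms
#' @export
term_spline <- function(column, df = 5L) {
  if (df < 3) abort("spline df must be >= 3")
  structure(list(kind = "spline", column = column, df = as.integer(df)),
            class = "ece_term")
}

#' @rdname model-terms
#' @export
term_categorical <- function(column) {
  structure(list(kind = "categorical", column = column), class = "ece_term")
}

#' @rdname model-terms
#' @export
term_interaction <- function(a, b) {
  structure(list(kind = "interaction", a = a, b = b), class = "ece_term")
}

#' @rdname model-terms
#' @export
term_quadratic_interaction <- function(a, b) {
  structure(list(kind = "quadratic_interaction", a = a, b = b),
            class = "ece_term")
}

term_label <- function(t) {
  switch(t$kind,
    linear = t$column,
    spline = glue::glue("splines::ns({t$column}, df = {t$df})"),
    categorical = t$column,
    interaction = glue::glue("{t$a}:{t$b}"),
    quadratic_interaction = glue::glue("I({t$a}^2):{t$b}")
  )
}

term_columns <- function(t) {
  switch(t$kind,
    linear = t$column, spline = t$column, categorical = t$column,
    interaction = c(t$a, t$b), quadratic_interaction = c(t$a, t$b)
  )
}

#' Specify a mixed model
#'
#' A declarative model specification: response, family, ordered fixed terms
#' (see [model-terms]) and crossed random intercepts. With
#' `standardize = TRUE` (the default, matching the reporting convention of
#' effect sizes in SD units) all numeric predictor columns entering fixed
#' terms are scaled to mean 0, SD 1 before fitting, and the scaling metadata
#' is stored in the fit.
#'
#' @param response Response column (`mass_d15_g` or `recruited`).
#' @param family `"gaussian"` or `"binomial"`.
#' @param fixed List of term objects.
#' @param random Character vector of grouping columns for random intercepts
#'   (default: year, brood, mother, nestbox).
#' @param standardize Scale numeric predictors before fitting?
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(response,
                        family = c("gaussian", "binomial"),
                        fixed,
                        random = c("year", "brood_id", "mother_id", "nestbox_id"),
                        standardize = TRUE) {
  family <- match.arg(family)
  # an empty fixed list gives an intercept-only model
  stopifnot(is.list(fixed),
            all(purrr::map_lgl(fixed, inherits, "ece_term")))
  cols <- unique(unlist(purrr::map(fixed, term_columns)))
  if (response %in% cols) {
    abort("the response may not appear among the predictors")
  }
  structure(
    list(response = response, family = family, fixed = fixed,
         random = random, standardize = standardize),
    class = "design_spec"
  )
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed) == 0) "1" else {
    paste(purrr::map_chr(spec$fixed, term_label), collapse = " + ")
  }
  ran <- paste(glue::glue("(1 | {spec$random})"), collapse = " + ")
  as.formula(paste(spec$response, "~", rhs, "+", ran))
}

prepare_model_data <- function(data, spec) {
  cols <- unique(unlist(purrr::map(spec$fixed, term_columns)))
  cat_cols <- unique(unlist(purrr::map(
    purrr::keep(spec$fixed, ~ .x$kind == "categorical"), term_columns)))
  num_cols <- setdiff(cols[purrr::map_lgl(cols, ~ is.numeric(data[[.x]]))],
                      cat_cols)
  missing <- setdiff(c(cols, spec$response, spec$random), names(data))
  if (length(missing) > 0) {
    abort(glue::glue("data is missing column(s): {toString(missing)}"))
  }
  for (g in spec$random) data[[g]] <- factor(data[[g]])
  keep <- complete.cases(data[, c(spec$response, cols)])
  data <- data[keep, , drop = FALSE]
  scaling <- NULL
  if (spec$standardize && length(num_cols) > 0) {
    data <- standardize(data, num_cols)
    scaling <- attr(data, "scaling")
  }
  list(data = data, scaling = scaling, n_dropped = sum(!keep))
}

wald_coefs <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se), conf.high = unname(est + z * se)
  )
}

varcomp_table <- function(model) {
  vc <- lme4::VarCorr(model)
  out <- purrr::imap(vc, function(m, g) {
    tibble(group = g, variance = unname(m[1, 1]), sd = sqrt(unname(m[1, 1])))
  }) |> bind_rows()
  if (lme4::isLMM(model)) {
    out <- bind_rows(out, tibble(group = "Residual",
                                 variance = stats::sigma(model)^2,
                                 sd = stats::sigma(model)))
  }
  out
}

new_ece_fit <- function(model, spec, scaling, n_dropped, converged, notes) {
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  structure(
    list(
      model = model, spec = spec,
      coefficients = wald_coefs(fe, se),
      varcomp = varcomp_table(model),
      logLik = as.numeric(logLik(model)),
      nobs = stats::nobs(model),
      n_dropped = n_dropped,
      scaling = scaling,
      converged = converged,
      notes = notes
    ),
    class = "ece_fit"
  )
}

check_convergence <- function(model) {
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  warns <- unlist(model@optinfo$warnings)
  notes <- c(msgs, warns)
  list(converged = length(msgs) == 0 && model@optinfo$conv$opt == 0,
       notes = if (length(notes) > 0) as.character(notes) else character())
}

check_rank <- function(model, data, spec) {
  form <- lme4::nobars(spec_formula(spec))
  X <- model.matrix(form, data)
  kept <- colnames(model.matrix(model))
  aliased <- setdiff(colnames(X), kept)
  if (length(aliased) > 0) {
    abort(glue::glue(
      "design is rank deficient; aliased column(s): {toString(aliased)}"
    ))
  }
}

#' Fit a linear mixed model for fledging mass
#'
#' REML fit of a Gaussian mixed model with crossed random intercepts,
#' following the declarative [design_spec()]. Inference on fixed effects is
#' Wald with a standard-normal reference (estimate, SE, z, p, 95% CI).
#' Non-convergence is flagged on the result, never thrown.
#'
#' @param data An analysis table (see [build_analysis_table()]).
#' @param spec A [design_spec()] with `family = "gaussian"`.
#' @param REML Use REML (default) or ML. ML is needed for likelihood
#'   comparisons between fixed-effect structures.
#' @return An object of class `ece_fit`; see [tidy.ece_fit()] and
#'   [glance.ece_fit()].
#' @export
fit_lmm <- function(data, spec, REML = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$family != "gaussian") abort("fit_lmm() requires a gaussian spec")
  prep <- prepare_model_data(data, spec)
  for (g in spec$random) {
    if (length(unique(prep$data[[g]])) < 2) {
      abort(glue::glue("random factor '{g}' has fewer than 2 levels"))
    }
  }
  model <- suppressMessages(suppressWarnings(
    lme4::lmer(spec_formula(spec), data = prep$data, REML = REML,
               control = lme4::lmerControl(calc.derivs = FALSE))
  ))
  check_rank(model, prep$data, spec)
  conv <- check_convergence(model)
  new_ece_fit(model, spec, prep$scaling, prep$n_dropped,
              conv$converged, conv$notes)
}

#' Fit a binomial mixed model for recruitment
#'
#' Maximum-likelihood (Laplace) fit of a logistic mixed model with crossed
#' random intercepts, with Wald z inference. Suspected complete separation
#' (huge estimates with huge standard errors) is flagged in `notes`, never
#' thrown.
#'
#' @inheritParams fit_lmm
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points; the
#'   default 1 is the Laplace approximation (required for crossed factors).
#' @return An `ece_fit`.
#' @export
fit_glmm_binomial <- function(data, spec, nAGQ = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$family != "binomial") abort("fit_glmm_binomial() requires a binomial spec")
  if (!all(data[[spec$response]] %in% c(0, 1, NA))) {
    abort("binomial response must be 0/1")
  }
  prep <- prepare_model_data(data, spec)
  model <- suppressMessages(suppressWarnings(
    lme4::glmer(spec_formula(spec), data = prep$data, family = stats::binomial(),
                nAGQ = nAGQ)
  ))
  check_rank(model, prep$data, spec)
  conv <- check_convergence(model)
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  notes <- conv$notes
  if (any(abs(fe) > 10 & se > 20)) {
    notes <- c(notes, "possible complete separation: inflated estimate and SE")
  }
  new_ece_fit(model, spec, prep$scaling, prep$n_dropped, conv$converged, notes)
}

#' @export
print.ece_fit <- function(x, ...) {
  form <- paste(trimws(deparse(spec_formula(x$spec))), collapse = " ")
  cat(glue::glue(
    "<ece_fit> {x$spec$family} | {form} | ",
    "n = {x$nobs} | converged: {x$converged}"
  ), "\n\nFixed effects (Wald, normal reference):\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  cat("\nRandom-intercept components:\n")
  print(as.data.frame(x$varcomp), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy fixed effects of a mixed-model fit
#'
#' @param x An `ece_fit`.
#' @param effects `"fixed"` (default) or `"ran_pars"` for variance components.
#' @param ... Unused.
#' @return A tibble in broom convention (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`).
#' @method tidy ece_fit
#' @export
tidy.ece_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coefficients else x$varcomp
}

#' One-row model summary
#'
#' @param x An `ece_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample size, log-likelihood, residual SD
#'   (Gaussian) and the convergence flag.
#' @method glance ece_fit
#' @export
glance.ece_fit <- function(x, ...) {
  tibble(
    nobs = x$nobs, logLik = x$logLik,
    sigma = if (lme4::isLMM(x$model)) stats::sigma(x$model) else NA_real_,
    n_random = length(x$spec$random),
    converged = x$converged,
    standardized = x$spec$standardize
  )
}

#' Group event counts into an ordered categorical variable
#'
#' Counts at or above `cap` are pooled into a single `"cap+"` level, so rare
#' high exposures contrast against zero events with adequate sample size.
#' The reference level is `"0"`; unused levels are dropped, so with a cap
#' above the observed maximum the categories equal the observed counts.
#'
#' @param counts Non-negative integer vector.
#' @param cap Pooling threshold (>= 1).
#' @return A factor with levels `0, 1, ..., cap-1, "cap+"` (observed ones).
#' @export
categorize_ece_counts <- function(counts, cap = 4L) {
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be >= 0")
  if (cap < 1) abort("cap must be >= 1")
  lab <- if_else(counts >= cap, paste0(cap, "+"), as.character(counts))
  lev <- c(as.character(0:(cap - 1)), paste0(cap, "+"))
  droplevels(factor(lab, levels = lev))
}

#' Variance inflation factors
#'
#' Generalized VIF per fixed term: for single-column terms this is the
#' classic 1 / (1 - R^2) of the auxiliary regression of that column on the
#' others; multi-column terms (splines, factors) get the Fox-Monette
#' determinant generalization together with `gvif^(1/(2 df))`. Perfect
#' collinearity is reported as `Inf`, not thrown.
#'
#' @param data A data frame holding the predictor columns.
#' @param fixed List of term objects (see [model-terms]); at least 2.
#' @return A tibble `term, df, gvif, gvif_scaled`.
#' @export
vif <- function(data, fixed) {
  stopifnot(length(fixed) >= 2)
  blocks <- purrr::map(fixed, function(t) {
    m <- switch(t$kind,
      linear = cbind(as.numeric(data[[t$column]])),
      spline = unclass(natural_spline_basis(data[[t$column]], t$df)),
      categorical = {
        f <- factor(data[[t$column]])
        model.matrix(~f)[, -1, drop = FALSE]
      },
      interaction = cbind(as.numeric(data[[t$a]]) * as.numeric(data[[t$b]])),
      quadratic_interaction = cbind(as.numeric(data[[t$a]])^2 *
                                      as.numeric(data[[t$b]]))
    )
    colnames(m) <- paste0(term_label(t), seq_len(ncol(m)))
    m
  })
  X <- do.call(cbind, blocks)
  R <- suppressWarnings(cor(X))
  if (any(!is.finite(R))) abort("constant column in VIF design")
  detR <- det(R)
  idx <- rep(seq_along(blocks), purrr::map_int(blocks, ncol))
  purrr::imap(fixed, function(t, j) {
    own <- idx == j
    g <- if (detR <= 1e-12) {
      Inf
    } else {
      det(R[own, own, drop = FALSE]) *
        det(R[!own, !own, drop = FALSE]) / detR
    }
    tibble(term = as.character(term_label(t)), df = sum(own), gvif = g,
           gvif_scaled = g^(1 / (2 * sum(own))))
  }) |> bind_rows()
}

#' Model predictions over a covariate grid
#'
#' Fixed-effect (population-level) predictions with delta-method 95%
#' intervals. Grid columns are given in natural units and standardized with
#' the scaling stored in the fit; covariates absent from the grid are held
#' at their training means (standardized 0) or at the factor reference
#' level. Binomial predictions are inverse-linked, with the interval
#' transformed from the logit scale.
#'
#' @param fit An `ece_fit`.
#' @param grid A data frame of covariate values.
#' @return `grid` with `.fitted`, `.se`, `.lower`, `.upper` columns.
#' @export
predict_response <- function(fit, grid) {
  spec <- fit$spec
  grid <- as_tibble(grid)
  tt <- delete.response(terms(fit$model, fixed.only = TRUE))
  needed <- all.vars(tt)
  unknown <- setdiff(names(grid), needed)
  if (length(unknown) > 0) {
    abort(glue::glue("grid column(s) not in the model: {toString(unknown)}"))
  }
  frame <- stats::model.frame(fit$model, fixed.only = TRUE)
  xlev <- stats::.getXlevels(terms(fit$model, fixed.only = TRUE), frame)
  full <- grid
  scaling <- fit$scaling
  if (!is.null(scaling)) {
    for (i in seq_len(nrow(scaling))) {
      col <- scaling$column[i]
      if (col %in% names(full)) {
        full[[col]] <- (full[[col]] - scaling$mean[i]) / scaling$sd[i]
      }
    }
  }
  for (col in setdiff(needed, names(full))) {
    if (col %in% names(xlev)) {
      full[[col]] <- factor(xlev[[col]][1], levels = xlev[[col]])
    } else {
      full[[col]] <- 0
    }
  }
  X <- model.matrix(tt, data = full, xlev = xlev)
  beta <- lme4::fixef(fit$model)
  X <- X[, names(beta), drop = FALSE]
  eta <- unname(drop(X %*% beta))
  se <- unname(sqrt(rowSums((X %*% as.matrix(vcov(fit$model))) * X)))
  lo <- eta - 1.96 * se
  hi <- eta + 1.96 * se
  if (spec$family == "binomial") {
    grid$.fitted <- plogis(eta)
    grid$.se <- se * plogis(eta) * (1 - plogis(eta))
    grid$.lower <- plogis(lo)
    grid$.upper <- plogis(hi)
  } else {
    grid$.fitted <- eta
    grid$.se <- se
    grid$.lower <- lo
    grid$.upper <- hi
  }
  grid
}
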