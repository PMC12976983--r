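test_that("standardization centres, scales, records metadata and inverts", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(10, 20, 40))
  s <- standardize(d, c("x", "y"))
  expect_equal(s$x, c(-1, 0, 1))
  sc <- attr(s, "scaling")
  expect_equal(sc$mean[sc$column == "x"], 2)
  expect_equal(sc$sd[sc$column == "x"], 1)
  expect_lt(abs(mean(s$y)), 1e-12)
  expect_equal(sd(s$y), 1, tolerance = 1e-12)
  back <- unstandardize(s)
  expect_equal(back$x, d$x, tolerance = 1e-12)
  expect_equal(back$y, d$y, tolerance = 1e-12)
  expect_error(standardize(tibble::tibble(z = rep(1, 5)), "z"), "constant")
  expect_error(standardize(d, "missing"), "not found")
})

test_that("natural spline basis has the requested dimension and guards input", {
  x <- seq(0, 10, length.out = 200)
  b <- natural_spline_basis(x, df = 5)
  expect_equal(ncol(b), 5)
  expect_equal(nrow(b), 200)
  expect_error(natural_spline_basis(rep(1:3, 10), df = 5), "distinct values")
  expect_error(natural_spline_basis(x, df = 2), ">= 3")
})

test_that("spline fits match an independent truncated-power construction", {
  set.seed(61)
  x <- sort(runif(300, 0, 10))
  y <- sin(x) + rnorm(300, 0, 0.3)
  f_ns <- lm(y ~ natural_spline_basis(x, df = 4))
  knots <- c(min(x), unname(quantile(x, c(1, 2, 3) / 4)), max(x))
  f_tp <- lm(y ~ rcs_truncated_power(x, knots))
  expect_lt(max(abs(fitted(f_ns) - fitted(f_tp))), 1e-8)
})

test_that("fitted spline curves are linear beyond the boundary knots", {
  set.seed(62)
  x <- runif(400, 2, 8)
  y <- cos(x) + rnorm(400, 0.2)
  fit <- lm(y ~ splines::ns(x, df = 5))
  grid <- seq(9, 12, by = 0.05)  # beyond the upper boundary knot
  pred <- predict(fit, newdata = data.frame(x = grid))
  d2 <- diff(pred, differences = 2) / 0.05^2
  expect_lt(max(abs(d2)), 1e-6)
  grid <- seq(-2, 1.5, by = 0.05)
  pred <- predict(fit, newdata = data.frame(x = grid))
  d2 <- diff(pred, differences = 2) / 0.05^2
  expect_lt(max(abs(d2)), 1e-6)
})

make_lmm_data <- function(n_group = 40, per_group = 8, ranef_sd = 0.5,
                          seed = 63, beta = c(x1 = 0.5, x2 = -0.3),
                          resid_sd = 1) {
  set.seed(seed)
  n <- n_group * per_group
  g1 <- rep(sprintf("g%02d", 1:n_group), each = per_group)
  g2 <- sample(sprintf("h%02d", 1:n_group), n, replace = TRUE)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- beta[["x1"]] * x1 + beta[["x2"]] * x2 +
    ranef_draw_test(g1, ranef_sd) + ranef_draw_test(g2, ranef_sd) +
    rnorm(n, 0, resid_sd)
  tibble::tibble(y = y, x1 = x1, x2 = x2, g1 = g1, g2 = g2)
}

ranef_draw_test <- function(ids, sd) {
  lev <- unique(ids)
  u <- rnorm(length(lev), 0, sd)
  u[match(ids, lev)]
}

test_that("with zero random-effect variance the LMM equals ordinary least squares", {
  d <- make_lmm_data(ranef_sd = 0, seed = 64)
  spec <- design_spec("y", "gaussian",
                      fixed = list(term_linear("x1"), term_linear("x2")),
                      random = c("g1", "g2"), standardize = FALSE)
  fit <- fit_lmm(d, spec)
  ols <- lm(y ~ x1 + x2, data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("standardized estimates equal raw estimates times the predictor SD", {
  d <- make_lmm_data(seed = 65)
  d$x1 <- d$x1 * 3 + 10  # give the predictors non-trivial scales
  spec_raw <- design_spec("y", "gaussian",
                          fixed = list(term_linear("x1"), term_linear("x2")),
                          random = c("g1", "g2"), standardize = FALSE)
  spec_std <- design_spec("y", "gaussian",
                          fixed = list(term_linear("x1"), term_linear("x2")),
                          random = c("g1", "g2"), standardize = TRUE)
  raw <- fit_lmm(d, spec_raw)
  std <- fit_lmm(d, spec_std)
  b_raw <- raw$coefficients$estimate[raw$coefficients$term == "x1"]
  b_std <- std$coefficients$estimate[std$coefficients$term == "x1"]
  expect_equal(b_std, b_raw * sd(d$x1), tolerance = 1e-6)
  expect_false(is.null(std$scaling))
  expect_null(raw$scaling)
})

test_that("adding a superfluous predictor never lowers the ML log-likelihood", {
  d <- make_lmm_data(seed = 66)
  set.seed(67)
  d$junk <- rnorm(nrow(d))
  base <- design_spec("y", "gaussian", fixed = list(term_linear("x1")),
                      random = c("g1", "g2"))
  bigger <- design_spec("y", "gaussian",
                        fixed = list(term_linear("x1"), term_linear("junk")),
                        random = c("g1", "g2"))
  expect_gte(fit_lmm(d, bigger, REML = FALSE)$logLik,
             fit_lmm(d, base, REML = FALSE)$logLik - 1e-8)
})

test_that("rank-deficient designs name the aliased term", {
  d <- make_lmm_data(seed = 68)
  d$x1_copy <- d$x1
  spec <- design_spec("y", "gaussian",
                      fixed = list(term_linear("x1"), term_linear("x1_copy")),
                      random = c("g1", "g2"), standardize = FALSE)
  expect_error(fit_lmm(d, spec), "rank deficient.*x1_copy")
})

test_that("event counts are pooled into capped categories with reference 0", {
  got <- categorize_ece_counts(c(0, 1, 4, 6), cap = 4)
  expect_equal(as.character(got), c("0", "1", "4+", "4+"))
  expect_equal(levels(got)[1], "0")
  # cap above the maximum leaves observed counts as the categories
  got <- categorize_ece_counts(c(0, 1, 2), cap = 10)
  expect_equal(levels(got), c("0", "1", "2"))
  # sizes are conserved
  x <- rpois(500, 1.5)
  expect_equal(sum(table(categorize_ece_counts(x, 3))), 500)
  expect_error(categorize_ece_counts(c(-1, 2), 3), ">= 0")
})

test_that("variance inflation factors match auxiliary regressions and car::vif", {
  set.seed(71)
  n <- 400
  d <- tibble::tibble(
    a = rnorm(n),
    b = rnorm(n)
  )
  d$c <- 0.7 * d$a + 0.5 * d$b + rnorm(n, 0, 0.6)
  terms <- list(term_linear("a"), term_linear("b"), term_linear("c"))
  got <- vif(d, terms)
  # single-column terms: classic 1 / (1 - R^2) from the auxiliary regression
  for (v in c("a", "b", "c")) {
    others <- setdiff(c("a", "b", "c"), v)
    r2 <- summary(lm(stats::reformulate(others, v), data = d))$r.squared
    expect_equal(got$gvif[got$term == v], 1 / (1 - r2), tolerance = 1e-8)
  }
  # cross-check against car's generalized VIF, including a factor term
  d$f <- factor(sample(letters[1:3], n, TRUE))
  d$y <- rnorm(n)
  got2 <- vif(d, list(term_linear("a"), term_linear("c"), term_categorical("f")))
  ref <- car::vif(lm(y ~ a + c + f, data = d))
  expect_equal(got2$gvif, unname(ref[, "GVIF"]), tolerance = 1e-8)
  # orthogonal design: all exactly 1
  p <- poly(seq_len(n), 2)
  d2 <- tibble::tibble(u = p[, 1], v = p[, 2])
  gotu <- vif(d2, list(term_linear("u"), term_linear("v")))
  expect_equal(gotu$gvif, c(1, 1), tolerance = 1e-10)
  # perfect collinearity reported as infinite, not an error
  d$a_copy <- d$a
  inf <- vif(d, list(term_linear("a"), term_linear("a_copy")))
  expect_true(all(is.infinite(inf$gvif)))
})

test_that("binomial mixed models: balanced data, recovery of direction, separation flag", {
  set.seed(72)
  n <- 2000
  d <- tibble::tibble(
    g = sample(sprintf("g%02d", 1:30), n, replace = TRUE),
    x = rnorm(n)
  )
  d$r <- rbinom(n, 1, plogis(0.8 * d$x))
  spec <- design_spec("r", "binomial", fixed = list(term_linear("x")),
                      random = "g", standardize = FALSE)
  fit <- fit_glmm_binomial(d, spec)
  b <- fit$coefficients
  expect_equal(b$estimate[b$term == "x"], 0.8,
               tolerance = 3 * b$std.error[b$term == "x"] / 0.8)
  # intercept-only on balanced outcomes sits at logit ~ 0
  d$r <- rep_len(c(0, 1), n)
  fit0 <- fit_glmm_binomial(d, design_spec("r", "binomial", fixed = list(),
                                           random = "g"))
  expect_lt(abs(fit0$coefficients$estimate[1]), 0.1)
  expect_error(
    fit_glmm_binomial(dplyr::mutate(d, r = r + 1), spec), "0/1")
})

test_that("population-level predictions behave over grids", {
  d <- make_lmm_data(seed = 73)
  spec <- design_spec("y", "gaussian",
                      fixed = list(term_linear("x1"), term_linear("x2")),
                      random = c("g1", "g2"))
  fit <- fit_lmm(d, spec)
  # covariates at their means reproduce the intercept
  at_mean <- predict_response(fit, tibble::tibble(x1 = mean(d$x1)))
  expect_equal(at_mean$.fitted,
               fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"],
               tolerance = 1e-8)
  # a single positive slope gives monotone predictions
  grid <- predict_response(fit, tibble::tibble(x1 = seq(-2, 2, length.out = 11)))
  expect_true(all(diff(grid$.fitted) > 0))
  expect_true(all(grid$.upper > grid$.fitted & grid$.fitted > grid$.lower))
  expect_error(predict_response(fit, tibble::tibble(bogus = 1)),
               "not in the model")
  # binomial intercept-only on ~50% data predicts ~0.5
  set.seed(74)
  db <- tibble::tibble(g = sample(sprintf("g%02d", 1:20), 1500, replace = TRUE),
                       r = rbinom(1500, 1, 0.5))
  fitb <- fit_glmm_binomial(db, design_spec("r", "binomial", fixed = list(),
                                            random = "g"))
  pb <- predict_response(fitb, tibble::tibble(.rows = 1))
  expect_equal(pb$.fitted, 0.5, tolerance = 0.06)
})
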