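test_that("degenerate and short deviation series are handled in calibration", {
  dev <- make_deviations(rep(2.5, 200), rep(2.5, 200))
  th <- calibrate_thresholds(dev, 0.05)
  expect_equal(th$hot_cut, 2.5)
  expect_equal(th$cold_cut, 2.5)
  expect_equal(th$rain_cut, 2.5)

  expect_error(calibrate_thresholds(make_deviations(rnorm(50), rnorm(50))),
               ">= 100")
  expect_error(calibrate_thresholds(dev, 0.6), "between 0 and 0.5")
  expect_error(calibrate_thresholds(dev, 0), "between 0 and 0.5")
})

test_that("calibrated cutoffs match closed-form normal quantiles", {
  set.seed(101)
  n <- 2e5
  dev <- make_deviations(rnorm(n) * 2, rnorm(n))
  th5 <- calibrate_thresholds(dev, 0.05)
  th1 <- calibrate_thresholds(dev, 0.01)
  expect_equal(th5$hot_cut, 2 * qnorm(0.95), tolerance = 0.02)
  expect_equal(th5$cold_cut, -2 * qnorm(0.95), tolerance = 0.02)
  expect_equal(th5$rain_cut, qnorm(0.95), tolerance = 0.02)
  expect_equal(th1$hot_cut, 2 * qnorm(0.99), tolerance = 0.02)
  # smaller tail never shrinks the cutoffs
  expect_gte(th1$hot_cut, th5$hot_cut)
  expect_lte(th1$cold_cut, th5$cold_cut)
  expect_gte(th1$rain_cut, th5$rain_cut)
})

test_that("day classification is inclusive and matches a per-day loop", {
  dev <- make_deviations(c(4.52, 4.51, -4.49, 0, 10), c(0, 6.2, 6.19, 0, 20))
  th <- structure(list(tail_prob = 0.05, hot_cut = 4.52, cold_cut = -4.49,
                       rain_cut = 6.2, calibration_span = range(dev$date),
                       baseline_mode = "calendar_month_longterm",
                       quantile_rule = "linear_interpolation_type7",
                       n_days = 5L),
                  class = "ece_thresholds")
  fl <- classify_days(dev, th)
  expect_identical(fl$is_hot, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(fl$is_cold, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(fl$is_rain, c(FALSE, TRUE, FALSE, FALSE, TRUE))

  # zero deviations produce no flags under positive cutoffs
  zero <- make_deviations(rep(0, 120), rep(0, 120))
  th0 <- calibrate_thresholds(make_deviations(rnorm(500), abs(rnorm(500))))
  expect_false(any(classify_days(zero, th0)$is_hot))

  # brute-force comparison on a random series
  set.seed(8)
  rdev <- make_deviations(rnorm(400, sd = 3), rnorm(400, sd = 4))
  th <- calibrate_thresholds(rdev, 0.05)
  fl <- classify_days(rdev, th)
  for (i in seq_len(nrow(rdev))) {
    expect_identical(fl$is_hot[i], rdev$tdev_c[i] >= th$hot_cut)
    expect_identical(fl$is_cold[i], rdev$tdev_c[i] <= th$cold_cut)
    expect_identical(fl$is_rain[i], rdev$raindev_mm[i] >= th$rain_cut)
  }
})

test_that("window exposure counts consecutive events separately and handles gaps", {
  cl <- make_climate(seq(as.Date("2001-05-01"), as.Date("2001-05-31"), by = "day"),
                     tmean = 10, rain = 0)
  dev <- make_deviations(rep(0, 31), rep(0, 31), dates = cl$date)
  dev$tdev_c[5:8] <- 6  # four consecutive hot days
  th <- structure(list(tail_prob = 0.05, hot_cut = 5, cold_cut = -5,
                       rain_cut = 5, calibration_span = range(cl$date),
                       baseline_mode = "calendar_month_longterm",
                       quantile_rule = "linear_interpolation_type7",
                       n_days = 31L),
                  class = "ece_thresholds")
  fl <- classify_days(dev, th)
  win <- list(stage = "hatchling", start_offset = 0L, end_offset = 7L)
  ex <- window_exposure(fl, cl, as.Date("2001-05-01"), win)
  expect_equal(ex$n_hot, 4)
  expect_true(ex$any_hot)
  expect_equal(ex$n_cold, 0)
  expect_false(ex$any_cold)
  expect_equal(ex$n_gap_days, 0)

  # window sticking out of the series records gap days; fully outside errors
  late <- window_exposure(fl, cl, as.Date("2001-05-26"), win)
  expect_equal(late$n_gap_days, 2)
  expect_error(window_exposure(fl, cl, as.Date("2002-05-01"), win),
               "outside the climate series")
})

test_that("vectorised brood exposure equals a brute-force day loop", {
  cl <- make_seasonal_climate(2000:2005, seed = 12)
  bl <- compute_monthly_baseline(cl)
  dev <- compute_deviations(cl, bl)
  th <- calibrate_thresholds(dev)
  fl <- classify_days(dev, th)
  set.seed(13)
  n <- 500
  broods <- tibble::tibble(
    brood_id = sprintf("b%03d", seq_len(n)),
    hatch_date = sample(seq(as.Date("2000-04-20"), as.Date("2005-06-10"),
                            by = "day"), n, replace = TRUE)
  )
  got <- brood_exposure(broods, fl, cl)
  wins <- stage_windows()
  for (i in sample(n, 60)) {
    for (w in 1:2) {
      days <- broods$hatch_date[i] + (wins$start_offset[w]:wins$end_offset[w])
      nh <- nc <- nr <- 0
      for (d in days) {
        j <- which(fl$date == d)
        if (length(j) == 1 && !is.na(fl$is_hot[j])) {
          nh <- nh + fl$is_hot[j]; nc <- nc + fl$is_cold[j]
          nr <- nr + fl$is_rain[j]
        }
      }
      row <- got[got$brood_id == broods$brood_id[i] & got$stage == wins$stage[w], ]
      expect_equal(row$n_hot, nh)
      expect_equal(row$n_cold, nc)
      expect_equal(row$n_rain, nr)
    }
  }
})

test_that("exposure invariants: nesting, monotonicity, binaries, stage additivity", {
  cl <- make_seasonal_climate(2000:2009, seed = 21)
  bl <- compute_monthly_baseline(cl)
  dev <- compute_deviations(cl, bl)
  th5 <- calibrate_thresholds(dev, 0.05)
  th1 <- calibrate_thresholds(dev, 0.01)
  fl5 <- classify_days(dev, th5)
  fl1 <- classify_days(dev, th1)
  # every 1%-tail flag is also a 5%-tail flag
  expect_true(all(fl5$is_hot[fl1$is_hot]))
  expect_true(all(fl5$is_cold[fl1$is_cold]))
  expect_true(all(fl5$is_rain[fl1$is_rain]))

  set.seed(22)
  broods <- tibble::tibble(
    brood_id = sprintf("b%03d", 1:300),
    hatch_date = sample(seq(as.Date("2000-04-15"), as.Date("2009-06-15"),
                            by = "day"), 300, replace = TRUE)
  )
  ex5 <- brood_exposure(broods, fl5, cl)
  ex1 <- brood_exposure(broods, fl1, cl)
  # shrinking the tail never increases a window count
  expect_true(all(ex1$n_hot <= ex5$n_hot))
  expect_true(all(ex1$n_cold <= ex5$n_cold))
  expect_true(all(ex1$n_rain <= ex5$n_rain))
  # binary presence is exactly count >= 1; counts bounded by window length
  for (ex in list(ex5, ex1)) {
    expect_identical(ex$any_hot, ex$n_hot >= 1)
    expect_identical(ex$any_rain, ex$n_rain >= 1)
    expect_true(all(ex$n_hot + ex$n_gap_days <= ex$n_days))
    expect_true(all(ex$n_days == 8))
  }
  # disjoint stages partition the whole 0-15 period
  whole <- brood_exposure(broods, fl5, cl,
                          windows = tibble::tibble(stage = "whole",
                                                   start_offset = 0L,
                                                   end_offset = 15L))
  per_stage <- stats::aggregate(cbind(n_hot, n_cold, n_rain) ~ brood_id,
                                data = ex5, FUN = sum)
  m <- match(whole$brood_id, per_stage$brood_id)
  expect_equal(whole$n_hot, per_stage$n_hot[m])
  expect_equal(whole$n_cold, per_stage$n_cold[m])
  expect_equal(whole$n_rain, per_stage$n_rain[m])
})

test_that("brood-specific baselines equal a direct averaging oracle", {
  # constant series: all brood-specific deviations are zero
  cl <- make_climate(seq(as.Date("2000-01-01"), as.Date("2002-12-31"), "day"),
                     tmean = 11)
  win <- list(stage = "hatchling", start_offset = 0L, end_offset = 7L)
  bs <- brood_specific_deviations(cl, as.Date("2001-05-10"), win)
  expect_equal(bs$tdev_c, rep(0, 8))

  # seasonal series: baseline equals the mean over the extended window's
  # calendar days across all years
  cl <- make_seasonal_climate(1995:2014, seed = 31)
  hatch <- as.Date("2000-05-10")
  bs <- brood_specific_deviations(cl, hatch, win, halfwidth = 15)
  ext <- seq(hatch - 15, hatch + 7 + 15, by = "day")
  doys <- unique(as.integer(format(ext, "%j")))
  oracle <- mean(cl$tmean_c[as.integer(format(cl$date, "%j")) %in% doys])
  expect_equal(attr(bs, "baseline"), oracle, tolerance = 1e-12)
  expect_equal(bs$tdev_c, cl$tmean_c[match(bs$date, cl$date)] - oracle,
               tolerance = 1e-12)
})

test_that("brood-specific counts track monthly-baseline counts closely", {
  cl <- simulate_climate(climate_sim_config(years = 1985:2014), seed = 41)
  bl <- compute_monthly_baseline(cl)
  dev <- compute_deviations(cl, bl)
  th <- calibrate_thresholds(dev)
  fl <- classify_days(dev, th)
  set.seed(42)
  # hatch dates shaped like the study population (mid-May centre, SD 9 d)
  yrs <- sample(1986:2013, 400, replace = TRUE)
  doy <- pmin(pmax(round(rnorm(400, 134, 9)), 105), 170)
  broods <- tibble::tibble(
    brood_id = sprintf("b%03d", 1:400),
    hatch_date = as.Date(paste0(yrs, "-01-01")) + doy - 1
  )
  monthly <- brood_exposure(broods, fl, cl)
  specific <- brood_specific_exposure(broods, cl, th)
  j <- dplyr::inner_join(monthly, specific, by = c("brood_id", "stage"),
                         suffix = c("_m", "_s"))
  # per-brood fast baseline equals the direct per-brood computation
  wins <- stage_windows()
  for (i in sample(nrow(broods), 10)) {
    for (w in 1:2) {
      direct <- brood_specific_deviations(
        cl, broods$hatch_date[i],
        list(stage = wins$stage[w], start_offset = wins$start_offset[w],
             end_offset = wins$end_offset[w]))
      row <- specific[specific$brood_id == broods$brood_id[i] &
                        specific$stage == wins$stage[w], ]
      expect_equal(row$baseline_c, attr(direct, "baseline"), tolerance = 1e-10)
      expect_equal(row$n_hot, sum(direct$tdev_c >= th$hot_cut))
    }
  }
  # the two definitions agree strongly at the brood level; with the
  # generator's discrete low counts over 8-day windows the attainable
  # correlation sits slightly below what continuous long-series data shows
  expect_gt(cor(j$n_hot_m, j$n_hot_s), 0.8)
  expect_gt(cor(j$n_cold_m, j$n_cold_s), 0.8)
  # and the distributions of counts match closely in level
  expect_lt(abs(mean(j$n_hot_m) - mean(j$n_hot_s)), 0.2)
  expect_lt(abs(mean(j$n_cold_m) - mean(j$n_cold_s)), 0.2)
})
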