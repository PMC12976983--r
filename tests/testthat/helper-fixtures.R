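# shared fixtures, all generated in code

# small gap-free climate tibble over given dates
make_climate <- function(dates, tmean = 10, rain = 0) {
  tibble::tibble(
    date = as.Date(dates),
    tmean_c = rep_len(tmean, length(dates)),
    rain_mm = rep_len(rain, length(dates))
  )
}

# sinusoidal multi-year series with deterministic "noise" structure
make_seasonal_climate <- function(years, seed = 1) {
  set.seed(seed)
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tibble::tibble(
    date = dates,
    tmean_c = 9.5 + 6.5 * cos(2 * pi * (doy - 200) / 365.25) +
      rnorm(length(dates), 0, 2.5),
    rain_mm = rbinom(length(dates), 1, 0.5) *
      rgamma(length(dates), 0.7, scale = 6)
  )
}

# two broods x three chicks
tiny_breeding <- function() {
  broods <- tibble::tibble(
    brood_id = c("b1", "b2"),
    year = c(2001L, 2001L),
    lay_doy = c(110L, 120L),
    hatch_date = as.Date(c("2001-05-09", "2001-05-19")),
    clutch_size = c(3L, 3L),
    mother_id = c("f1", "f2"),
    nestbox_id = c("nb1", "nb2")
  )
  chicks <- tibble::tibble(
    chick_id = paste0("c", 1:6),
    brood_id = rep(c("b1", "b2"), each = 3),
    mass_d15_g = c(18.1, 18.4, 17.9, 19.0, 18.6, 18.8),
    recruited = c(0, 1, 0, 0, 0, 1)
  )
  list(broods = broods, chicks = chicks)
}

# deviations tibble without going through a baseline (for threshold tests)
make_deviations <- function(tdev, raindev,
                            dates = seq(as.Date("2000-01-01"),
                                        by = "day", length.out = length(tdev)),
                            mode = "calendar_month_longterm") {
  out <- tibble::tibble(date = dates, tmean_c = tdev, rain_mm = pmax(raindev, 0),
                        tdev_c = tdev, raindev_mm = raindev)
  attr(out, "baseline_mode") <- mode
  out
}

# Harrell-style truncated-power restricted cubic spline basis (independent
# construction used as an oracle for the ns() path); knots include boundaries
rcs_truncated_power <- function(x, knots) {
  K <- length(knots)
  tk <- sort(knots)
  cub <- function(u) pmax(u, 0)^3
  nonlin <- sapply(seq_len(K - 2), function(j) {
    cub(x - tk[j]) -
      cub(x - tk[K - 1]) * (tk[K] - tk[j]) / (tk[K] - tk[K - 1]) +
      cub(x - tk[K]) * (tk[K - 1] - tk[j]) / (tk[K] - tk[K - 1])
  })
  cbind(x, nonlin)
}
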