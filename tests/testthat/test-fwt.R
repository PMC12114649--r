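test_that("sine interpolation hits its landmarks and stays in range", {
  # zero amplitude: all 24 hours equal the common value
  expect_equal(hourly_temps(5, 5), rep(5, 24))
  tw <- hourly_temps(-5, 5)
  expect_equal(tw[12], 5) # maximum at hour 12
  expect_equal(tw[24], -5) # minimum at hour 24
  expect_equal(tw[6], 0) # midpoint where the sine vanishes
  expect_equal(tw[18], 0)
  expect_true(all(tw >= -5 & tw <= 5))
  expect_error(hourly_temps(3, 1), "t_min > t_max")
})

test_that("daily chill hours use strict bounds and match exhaustive enumeration", {
  expect_equal(daily_chill_hours(3, 3), 24L) # all hours inside (0, 7.2)
  expect_equal(daily_chill_hours(10, 20), 0L) # all hours above
  expect_equal(daily_chill_hours(0, 0), 0L) # boundary hours count zero
  expect_equal(daily_chill_hours(7.2, 7.2), 0L)
  # random pairs against the hour-by-hour scalar oracle
  set.seed(7)
  tmin <- stats::runif(2000, -25, 10)
  tmax <- tmin + stats::runif(2000, 0, 15)
  got <- daily_chill_hours(tmin, tmax)
  want <- mapply(oracle_chill_hours, tmin, tmax)
  expect_equal(got, as.integer(want))
})

test_that("widening the chilling band never loses hours", {
  set.seed(8)
  tmin <- stats::runif(500, -15, 8)
  tmax <- tmin + stats::runif(500, 0, 12)
  expect_true(all(
    daily_chill_hours(tmin, tmax, 0, 7.2) >= daily_chill_hours(tmin, tmax, 0, 4)
  ))
})

test_that("accumulated chill hours count the calendar window exactly", {
  cs <- constant_climate(1999:2002, t_min = 3, t_max = 3)
  # 61 days Nov-Dec + 46 days to S-1, all 24 h; the Nov-Dec span has 61
  # days in leap and common years alike, and with S = 47 the new-year span
  # ends before any 29 February
  expect_equal(accumulated_chill_hours(cs, 2002, s_start = 47), 24 * 107)
  expect_equal(accumulated_chill_hours(cs, 2001, s_start = 47), 24 * 107)
  # a leap 29 February inside the window does count: S = 70 in 2000
  expect_equal(accumulated_chill_hours(cs, 2000, s_start = 70), 24 * (61 + 69))
  warm <- constant_climate(2000:2001, t_min = 10, t_max = 10)
  expect_equal(accumulated_chill_hours(warm, 2001, s_start = 47), 0)
  # additivity over a partition of the window
  st <- small_study()
  yr <- st$pheno$year[4]
  full <- accumulated_chill_hours(st$climate, yr, s_start = 47)
  win <- climate_window(st$climate, yr - 1, 305, yr, 46)
  parts <- split(seq_len(nrow(win)), cut(seq_len(nrow(win)), 5))
  expect_equal(
    sum(vapply(parts, function(ix) {
      sum(daily_chill_hours(win$t_min[ix], win$t_max[ix]))
    }, numeric(1))),
    full
  )
})

test_that("feature summaries are exact on constant climate and ordered in general", {
  cs <- constant_climate(2000:2001, t_min = -10, t_max = 0, t_mean = -5)
  f <- fwt_features(cs, 2001, s_start = 47, critical_low = 2.9)
  expect_equal(f$x1, 107) # every day's minimum is below 2.9
  expect_equal(f$x3, -10)
  expect_equal(f$x4, 0)
  expect_equal(f$x5, -5)
  expect_equal(f$x6, -10)
  # critical temperature below the global minimum: no cold days
  expect_equal(fwt_features(cs, 2001, 47, critical_low = -20)$x1, 0)
  # single-day window (inclusive-start variant of a 1 Nov start)
  f1 <- fwt_features(cs, 2001, s_start = 1, critical_low = 0, include_start = TRUE)
  expect_equal(f1$x3, -10)
  # ordering invariants on realistic windows
  st <- small_study()
  fr <- fwt_features(st$climate, st$pheno$year, 47, critical_low = 2.9)
  expect_true(all(fr$x6 <= fr$x3))
  expect_true(all(fr$x3 <= fr$x5))
  expect_true(all(fr$x5 <= fr$x4))
  expect_true(all(fr$x1 >= 0 & fr$x1 <= 108))
  expect_true(all(fr$x2 >= 0 & fr$x2 <= 24 * 108))
})

test_that("the critical-temperature scan maximizes deviance and flags flat profiles", {
  st <- small_study()
  years <- st$pheno$year
  feats <- fwt_features(st$climate, years, 47, critical_low = 2.9)
  # residuals driven by x1 at a known critical temperature
  x1_true <- local({
    f <- fwt_features(st$climate, years, 47, critical_low = 0)
    f$x1
  })
  y <- 0.35 * (x1_true - mean(x1_true))
  sc <- scan_critical_temperature(y, st$climate, years, 47,
    candidates = seq(-3, 3, by = 0.5), terms = c("x1", "x5")
  )
  expect_lt(abs(sc$critical_low - 0), 1.01)
  expect_gt(sc$deviance_explained, 0.8)
  expect_equal(nrow(sc$profile), 13L)
  # identical x1 vectors give identical deviance
  prof <- sc$profile
  x1_at <- function(cl) fwt_features(st$climate, years, 47, cl)$x1
  same <- which(vapply(prof$candidate, function(cl) {
    identical(x1_at(cl), x1_at(prof$candidate[1]))
  }, logical(1)))
  if (length(same) > 1) {
    expect_equal(
      prof$deviance_explained[same],
      rep(prof$deviance_explained[same[1]], length(same))
    )
  }
  # candidates so close that every x1 vector coincides: the profile is
  # exactly flat and the flatness warning fires
  set.seed(21)
  expect_warning(
    scan_critical_temperature(stats::rnorm(length(years)), st$climate,
      years, 47,
      candidates = c(2.9, 2.9000001), terms = c("x1", "x5")
    ),
    "flat"
  )
})
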