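test_that("trapezoid attainment handles exact hits, straddles, and deficits", {
  expect_equal(accumulate_until(rep(2, 10), 10), 5)
  expect_equal(accumulate_until(c(4, 5, 3), 10, s_start = 60), 61 + 1 / 3)
  # threshold inside the first day interpolates below S
  expect_equal(accumulate_until(c(4, 5), 1, s_start = 10), 9.25)
  err <- tryCatch(
    accumulate_until(rep(0, 5), 3),
    adpgam_non_attainment = function(e) e
  )
  expect_s3_class(err, "adpgam_non_attainment")
  expect_equal(err$deficit, 3)
  expect_error(accumulate_until(c(1, -1), 1), "negative")
})

test_that("trapezoid attainment agrees with a brute-force refinement oracle", {
  set.seed(101)
  for (i in 1:250) {
    n <- sample(5:60, 1)
    inc <- stats::runif(n, 0, 2) * stats::rbinom(n, 1, 0.9) # some zero days
    total <- sum(inc)
    if (total == 0) next
    thr <- stats::runif(1, 0.05, 0.95) * total
    s <- sample(1:80, 1)
    expect_equal(
      accumulate_until(inc, thr, s),
      oracle_attain_refined(inc, thr, s),
      tolerance = 1e-11
    )
  }
})

test_that("starting-date selection finds perfect anticorrelation and breaks ties low", {
  # each year has a constant temperature c_i, so the windowed mean equals
  # c_i for every candidate start; flowering is an exactly decreasing
  # function of c_i, hence every candidate shows correlation -1 and the
  # tie-break returns the earliest day-of-year
  years <- 2001:2010
  c_i <- seq(2, 6.5, by = 0.5)
  dates <- seq(as.Date("2001-01-01"), as.Date("2010-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  tm <- c_i[yr - 2000]
  cs <- climate_series(data.frame(
    date = dates, t_min = tm - 1, t_max = tm + 1, t_mean = tm
  ))
  ph <- phenology_records(years, round(130 - 6 * c_i))
  sel <- select_start_date_add(cs, ph, candidates = c(20, 40, 60))
  expect_equal(sel$correlation, -1)
  expect_equal(sel$s_start, 20) # tie among candidates: earliest wins
  expect_equal(sel$profile$correlation, rep(-1, 3))
  # on a realistic forcing-driven study the selection lands before the
  # earliest flowering date with a negative coefficient
  st <- small_study()
  sel2 <- select_start_date_add(st$climate, st$pheno, candidates = seq(20, 80, 5))
  expect_lt(sel2$correlation, 0)
  expect_lt(sel2$s_start, min(st$pheno$ffd))
  # fewer than 3 years is refused
  expect_error(select_start_date_add(cs, ph[1:2, ], 20), "3 years")
})

test_that("degree-day fitting is translation invariant and exact for one year", {
  st <- small_study()
  fit <- fit_add(st$climate, st$pheno, s_start = 47,
    t0_candidates = seq(-3, 3, by = 0.5)
  )
  # shift climate and grid by the same constant: identical everything
  shifted <- st$climate
  shifted$t_min <- shifted$t_min + 2
  shifted$t_max <- shifted$t_max + 2
  shifted$t_mean <- shifted$t_mean + 2
  shifted <- climate_series(
    as.data.frame(shifted)[, c("date", "t_min", "t_max", "t_mean")]
  )
  fit2 <- fit_add(shifted, st$pheno, s_start = 47,
    t0_candidates = seq(-3, 3, by = 0.5) + 2
  )
  expect_equal(fit2$params[["t0"]], fit$params[["t0"]] + 2)
  expect_equal(fit2$threshold, fit$threshold, tolerance = 1e-10)
  expect_equal(fit2$per_year$predicted, fit$per_year$predicted, tolerance = 1e-10)
  expect_equal(fit2$rmse, fit$rmse, tolerance = 1e-10)
  # single-year degeneracy: threshold equals that year's requirement, so
  # the prediction reproduces the observation and the RMSE is zero
  one <- st$pheno[3, , drop = FALSE]
  fit1 <- fit_add(st$climate, one, s_start = 47, t0_candidates = 0)
  expect_equal(fit1$per_year$predicted, one$ffd, tolerance = 1e-8)
  expect_lt(fit1$rmse, 1e-8)
})

test_that("the fitted RMSE is recomputable from the per-year table", {
  st <- small_study()
  fit <- fit_adts(st$climate, st$pheno,
    s_candidates = 45:49, ea_candidates = seq(10, 20, 1)
  )
  expect_equal(fit$rmse, sqrt(mean(fit$per_year$residual^2)), tolerance = 1e-10)
  expect_true(all(fit$per_year$predicted > fit$s_start))
  expect_gt(fit$threshold, 0)
})

test_that("ADTS at Ea = 0 reduces to the closed-form day count", {
  st <- small_study()
  s <- 47
  fit <- fit_adts(st$climate, st$pheno, s_candidates = s, ea_candidates = 0)
  # every day contributes exactly 1, so U_i = E_i - S + 1 and the
  # trapezoid prediction is S - 1 + mean(U)
  ubar <- mean(floor(st$pheno$ffd) - s + 1)
  expect_equal(fit$threshold, ubar, tolerance = 1e-12)
  expect_equal(fit$per_year$predicted, rep(s - 1 + ubar, nrow(st$pheno)),
    tolerance = 1e-12
  )
})

test_that("constant climate makes the ADTS objective flat in Ea", {
  cs <- constant_climate(2000:2004, t_min = 8, t_max = 12)
  ph <- phenology_records(2001:2004, rep(100, 4))
  fit <- fit_adts(cs, ph, s_candidates = 47, ea_candidates = c(5, 10, 20))
  expect_true(all(abs(fit$surface - fit$surface[1, 1]) < 1e-9))
  expect_lt(fit$rmse, 1e-9)
})

test_that("ADP recovers a known forward-simulated model", {
  st <- small_study() # sigma_obs = 0, truth: arrhenius B=-4.38 Ea=15.04, S=47
  fit <- fit_adp(st$climate, st$pheno, s_candidates = 45:49)
  expect_lt(fit$rmse, 0.5) # whole-day rounding floor
  expect_lt(abs(fit$s_start - 47), 2)
  # accumulated progress at the observed dates is within 2% of 100%
  expect_true(all(abs(fit$progress_at_observed - 1) < 0.02))
})

test_that("raising a day's temperature never delays any method's prediction", {
  st <- small_study()
  bump <- function(cs, year, d, delta) {
    i <- which(cs$year == year & cs$doy == d)
    cs$t_min[i] <- cs$t_min[i] + delta
    cs$t_max[i] <- cs$t_max[i] + delta
    cs$t_mean[i] <- cs$t_mean[i] + delta
    climate_series(as.data.frame(cs)[, c("date", "t_min", "t_max", "t_mean")])
  }
  y <- st$pheno$year[5]
  fits <- list(
    fit_add(st$climate, st$pheno, 47, t0_candidates = 0),
    fit_adts(st$climate, st$pheno, s_candidates = 47, ea_candidates = 15),
    fit_adp(st$climate, st$pheno, s_candidates = 47)
  )
  warmer <- bump(st$climate, y, 60, +5)
  for (fit in fits) {
    p0 <- predict_years(fit, st$climate, y)$predicted
    p1 <- predict_years(fit, warmer, y)$predicted
    expect_lte(p1, p0)
  }
})

test_that("predictions on training years reproduce the fit table", {
  st <- small_study()
  fit <- fit_adts(st$climate, st$pheno, s_candidates = 47, ea_candidates = 15)
  out <- predict_years(fit, st$climate, st$pheno$year)
  expect_equal(out$predicted, fit$per_year$predicted, tolerance = 1e-12)
})
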