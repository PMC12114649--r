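# Shared 30-year feature fixture for the GAM tests: enough years for the
# full six-smooth candidate set (31 coefficients needs > 30 observations,
# so the six-term model is exercised with 40 years in the selection test).
gam_fixture <- function(n_years = 40, seed = 5) {
  cs <- simulate_climate(climate_gen_spec(seq(2010 - n_years, 2010), seed = seed))
  years <- (2010 - n_years + 1):2010
  fwt_features(cs, years, s_start = 47, critical_low = 2.9)
}

test_that("deviance explained behaves at its edges and recovers linear signal", {
  feats <- gam_fixture()
  # constant response: no deviance to explain
  fit0 <- fit_residual_gam(rep(2, nrow(feats)), feats, c("x4", "x5"))
  expect_equal(fit0$deviance_explained, 0)
  # near-noiseless linear signal: deviance -> 1 and the smooth is a line
  set.seed(31)
  y <- 2 * feats$x4 + stats::rnorm(nrow(feats), 0, 1e-4)
  fit1 <- fit_residual_gam(y, feats, "x4")
  expect_gt(fit1$deviance_explained, 0.999)
  edf <- sum(fit1$model$edf) - 1
  expect_lt(edf, 1.2) # effectively linear
  # deviance explained is invariant to adding a constant to y
  fit2 <- fit_residual_gam(y + 100, feats, "x4")
  expect_equal(fit2$deviance_explained, fit1$deviance_explained,
    tolerance = 1e-6
  )
})

test_that("over-parameterized formulas are rejected with guidance", {
  feats <- gam_fixture(n_years = 12)
  y <- stats::rnorm(nrow(feats))
  expect_error(
    fit_residual_gam(y, feats, paste0("x", 1:6), k = 6),
    "basis"
  )
  expect_error(fit_residual_gam(y, feats, "x9"), "missing")
})

test_that("model selection prefers the generative features and is deterministic", {
  feats <- gam_fixture()
  set.seed(32)
  y <- 0.3 * (feats$x1 - mean(feats$x1)) - 0.02 * (feats$x2 - mean(feats$x2)) +
    stats::rnorm(nrow(feats), 0, 0.5)
  # candidate set containing the generative pair and decoys: the exact
  # pair must qualify and win on deviance explained
  cands <- list(
    c("x1", "x2"), c("x1", "x5"), c("x2", "x4"), c("x4", "x5"),
    c("x1", "x2", "x5")
  )
  sel1 <- suppressWarnings(select_best_gam(y, feats, candidates = cands))
  sel2 <- suppressWarnings(select_best_gam(y, feats, candidates = cands))
  expect_true(all(c("x1", "x2") %in% sel1$best$terms))
  expect_identical(sel1$best$terms, sel2$best$terms)
  expect_equal(sel1$table$aic, sel2$table$aic)
  # with the default candidate table, dropping the active x2 costs the
  # most deviance of any single-feature removal
  tab <- suppressWarnings(select_best_gam(y, feats))$table
  expect_equal(nrow(tab), 10L)
  drop_x2 <- !grepl("x2", tab$formula)
  expect_lt(max(tab$deviance_explained[drop_x2]),
    min(tab$deviance_explained[!drop_x2], na.rm = TRUE)
  )
  # single candidate with all terms significant is returned as-is
  one <- select_best_gam(y, feats, candidates = list(c("x1", "x2")))
  expect_true(one$qualified)
  expect_identical(one$best$terms, c("x1", "x2"))
})

test_that("contribution rates follow the inverse drop-one-deviance rule", {
  feats <- gam_fixture()
  set.seed(33)
  y <- -0.02 * (feats$x2 - mean(feats$x2)) - 6 * (feats$x4 - mean(feats$x4)) +
    stats::rnorm(nrow(feats), 0, 0.5)
  cr <- contribution_rates(y, feats, c("x2", "x4"))
  de0 <- attr(cr, "de0")
  dej <- attr(cr, "de_dropone")
  # hand evaluation of the partition rule from the drop-one deviances
  w <- (1 / dej) / sum(1 / dej)
  expect_equal(as.numeric(cr), as.numeric(w * de0 * 100), tolerance = 1e-12)
  expect_equal(sum(cr), de0 * 100, tolerance = 1e-9)
  # the feature whose removal hurts more receives the larger share
  expect_equal(order(dej), order(-cr))
})

test_that("adjusting predictions reproduces the least-squares improvement", {
  st <- small_study()
  fit <- fit_adts(st$climate, st$pheno, s_candidates = 47, ea_candidates = seq(10, 20, 1))
  y <- fit$per_year$residual
  feats <- fwt_features(st$climate, st$pheno$year, fit$s_start, critical_low = 2.9)
  gam <- fit_residual_gam(y, feats, c("x4", "x5"), k = 4)
  adj <- adjust_predictions(fit, gam)
  # the GAM includes an intercept, so in-sample adjustment cannot hurt
  expect_lte(adj$rmse_adjusted, adj$rmse_unadjusted + 1e-12)
  expect_equal(adj$per_year$adjusted, fit$per_year$predicted + gam$fitted)
  # adjusted RMSE is recomputable from the adjusted series
  expect_equal(
    adj$rmse_adjusted,
    sqrt(mean((adj$per_year$observed - adj$per_year$adjusted)^2)),
    tolerance = 1e-12
  )
  # a zero correction leaves predictions untouched
  gam0 <- gam
  gam0$fitted <- rep(0, length(gam$fitted))
  adj0 <- adjust_predictions(fit, gam0)
  expect_equal(adj0$per_year$adjusted, fit$per_year$predicted)
  expect_equal(adj0$rmse_adjusted, fit$rmse)
  # mismatched years are refused
  gam_bad <- gam
  gam_bad$years <- gam$years + 1
  expect_error(adjust_predictions(fit, gam_bad), "years")
})
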