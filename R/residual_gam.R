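# Generalized additive models of forcing-method residuals on fall-winter
# temperature features: candidate-model comparison, drop-one contribution
# rates, and adjusted event-date predictions. Model fitting is delegated to
# mgcv (penalized regression splines, GCV smoothing selection).

#' Default candidate GAM formulas over the six fall-winter features
#'
#' The comparison set spans the full six-feature model, every five-feature
#' drop-one model, and three reduced models; each entry is the character
#' vector of features receiving one univariate smooth.
#'
#' @return list of character vectors.
#' @export
gam_candidate_formulas <- function() {
  list(
    c("x1", "x2", "x3", "x4", "x5", "x6"),
    c("x2", "x3", "x4", "x5", "x6"),
    c("x1", "x3", "x4", "x5", "x6"),
    c("x1", "x2", "x4", "x5", "x6"),
    c("x1", "x2", "x3", "x5", "x6"),
    c("x1", "x2", "x3", "x4", "x6"),
    c("x1", "x2", "x3", "x4", "x5"),
    c("x1", "x2", "x4", "x5"),
    c("x1", "x2", "x5"),
    c("x1", "x2", "x4")
  )
}

#' Fit a Gaussian additive model of residuals on fall-winter features
#'
#' One penalized univariate smooth per listed feature (thin-plate basis,
#' dimension `k`, smoothing parameters by GCV), Gaussian family. Deviance
#' explained is `1 - residual deviance / null deviance` (0 when the
#' response is constant); per-smooth significance is the Wald-type
#' approximate test of the penalized fit.
#'
#' @param y per-year residuals (response), one value per feature row.
#' @param features data frame holding the columns named in `terms`
#'   (typically from [fwt_features()]).
#' @param terms character vector of feature names to smooth over.
#' @param k basis dimension per smooth (default 6; small bases guard
#'   against overfitting short phenology series).
#' @return a `gam_result`: list with the fitted mgcv `model`, `terms`,
#'   `deviance_explained` (fraction), `aic`, `term_pvalues` (named),
#'   `fitted` (per-year fitted residuals) and `years` (if `features` has a
#'   `year` column).
#' @export
fit_residual_gam <- function(y, features, terms, k = 6) {
  if (length(y) != nrow(features)) {
    stop("`y` and `features` differ in length", call. = FALSE)
  }
  miss <- setdiff(terms, names(features))
  if (length(miss)) {
    stop("features missing from table: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  n_coef <- 1 + length(terms) * (k - 1)
  if (n_coef > length(y)) {
    stop(sprintf(
      paste0(
        "model has %d coefficients for %d years; ",
        "reduce the basis dimension `k` or the number of terms"
      ),
      n_coef, length(y)
    ), call. = FALSE)
  }
  dat <- features[, terms, drop = FALSE]
  dat$y <- y
  fml <- stats::reformulate(
    sprintf("s(%s, k = %d)", terms, k),
    response = "y"
  )
  environment(fml) <- environment()
  model <- mgcv::gam(fml,
    data = dat, family = stats::gaussian(),
    method = "GCV.Cp"
  )
  sm <- summary(model)
  dev_expl <- if (model$null.deviance < 1e-10) 0 else sm$dev.expl
  pv <- stats::setNames(sm$s.table[, "p-value"], terms)
  structure(
    list(
      model = model, terms = terms, k = k,
      deviance_explained = as.numeric(dev_expl),
      aic = stats::AIC(model),
      term_pvalues = pv,
      fitted = as.numeric(stats::fitted(model)),
      years = if ("year" %in% names(features)) features$year else NULL
    ),
    class = "gam_result"
  )
}

#' @export
print.gam_result <- function(x, ...) {
  cat(sprintf(
    "<gam_result> y ~ %s | deviance explained %.1f%%, AIC %.2f\n",
    paste(sprintf("s(%s)", x$terms), collapse = " + "),
    100 * x$deviance_explained, x$aic
  ))
  invisible(x)
}

#' Select the best residual GAM among candidates
#'
#' Among candidates whose every smooth term is significant at level
#' `alpha`, the model with the largest deviance explained wins. If no
#' candidate fully qualifies, the lowest-AIC candidate is returned with a
#' warning. Failed fits are recorded and skipped.
#'
#' @inheritParams fit_residual_gam
#' @param candidates list of character vectors of feature names (default
#'   [gam_candidate_formulas()]).
#' @param alpha per-smooth significance level (default 0.05).
#' @return list with `best` (a `gam_result`), `qualified` (logical: did any
#'   candidate have all terms significant), and `table` (data frame:
#'   formula, aic, deviance_explained, nonsignificant terms).
#' @export
select_best_gam <- function(y, features, candidates = gam_candidate_formulas(),
                            alpha = 0.05, k = 6) {
  if (!length(candidates)) stop("no candidate formulas", call. = FALSE)
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    terms <- candidates[[i]]
    fml_txt <- paste0(
      "y ~ ", paste(sprintf("s(%s)", terms), collapse = " + ")
    )
    fit <- tryCatch(fit_residual_gam(y, features, terms, k = k),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(
        formula = fml_txt, aic = NA_real_, deviance_explained = NA_real_,
        nonsignificant = paste("fit failed:", conditionMessage(fit))
      )
      next
    }
    fits[[i]] <- fit
    ns <- names(fit$term_pvalues)[fit$term_pvalues >= alpha]
    rows[[i]] <- data.frame(
      formula = fml_txt, aic = fit$aic,
      deviance_explained = fit$deviance_explained,
      nonsignificant = if (length(ns)) paste(ns, collapse = ", ") else "-"
    )
  }
  tab <- do.call(rbind, rows)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("every candidate GAM failed", call. = FALSE)
  all_sig <- ok & tab$nonsignificant == "-"
  if (any(all_sig)) {
    idx <- which(all_sig)[which.max(tab$deviance_explained[all_sig])]
    qualified <- TRUE
  } else {
    warning(
      "no candidate had all smooth terms significant; ",
      "returning the lowest-AIC model",
      call. = FALSE
    )
    idx <- which(ok)[which.min(tab$aic[ok])]
    qualified <- FALSE
  }
  list(best = fits[[idx]], qualified = qualified, table = tab)
}

#' Drop-one contribution rates of the features in a GAM
#'
#' Partitions the full model's deviance explained `DE0` across its `z`
#' features using inverse drop-one deviances: with `DEj` the deviance
#' explained after dropping feature j,
#' `CR_i = (1 / DE_i) / sum_j(1 / DE_j) * DE0 * 100`. A feature whose
#' removal hurts more (smaller `DEj`) receives a larger share; the rates
#' sum to `DE0 * 100` exactly.
#'
#' @inheritParams fit_residual_gam
#' @param terms the features of the full model (at least 2).
#' @return named numeric vector of contribution rates (percent), with
#'   attributes `de0` (full-model deviance explained) and `de_dropone`
#'   (named drop-one deviances).
#' @export
contribution_rates <- function(y, features, terms, k = 6) {
  if (length(terms) < 2) {
    stop("contribution rates need at least 2 features", call. = FALSE)
  }
  de0 <- fit_residual_gam(y, features, terms, k = k)$deviance_explained
  dej <- vapply(seq_along(terms), function(j) {
    fit_residual_gam(y, features, terms[-j], k = k)$deviance_explained
  }, numeric(1))
  names(dej) <- terms
  if (any(dej <= 0)) {
    stop(
      "a drop-one model explains no deviance (division by zero in the ",
      "inverse-deviance weights); drop that feature from the model instead",
      call. = FALSE
    )
  }
  w <- (1 / dej) / sum(1 / dej)
  structure(stats::setNames(w * de0 * 100, terms),
    de0 = de0, de_dropone = dej
  )
}

#' Adjust forcing-method predictions with a fitted residual GAM
#'
#' Adds the GAM's fitted residual to each year's forcing prediction
#' (residuals are observed minus predicted, so the adjusted prediction
#' moves toward the observation) and recomputes the RMSE.
#'
#' @param fit a `method_fit` whose residuals the GAM was fitted on.
#' @param gam a `gam_result` from [fit_residual_gam()] on those residuals
#'   (matching years).
#' @return list with `per_year` (data frame: year, observed, predicted,
#'   adjusted), `rmse_unadjusted` and `rmse_adjusted`.
#' @export
adjust_predictions <- function(fit, gam) {
  py <- fit$per_year
  if (!is.null(gam$years) && !identical(as.integer(gam$years),
    as.integer(py$year)
  )) {
    stop("GAM years do not match the method fit", call. = FALSE)
  }
  if (length(gam$fitted) != nrow(py)) {
    stop("GAM fitted values do not match the method fit", call. = FALSE)
  }
  adjusted <- py$predicted + gam$fitted
  list(
    per_year = data.frame(
      year = py$year, observed = py$observed,
      predicted = py$predicted, adjusted = adjusted
    ),
    rmse_unadjusted = fit$rmse,
    rmse_adjusted = .rmse(py$observed - adjusted)
  )
}
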