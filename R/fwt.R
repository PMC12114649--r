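# Fall-winter temperature (FWT) predictors: six per-year summaries of the
# window from 1 November of the preceding year to the day before the
# spring starting date, including the Chilling Hours model with
# sine-interpolated hourly temperatures and a scannable critical low
# temperature for the cold-day counter.

#' Sine-interpolated hourly temperatures from a daily min/max pair
#'
#' `T_w = (t_max - t_min)/2 * sin(pi/12 * w - pi/2) + (t_min + t_max)/2`
#' for hours `w = 1..24`. The maximum `t_max` is attained at `w = 12`, the
#' minimum `t_min` at `w = 24`; all values lie within `[t_min, t_max]`.
#' No timezone or solar-time correction is applied.
#'
#' @param t_min,t_max daily minimum and maximum temperatures, degrees C
#'   (scalars, `t_min <= t_max`).
#' @return numeric vector of 24 hourly temperatures.
#' @export
hourly_temps <- function(t_min, t_max) {
  .assert_scalar_finite(t_min, "t_min")
  .assert_scalar_finite(t_max, "t_max")
  if (t_min > t_max) stop("t_min > t_max", call. = FALSE)
  w <- 1:24
  (t_max - t_min) / 2 * sin(pi / 12 * w - pi / 2) + (t_min + t_max) / 2
}

.chill_sine <- sin(pi / 12 * (1:24) - pi / 2)

#' Chilling hours of one or more days
#'
#' Counts the sine-interpolated hourly temperatures strictly between
#' `lower` and `upper` (both inequalities strict: boundary hours count 0).
#' The classical Chilling Hours bounds are 0 and 7.2 degrees C.
#'
#' @param t_min,t_max daily minimum and maximum temperatures, degrees C
#'   (vectors of equal length, elementwise `t_min <= t_max`).
#' @param lower,upper chilling bounds, degrees C (`lower < upper`).
#' @return integer vector of per-day chill-hour counts in 0..24.
#' @export
daily_chill_hours <- function(t_min, t_max, lower = 0, upper = 7.2) {
  if (length(t_min) != length(t_max)) stop("length mismatch", call. = FALSE)
  if (any(t_min > t_max)) stop("t_min > t_max", call. = FALSE)
  if (!(lower < upper)) stop("need lower < upper", call. = FALSE)
  if (!length(t_min)) return(integer(0))
  tw <- outer(.chill_sine, (t_max - t_min) / 2) +
    rep((t_min + t_max) / 2, each = 24L)
  as.integer(colSums(tw > lower & tw < upper))
}

# The fall-winter window of one phenology year: 1 November of the
# preceding year through day-of-year `s_start - 1` (or `s_start` when the
# inclusive variant is requested).
.fwt_window <- function(climate, year, s_start, include_start = FALSE) {
  end_doy <- if (include_start) s_start else s_start - 1L
  climate_window(climate, year - 1L, doy(as.Date(paste0(year - 1L, "-11-01"))),
    year, end_doy
  )
}

#' Accumulated chilling hours over the fall-winter window
#'
#' Sums [daily_chill_hours()] from 1 November of the preceding year
#' through 31 December, plus 1 January through day-of-year `s_start - 1`
#' of the given year (the second span excludes the starting day itself).
#'
#' @param climate a [climate_series()] covering the window.
#' @param year phenology year (the window starts in `year - 1`).
#' @param s_start spring starting day-of-year.
#' @param lower,upper chilling bounds, degrees C.
#' @return accumulated chilling hours (integer).
#' @export
accumulated_chill_hours <- function(climate, year, s_start,
                                    lower = 0, upper = 7.2) {
  win <- .fwt_window(climate, year, s_start)
  sum(daily_chill_hours(win$t_min, win$t_max, lower, upper))
}

#' Six fall-winter temperature predictors per year
#'
#' For each year, over the window from 1 November of the preceding year to
#' the day before the starting date (all six features share one window;
#' set `include_start = TRUE` for the variant that includes the starting
#' day):
#' \describe{
#'   \item{x1}{number of days with daily minimum temperature at or below
#'     `critical_low`;}
#'   \item{x2}{accumulated chilling hours ([accumulated_chill_hours()]);}
#'   \item{x3}{mean of the daily minimum temperatures;}
#'   \item{x4}{mean of the daily maximum temperatures;}
#'   \item{x5}{mean of the daily mean temperatures;}
#'   \item{x6}{minimum of the daily minimum temperatures.}
#' }
#'
#' @param climate a [climate_series()].
#' @param years integer phenology years.
#' @param s_start spring starting day-of-year.
#' @param critical_low critical low temperature for the cold-day count x1,
#'   degrees C.
#' @param lower,upper chilling bounds for x2, degrees C.
#' @param include_start include the starting day itself in the window
#'   (default `FALSE`, consistent with the chilling-hours accumulation).
#' @return data frame `year`, `x1`..`x6`.
#' @export
fwt_features <- function(climate, years, s_start, critical_low,
                         lower = 0, upper = 7.2, include_start = FALSE) {
  rows <- lapply(years, function(y) {
    win <- .fwt_window(climate, y, s_start, include_start)
    data.frame(
      year = y,
      x1 = sum(win$t_min <= critical_low),
      x2 = sum(daily_chill_hours(win$t_min, win$t_max, lower, upper)),
      x3 = mean(win$t_min),
      x4 = mean(win$t_max),
      x5 = mean(win$t_mean),
      x6 = min(win$t_min)
    )
  })
  do.call(rbind, rows)
}

#' Scan candidate critical low temperatures by GAM deviance explained
#'
#' For each candidate critical temperature, rebuilds the cold-day count x1,
#' refits the chosen residual GAM, and records the percentage of deviance
#' explained; the candidate with the largest deviance explained is selected
#' (the lowest such candidate on ties). Candidates whose GAM fit fails are
#' skipped with a warning and appear as `NA` in the profile.
#'
#' @param y per-year forcing-method residuals (observed minus predicted
#'   days), aligned with `years`.
#' @param climate a [climate_series()].
#' @param years phenology years.
#' @param s_start spring starting day-of-year.
#' @param candidates candidate critical low temperatures, degrees C
#'   (default -10..7 step 0.1).
#' @param terms features entering the GAM formula (default
#'   `c("x1", "x2", "x4", "x5")`).
#' @param lower,upper chilling bounds for x2.
#' @param k per-smooth basis dimension (see [fit_residual_gam()]).
#' @param include_start passed to [fwt_features()].
#' @return list with `critical_low` (selected candidate),
#'   `deviance_explained` (at the selection), `profile` (data frame
#'   `candidate`, `deviance_explained`) and `features` (the feature table
#'   rebuilt at the selected candidate).
#' @export
scan_critical_temperature <- function(y, climate, years, s_start,
                                      candidates = seq(-10, 7, by = 0.1),
                                      terms = c("x1", "x2", "x4", "x5"),
                                      lower = 0, upper = 7.2, k = 6,
                                      include_start = FALSE) {
  if (!length(candidates)) stop("no candidates", call. = FALSE)
  candidates <- sort(candidates)
  feats <- fwt_features(climate, years, s_start,
    critical_low = candidates[1],
    lower = lower, upper = upper, include_start = include_start
  )
  # only x1 depends on the candidate; precompute each year's window t_min
  tmins <- lapply(years, function(yy) {
    .fwt_window(climate, yy, s_start, include_start)$t_min
  })
  dev <- rep(NA_real_, length(candidates))
  for (ci in seq_along(candidates)) {
    feats$x1 <- vapply(tmins, function(v) sum(v <= candidates[ci]), numeric(1))
    fit <- tryCatch(
      fit_residual_gam(y, feats, terms, k = k),
      error = function(e) {
        warning(sprintf(
          "GAM failed at candidate %.3g: %s", candidates[ci],
          conditionMessage(e)
        ), call. = FALSE)
        NULL
      }
    )
    if (!is.null(fit)) dev[ci] <- fit$deviance_explained
  }
  if (all(is.na(dev))) stop("every candidate GAM failed", call. = FALSE)
  if (diff(range(dev, na.rm = TRUE)) < 0.05) {
    warning("deviance profile is nearly flat across candidates",
      call. = FALSE
    )
  }
  best <- candidates[which.max(dev)]
  feats$x1 <- vapply(tmins, function(v) sum(v <= best), numeric(1))
  list(
    critical_low = best,
    deviance_explained = max(dev, na.rm = TRUE),
    profile = data.frame(candidate = candidates, deviance_explained = dev),
    features = feats
  )
}
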