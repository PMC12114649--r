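# Seeded synthetic daily climate and phenology, used to validate every
# stage of the pipeline end to end without external data. The climate is a
# seasonal sinusoid with AR(1) anomalies and a jittered diurnal spread
# (temperate continental, Beijing-like, by default); flowering dates are
# forward-simulated from a known developmental-rate model, optionally
# shifted by additive fall-winter feature effects and observation noise.

#' Specification of a synthetic daily-climate series
#'
#' Daily mean temperature is
#' `mu - amplitude * cos(2 pi (doy - d_min) / 365.25)` plus an AR(1)
#' anomaly with coefficient `phi` and innovation standard deviation
#' `sigma`; minima and maxima sit half the (jittered) diurnal range below
#' and above the mean, so `t_min <= t_mean <= t_max` always holds. The
#' defaults give a mid-latitude continental climate with winter means
#' below 0 degrees C and on the order of 100-130 chill-capable days per
#' year.
#'
#' @param years integer years to generate (whole calendar years).
#' @param mu mean annual temperature, degrees C.
#' @param amplitude seasonal half-range, degrees C.
#' @param d_min day-of-year of the coldest point of the seasonal cycle.
#' @param diurnal_range mean daily max-min spread, degrees C (> 0).
#' @param phi AR(1) coefficient of the daily anomaly (|phi| < 1).
#' @param sigma AR(1) innovation standard deviation, degrees C (>= 0).
#' @param sigma_diurnal standard deviation of the half-range jitter,
#'   degrees C.
#' @param seed integer seed.
#' @return a `climate_gen_spec` list.
#' @export
climate_gen_spec <- function(years, mu = 12, amplitude = 15, d_min = 15,
                             diurnal_range = 8, phi = 0.7, sigma = 2,
                             sigma_diurnal = 1.5, seed = 1) {
  stopifnot(
    diurnal_range > 0, abs(phi) < 1, sigma >= 0, sigma_diurnal >= 0,
    length(years) >= 1
  )
  structure(
    list(
      years = sort(unique(as.integer(years))), mu = mu,
      amplitude = amplitude, d_min = d_min, diurnal_range = diurnal_range,
      phi = phi, sigma = sigma, sigma_diurnal = sigma_diurnal,
      seed = as.integer(seed)
    ),
    class = "climate_gen_spec"
  )
}

#' Simulate a daily climate series
#'
#' @param spec a [climate_gen_spec()].
#' @return a [climate_series()] covering the specified whole years;
#'   reproducible under the spec's seed.
#' @export
simulate_climate <- function(spec) {
  stopifnot(inherits(spec, "climate_gen_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  dates <- seq(
    as.Date(paste0(min(spec$years), "-01-01")),
    as.Date(paste0(max(spec$years), "-12-31")),
    by = "day"
  )
  n <- length(dates)
  d <- doy(dates)
  base <- spec$mu -
    spec$amplitude * cos(2 * pi * (d - spec$d_min) / 365.25)
  anom <- if (spec$sigma > 0) {
    as.numeric(stats::filter(stats::rnorm(n, 0, spec$sigma), spec$phi,
      method = "recursive"
    ))
  } else {
    numeric(n)
  }
  t_mean <- base + anom
  half_lo <- pmax(0, spec$diurnal_range / 2 +
    stats::rnorm(n, 0, spec$sigma_diurnal))
  half_hi <- pmax(0, spec$diurnal_range / 2 +
    stats::rnorm(n, 0, spec$sigma_diurnal))
  climate_series(data.frame(
    date = dates,
    t_min = t_mean - half_lo,
    t_max = t_mean + half_hi,
    t_mean = t_mean
  ))
}

# Save/restore the global RNG state so seeded simulators do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specification of synthetic phenology
#'
#' Each year's true event day is the fractional day at which the
#' accumulated daily developmental rates of `model`, summed from
#' `s_start`, reach 100%. The observed day adds optional additive
#' fall-winter feature effects (centered linear shifts, in days per
#' feature unit) and Gaussian observation noise, then rounds to a whole
#' day (records are whole days; the ground truth stays fractional).
#'
#' The default truth is an Arrhenius rate with `B = -4.38`,
#' `Ea = 15.04 kcal mol^-1` and `s_start = 47`, which produces realistic
#' early-spring flowering (around day-of-year 90-110) under the default
#' climate.
#'
#' @param model a [rate_model()] (the true developmental-rate equation).
#' @param s_start true starting day-of-year.
#' @param fwt_effects named list of per-feature linear effect slopes, e.g.
#'   `list(x2 = -0.01, x4 = -1)`: the shift added to a year's event day is
#'   `slope * (x - mean(x))` summed over the named features (names among
#'   x1..x6).
#' @param sigma_obs observation-noise standard deviation, days (>= 0).
#' @param critical_low,lower,upper feature-window settings used when
#'   `fwt_effects` reference x1/x2 (defaults 2.9, 0, 7.2 degrees C).
#' @param seed integer seed (observation noise).
#' @return a `pheno_gen_spec` list.
#' @export
pheno_gen_spec <- function(model = rate_model(
                             "arrhenius",
                             c(B = -4.38, Ea = 15.04)
                           ),
                           s_start = 47, fwt_effects = list(),
                           sigma_obs = 1, critical_low = 2.9,
                           lower = 0, upper = 7.2, seed = 1) {
  stopifnot(inherits(model, "rate_model"), sigma_obs >= 0)
  if (length(fwt_effects) &&
    !all(names(fwt_effects) %in% paste0("x", 1:6))) {
    stop("fwt_effects names must be among x1..x6", call. = FALSE)
  }
  structure(
    list(
      model = model, s_start = as.integer(s_start),
      fwt_effects = fwt_effects, sigma_obs = sigma_obs,
      critical_low = critical_low, lower = lower, upper = upper,
      seed = as.integer(seed)
    ),
    class = "pheno_gen_spec"
  )
}

#' Forward-simulate observed flowering dates from a climate series
#'
#' @param climate a [climate_series()]. Events are generated for every
#'   covered year except the first (the first year only feeds the
#'   preceding-November feature window).
#' @param spec a [pheno_gen_spec()].
#' @return phenology records (`year`, `ffd`) with attribute `truth`: a data
#'   frame logging, per year, the fractional true day, the per-feature
#'   shifts, the observation noise and the pre-rounding observed day. An
#'   error is raised if any year's progress fails to reach 100% by
#'   day-of-year 180 (the generated climate is then unrealistically cold
#'   for the model supplied).
#' @export
simulate_ffd <- function(climate, spec) {
  stopifnot(inherits(spec, "pheno_gen_spec"))
  yrs <- sort(unique(climate$year))
  if (length(yrs) < 2) stop("need at least 2 climate years", call. = FALSE)
  years <- yrs[-1]
  tml <- .year_tmean(climate, years)
  e_true <- vapply(seq_along(years), function(i) {
    r <- dev_rate(spec$model, tml[[i]])
    a <- .attain_from_curve(cumsum(r), spec$s_start, 1)
    if (is.na(a$day) || a$day > 180) {
      stop(sprintf(
        "progress did not reach 100%% by day 180 in year %d", years[i]
      ), call. = FALSE)
    }
    a$day
  }, numeric(1))
  shift <- rep(0, length(years))
  shifts <- NULL
  if (length(spec$fwt_effects)) {
    feats <- fwt_features(climate, years, spec$s_start,
      critical_low = spec$critical_low,
      lower = spec$lower, upper = spec$upper
    )
    shifts <- sapply(names(spec$fwt_effects), function(nm) {
      x <- feats[[nm]]
      spec$fwt_effects[[nm]] * (x - mean(x))
    })
    shift <- rowSums(shifts)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  noise <- stats::rnorm(length(years), 0, spec$sigma_obs)
  e_obs_frac <- e_true + shift + noise
  pheno <- phenology_records(years, round(e_obs_frac))
  truth <- data.frame(
    year = years, e_true = e_true, shift = shift, noise = noise,
    e_obs_frac = e_obs_frac
  )
  if (!is.null(shifts)) {
    truth <- cbind(truth, stats::setNames(
      as.data.frame(shifts),
      paste0("shift_", names(spec$fwt_effects))
    ))
  }
  attr(pheno, "truth") <- truth
  pheno
}
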