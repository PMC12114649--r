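# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are deliberately written with different arithmetic/control flow
# than the implementation they check.

# Trapezoid attainment oracle: subdivide each day's increment into
# `substeps` equal parts and walk the refined piecewise-linear cumulative
# curve step by step, interpolating inside the crossing substep. The
# cumulative curve is linear within a day, so the refinement must agree
# with direct day-level interpolation.
oracle_attain_refined <- function(increments, threshold, s_start = 1,
                                  substeps = 24) {
  cum <- 0
  for (j in seq_along(increments)) {
    step <- increments[j] / substeps
    for (k in seq_len(substeps)) {
      nxt <- cum + step
      if (nxt >= threshold) {
        frac_in_step <- if (step == 0) 0 else (threshold - cum) / step
        day_frac <- (k - 1 + frac_in_step) / substeps
        return(s_start + j - 2 + day_frac)
      }
      cum <- nxt
    }
  }
  NA_real_
}

# Chill-hour oracle: hour-by-hour scalar evaluation using the identity
# sin(pi w / 12 - pi/2) = -cos(pi w / 12).
oracle_chill_hours <- function(t_min, t_max, lower = 0, upper = 7.2) {
  amp <- (t_max - t_min) / 2
  mid <- (t_max + t_min) / 2
  count <- 0L
  for (w in 1:24) {
    tw <- mid - amp * cos(pi * w / 12)
    if (tw > lower && tw < upper) count <- count + 1L
  }
  count
}

# Naive calendar iteration: count days from one (year, doy) to another by
# repeated date increments.
oracle_window_length <- function(from_year, from_doy, to_year, to_doy) {
  d <- doy_to_date(from_year, from_doy)
  end <- doy_to_date(to_year, to_doy)
  n <- 0L
  while (d <= end) {
    n <- n + 1L
    d <- d + 1
  }
  n
}

# Shared small synthetic study (13 climate years -> 12 phenology years),
# built once per test run.
.fixtures <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixtures$small)) {
    cs <- simulate_climate(climate_gen_spec(1980:1992, seed = 42))
    ph <- simulate_ffd(cs, pheno_gen_spec(sigma_obs = 0, seed = 42))
    .fixtures$small <- list(climate = cs, pheno = ph)
  }
  .fixtures$small
}

# A constant-temperature climate series (exact hand-computable windows).
constant_climate <- function(years, t_min, t_max, t_mean = (t_min + t_max) / 2) {
  dates <- seq(
    as.Date(paste0(min(years), "-01-01")),
    as.Date(paste0(max(years), "-12-31")),
    by = "day"
  )
  climate_series(data.frame(
    date = dates, t_min = t_min, t_max = t_max, t_mean = t_mean
  ))
}
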