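# Spring forcing-accumulation methods: ADD (accumulated degree days),
# ADTS (accumulated days transferred to a standardized temperature), and
# ADP (accumulated developmental progress with an arbitrary rate model).
#
# All three share the same prediction kernel: daily increments are summed
# from a starting day-of-year S until a mean annual requirement is reached,
# with the trapezoid method interpolating a fractional attainment day
# between consecutive days.

# Core attainment search on a cumulative sum. Returns list(day, deficit):
# `day` is NA when the threshold is never reached, with the remaining
# deficit reported. Exact attainment at day F returns F; a straddle between
# F and F+1 returns F + (threshold - C_F) / (C_{F+1} - C_F).
.attain <- function(increments, threshold, s_start = 1) {
  C <- cumsum(increments)
  n <- length(C)
  if (n == 0L || C[n] < threshold) {
    return(list(day = NA_real_, deficit = threshold - if (n) C[n] else 0))
  }
  j0 <- findInterval(threshold, C) # number of cumulative values <= threshold
  if (j0 >= 1L && C[j0] == threshold) {
    return(list(day = s_start + j0 - 1, deficit = 0))
  }
  prev <- if (j0 == 0L) 0 else C[j0]
  list(
    day = s_start + j0 - 1 + (threshold - prev) / (C[j0 + 1L] - prev),
    deficit = 0
  )
}

#' Fractional attainment day of a running accumulation (trapezoid method)
#'
#' Accumulates non-negative daily increments, the first of which belongs to
#' day `s_start`, until the running sum reaches `threshold`. If the sum
#' first equals the threshold exactly on day F, F is returned; if it
#' straddles the threshold between days F and F+1, the attainment day is
#' linearly interpolated on the cumulative curve (the trapezoid method),
#' giving a real-valued day-of-year.
#'
#' @param increments ordered non-negative daily increments starting at day
#'   `s_start`.
#' @param threshold positive accumulation requirement.
#' @param s_start day-of-year of the first increment (default 1).
#' @return fractional day-of-year of attainment. If the threshold is never
#'   reached an error of class `adpgam_non_attainment` is raised carrying
#'   the final `deficit`.
#' @examples
#' accumulate_until(rep(2, 10), 10) # day 5 exactly
#' accumulate_until(c(4, 5, 3), 10, s_start = 60) # 61.333...
#' @export
accumulate_until <- function(increments, threshold, s_start = 1) {
  if (any(increments < 0)) stop("negative increment", call. = FALSE)
  .assert_scalar_finite(threshold, "threshold")
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  res <- .attain(increments, threshold, s_start)
  if (is.na(res$day)) .stop_non_attainment(res$deficit)
  res$day
}

# Vectorised attainment against a precomputed full-year cumulative curve C
# (C[j] = accumulation over days 1..j). For each start S and threshold u,
# finds the fractional day where accumulation from S reaches u.
# Returns list(day, deficit) vectors.
.attain_from_curve <- function(C, s, u) {
  n <- length(C)
  C0 <- c(0, C)
  target <- C0[s] + u # absolute cumulative level to reach
  j0 <- findInterval(target, C)
  day <- rep(NA_real_, length(target))
  deficit <- pmax(0, target - C[n])
  hit <- target <= C[n]
  exact <- hit & j0 >= 1L & C[pmax(j0, 1L)] == target
  day[exact] <- j0[exact]
  interp <- hit & !exact
  if (any(interp)) {
    prev <- ifelse(j0[interp] == 0L, 0, C[pmax(j0[interp], 1L)])
    nxt <- C[j0[interp] + 1L]
    day[interp] <- j0[interp] + (target[interp] - prev) / (nxt - prev)
  }
  list(day = day, deficit = deficit)
}

#' Starting-date selection for the degree-day method (correlation protocol)
#'
#' For each candidate starting day-of-year S, computes per year the mean of
#' the daily mean temperatures over the inclusive window from S to the
#' observed event day, and the Pearson correlation of those means with the
#' observed days across years. The candidate with the lowest (most
#' negative) coefficient is selected: a warmer development window should
#' advance the event, so the "true" start shows the strongest
#' anticorrelation.
#'
#' @param climate a [climate_series()].
#' @param pheno phenology records (`year`, `ffd`), at least 3 years.
#' @param candidates candidate starting days-of-year; each must precede the
#'   earliest observed event day. Default 1:90.
#' @return list with `s_start` (selected day, earliest wins ties) and
#'   `profile` (data frame `candidate`, `correlation`).
#' @export
select_start_date_add <- function(climate, pheno, candidates = 1:90) {
  if (nrow(pheno) < 3L) stop("need at least 3 years", call. = FALSE)
  E <- pheno$ffd
  bad <- candidates >= min(E)
  if (any(bad)) {
    warning(sprintf(
      "%d candidate(s) not before the earliest observed day (%d) dropped",
      sum(bad), as.integer(min(E))
    ), call. = FALSE)
    candidates <- candidates[!bad]
  }
  if (!length(candidates)) stop("no admissible candidates", call. = FALSE)
  candidates <- sort(candidates)
  tml <- .year_tmean(climate, pheno$year, through_doy = NULL)
  # cumulative means via per-year cumulative sums over DOY
  cors <- vapply(candidates, function(s) {
    means <- vapply(seq_along(tml), function(i) {
      tm <- tml[[i]]
      e <- floor(E[i])
      mean(tm[s:e])
    }, numeric(1))
    if (stats::sd(means) == 0 || stats::sd(E) == 0) {
      warning("zero variance at candidate ", s, "; skipped", call. = FALSE)
      return(NA_real_)
    }
    stats::cor(means, E)
  }, numeric(1))
  ok <- !is.na(cors)
  if (!any(ok)) stop("all candidates skipped", call. = FALSE)
  best <- candidates[ok][which.min(cors[ok])]
  list(
    s_start = best,
    correlation = min(cors[ok]),
    profile = data.frame(candidate = candidates, correlation = cors)
  )
}

# Assemble the common per-year fit table and the method_fit object.
.method_fit <- function(method, family, s_start, params, threshold,
                        years, observed, predicted, rmse, extra = list()) {
  out <- c(
    list(
      method = method, family = family, s_start = s_start,
      params = params, threshold = threshold,
      per_year = data.frame(
        year = years, observed = observed, predicted = predicted,
        residual = observed - predicted
      ),
      rmse = rmse
    ),
    extra
  )
  class(out) <- "method_fit"
  out
}

#' @export
print.method_fit <- function(x, ...) {
  cat(sprintf(
    "<method_fit: %s%s> S = %d, %s, threshold = %.6g, RMSE = %.6f days (%d years)\n",
    x$method, if (!is.null(x$family)) paste0("-", x$family) else "",
    x$s_start,
    paste(names(x$params), signif(x$params, 6), sep = " = ", collapse = ", "),
    x$threshold, x$rmse, nrow(x$per_year)
  ))
  invisible(x)
}

#' Fit the accumulated degree-days (ADD) method
#'
#' With the starting day S fixed (normally chosen by
#' [select_start_date_add()]), scans candidate base temperatures T0. For
#' each T0 the annual requirement is
#' `k_i = sum over days S..E_i of max(T - T0, 0)` (days colder than the
#' biological zero contribute nothing); the mean requirement `kbar` is then
#' used to predict each year's event day by trapezoid accumulation of the
#' same daily increments, and the T0 with the lowest RMSE between observed
#' and predicted days wins (smallest T0 on ties).
#'
#' @param climate a [climate_series()].
#' @param pheno phenology records (`year`, `ffd`).
#' @param s_start starting day-of-year.
#' @param t0_candidates candidate base temperatures, degrees C. Default
#'   -5..5 in steps of 0.01.
#' @return a `method_fit` with `search` = data frame of the T0 grid and its
#'   RMSE profile. Candidates for which some year never attains the mean
#'   requirement get an infinite objective.
#' @export
fit_add <- function(climate, pheno, s_start,
                    t0_candidates = seq(-5, 5, by = 0.01)) {
  stopifnot(.is_count(s_start), s_start >= 1)
  if (any(pheno$ffd <= s_start)) {
    stop("observed event day on or before the starting day", call. = FALSE)
  }
  tml <- .year_tmean(climate, pheno$year)
  E <- floor(pheno$ffd)
  n <- length(E)
  eval_t0 <- function(t0) {
    pred <- numeric(n)
    k <- numeric(n)
    curves <- vector("list", n)
    for (i in seq_len(n)) {
      C <- cumsum(pmax(tml[[i]] - t0, 0))
      curves[[i]] <- C
      k[i] <- C[E[i]] - c(0, C)[s_start]
    }
    kbar <- mean(k)
    for (i in seq_len(n)) {
      a <- .attain_from_curve(curves[[i]], s_start, kbar)
      pred[i] <- a$day
    }
    list(
      rmse = if (anyNA(pred)) Inf else .rmse(pheno$ffd - pred),
      kbar = kbar, pred = pred, k = k
    )
  }
  prof <- vapply(t0_candidates, function(t0) eval_t0(t0)$rmse, numeric(1))
  if (all(!is.finite(prof))) {
    stop("no base-temperature candidate attains the requirement",
      call. = FALSE
    )
  }
  best_t0 <- t0_candidates[which.min(prof)]
  best <- eval_t0(best_t0)
  .method_fit(
    "ADD", NULL, as.integer(s_start), c(t0 = best_t0), best$kbar,
    pheno$year, pheno$ffd, best$pred, best$rmse,
    extra = list(
      k_per_year = best$k,
      search = data.frame(t0 = t0_candidates, rmse = prof)
    )
  )
}

#' Fit the accumulated days-transferred-to-standard-temperature (ADTS) method
#'
#' Each day at mean temperature T contributes `dts(T, Ea)` equivalent days
#' at the 25 C standard. A full grid over candidate starting days S and
#' activation energies Ea is evaluated: the annual accumulated DTS
#' `U_i = sum over S..E_i`, its mean `Ubar`, the trapezoid-predicted day
#' for each year, and the RMSE; the (S, Ea) pair with the lowest RMSE is
#' selected (smallest S, then smallest Ea, on ties).
#'
#' @inheritParams fit_add
#' @param s_candidates candidate starting days-of-year (default 1:90).
#' @param ea_candidates candidate activation energies, kcal mol^-1
#'   (default 1..40 step 0.1).
#' @return a `method_fit`; `surface` holds the full RMSE objective matrix
#'   (rows = S candidates, columns = Ea candidates) for contour plotting.
#' @export
fit_adts <- function(climate, pheno, s_candidates = 1:90,
                     ea_candidates = seq(1, 40, by = 0.1)) {
  if (!length(s_candidates) || !length(ea_candidates)) {
    stop("empty candidate grid", call. = FALSE)
  }
  s_candidates <- sort(unique(as.integer(s_candidates)))
  ea_candidates <- sort(unique(ea_candidates))
  if (any(pheno$ffd <= max(s_candidates))) {
    stop("candidate starting days must precede every observed event day",
      call. = FALSE
    )
  }
  tml <- .year_tmean(climate, pheno$year)
  E <- floor(pheno$ffd)
  n <- length(E)
  ts <- thermal_constants$t_standard
  # dts(T, Ea) = exp(Ea * g(T)); precompute g per day once
  gl <- lapply(tml, function(tm) {
    tk <- tm + 273.15
    (tk - ts) / (thermal_constants$r_gas * tk * ts)
  })
  ns <- length(s_candidates)
  surface <- matrix(NA_real_, nrow = ns, ncol = length(ea_candidates),
    dimnames = list(s_candidates, ea_candidates)
  )
  best <- list(rmse = Inf)
  for (e_idx in seq_along(ea_candidates)) {
    ea <- ea_candidates[e_idx]
    Cl <- lapply(gl, function(g) cumsum(exp(ea * g)))
    U <- matrix(0, nrow = n, ncol = ns)
    for (i in seq_len(n)) {
      Ci <- Cl[[i]]
      U[i, ] <- Ci[E[i]] - c(0, Ci)[s_candidates]
    }
    ubar <- colMeans(U)
    pred <- matrix(NA_real_, nrow = n, ncol = ns)
    for (i in seq_len(n)) {
      pred[i, ] <- .attain_from_curve(Cl[[i]], s_candidates, ubar)$day
    }
    res <- pheno$ffd - pred
    rmse_s <- sqrt(colMeans(res^2)) # NA when some year never attains
    rmse_s[is.na(rmse_s)] <- Inf
    surface[, e_idx] <- rmse_s
    s_idx <- which.min(rmse_s) # earliest S wins ties
    if (rmse_s[s_idx] < best$rmse) { # strict `<`: smallest Ea wins ties
      best <- list(
        rmse = rmse_s[s_idx], s = s_candidates[s_idx], ea = ea,
        ubar = ubar[s_idx], pred = pred[, s_idx], u = U[, s_idx]
      )
    }
  }
  if (!is.finite(best$rmse)) {
    stop("no (S, Ea) combination attains the requirement", call. = FALSE)
  }
  .method_fit(
    "ADTS", NULL, best$s, c(ea = best$ea), best$ubar,
    pheno$year, pheno$ffd, best$pred, best$rmse,
    extra = list(
      u_per_year = best$u,
      surface = surface,
      s_candidates = s_candidates, ea_candidates = ea_candidates
    )
  )
}

# Objective factory for the ADP optimizer: RMSE with non-attainment years
# penalized by (last day - E_i) + 100 * deficit, keeping the surface finite
# and decreasing as the deficit shrinks (simplex-friendly). Rates for all
# years are evaluated in one vectorised call per objective evaluation.
.adp_make_objective <- function(family, tml, s_start, E_obs) {
  tm_flat <- unlist(tml, use.names = FALSE)
  lens <- lengths(tml)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  n <- length(tml)
  names_p <- .rate_param_names[[family]]
  function(par) {
    if (any(!is.finite(par))) return(1e12)
    params <- stats::setNames(par, names_p)
    if (family == "logan" && (params[["psi"]] <= 0 || params[["z"]] <= 0)) {
      return(1e12)
    }
    if (family == "logistic" &&
      !(params[["K0"]] > 0 && params[["K0"]] < params[["K"]])) {
      return(1e12)
    }
    r <- .dev_rate_raw(family, params, tm_flat)
    if (any(!is.finite(r))) return(1e12)
    res <- numeric(n)
    for (i in seq_len(n)) {
      C <- cumsum(r[starts[i]:ends[i]])
      nn <- lens[i]
      target <- (if (s_start > 1L) C[s_start - 1L] else 0) + 1
      if (C[nn] < target) {
        res[i] <- (nn - E_obs[i]) + 100 * (target - C[nn])
      } else {
        j0 <- findInterval(target, C)
        day <- if (j0 >= 1L && C[j0] == target) {
          j0
        } else {
          prev <- if (j0 == 0L) 0 else C[j0]
          j0 + (target - prev) / (C[j0 + 1L] - prev)
        }
        res[i] <- E_obs[i] - day
      }
    }
    sqrt(mean(res * res))
  }
}

# Initial parameter vector for a family; "auto" chains from a light ADTS-
# style scan for arrhenius (Ea from a coarse grid at this S, B chosen so
# the mean accumulated progress at the observed days is exactly 1), and
# literature-scale values for logan/logistic.
.adp_init <- function(family, tml, s_start, E_obs) {
  if (family == "arrhenius") {
    rg <- thermal_constants$r_gas
    qfun <- function(ea) {
      vapply(seq_along(tml), function(i) {
        tm <- tml[[i]][s_start:floor(E_obs[i])]
        sum(thermal_constants$arrhenius_scale * exp(-ea / (rg * (tm + 273.15))))
      }, numeric(1))
    }
    ea_grid <- seq(5, 30, by = 1)
    # Ea for which the annual requirements are most nearly constant
    cv <- vapply(ea_grid, function(ea) {
      q <- qfun(ea)
      stats::sd(q) / mean(q)
    }, numeric(1))
    ea0 <- ea_grid[which.min(cv)]
    b0 <- -log(mean(qfun(ea0)))
    c(B = b0, Ea = ea0)
  } else if (family == "linear") {
    c(a = 0.02, b = 0.004)
  } else if (family == "logan") {
    c(psi = 0.01, rho = 0.1, t_u = 40, z = 6)
  } else {
    c(K = 0.15, K0 = 0.01, b = 0.1)
  }
}

#' Fit the accumulated developmental-progress (ADP) method
#'
#' For each candidate starting day S, the parameters of the chosen
#' developmental-rate equation are estimated by Nelder-Mead minimization of
#' the RMSE between observed event days and the days at which the
#' accumulated daily rates (developmental progress) reach 100%; the
#' (S, parameters) pair with the global minimum RMSE is returned. Years in
#' which progress never reaches 100% during a candidate evaluation receive
#' a large finite penalty so the simplex can recover.
#'
#' @inheritParams fit_adts
#' @param family rate-equation family (see [rate_model()]).
#' @param init `"auto"` (default) or a named numeric vector of starting
#'   parameters. Auto initialization chains the Arrhenius start from a
#'   coarse equivalent-days scan and uses literature-scale values for the
#'   other families.
#' @param n_restarts number of jittered restarts per candidate S (the
#'   best of the base start, a warm start from the previous S, and the
#'   jittered starts is kept). `NULL` (default) chooses 0 for the
#'   well-conditioned arrhenius/linear families and 5 for logan/logistic.
#' @param control passed to [stats::optim()]; defaults to
#'   `reltol = 1e-8, maxit = 2000`.
#' @return a `method_fit`; extras: `model` (the fitted [rate_model()]),
#'   `progress_at_observed` (per-year accumulated progress V_i evaluated at
#'   the observed day, 1 in a perfect fit), and `search` (per-S best RMSE).
#' @export
fit_adp <- function(climate, pheno, s_candidates = 1:90,
                    family = c("arrhenius", "linear", "logan", "logistic"),
                    init = "auto", n_restarts = NULL,
                    control = list(reltol = 1e-8, maxit = 2000)) {
  family <- match.arg(family)
  if (is.null(n_restarts)) {
    n_restarts <- if (family %in% c("logan", "logistic")) 5L else 0L
  }
  if (!length(s_candidates)) stop("empty S candidates", call. = FALSE)
  s_candidates <- sort(unique(as.integer(s_candidates)))
  if (any(pheno$ffd <= max(s_candidates))) {
    stop("candidate starting days must precede every observed event day",
      call. = FALSE
    )
  }
  tml <- .year_tmean(climate, pheno$year)
  E_obs <- pheno$ffd
  best <- list(rmse = Inf)
  search <- data.frame(s = s_candidates, rmse = NA_real_)
  prev_par <- NULL
  auto_p0 <- NULL
  for (si in seq_along(s_candidates)) {
    s <- s_candidates[si]
    p0 <- if (identical(init, "auto")) {
      # the auto start is insensitive to S at this resolution: compute once
      if (is.null(auto_p0)) auto_p0 <- .adp_init(family, tml, s, E_obs)
      auto_p0
    } else {
      unlist(init)[.rate_param_names[[family]]]
    }
    starts <- list(p0)
    if (!is.null(prev_par)) starts <- c(starts, list(prev_par))
    if (n_restarts > 0) {
      for (j in seq_len(n_restarts)) {
        jit <- p0 * (1 + 0.1 * sin(1000 * j + seq_along(p0))) # deterministic jitter
        starts <- c(starts, list(jit))
      }
    }
    objective <- .adp_make_objective(family, tml, s, E_obs)
    s_best <- list(value = Inf)
    for (st in starts) {
      opt <- tryCatch(
        stats::optim(st, objective,
          method = "Nelder-Mead", control = control
        ),
        error = function(e) NULL
      )
      if (!is.null(opt) && opt$value < s_best$value) s_best <- opt
    }
    search$rmse[si] <- s_best$value
    if (is.finite(s_best$value)) prev_par <- s_best$par
    if (s_best$value < best$rmse) { # strict `<`: smallest S wins ties
      best <- list(rmse = s_best$value, s = s, par = s_best$par)
    }
  }
  if (!is.finite(best$rmse)) {
    stop("ADP optimization failed for every candidate S", call. = FALSE)
  }
  params <- stats::setNames(best$par, .rate_param_names[[family]])
  model <- rate_model(family, params)
  n <- nrow(pheno)
  pred <- numeric(n)
  v_obs <- numeric(n)
  for (i in seq_len(n)) {
    C <- cumsum(dev_rate(model, tml[[i]]))
    a <- .attain_from_curve(C, best$s, 1)
    pred[i] <- a$day
    v_obs[i] <- C[floor(E_obs[i])] - c(0, C)[best$s]
  }
  rmse <- if (anyNA(pred)) best$rmse else .rmse(E_obs - pred)
  .method_fit(
    "ADP", family, best$s, params, 1,
    pheno$year, E_obs, pred, rmse,
    extra = list(
      model = model, progress_at_observed = v_obs, search = search
    )
  )
}

# Daily increments of a fitted method for a vector of daily mean temps.
.fit_increments <- function(fit, tm) {
  switch(fit$method,
    ADD = pmax(tm - fit$params[["t0"]], 0),
    ADTS = dts(tm, fit$params[["ea"]]),
    ADP = dev_rate(fit$model, tm),
    stop("unknown method", call. = FALSE)
  )
}

#' Apply a fitted forcing method to (possibly new) years
#'
#' Applies the fitted starting day, parameters and threshold to the climate
#' of the requested years. On the training years this reproduces the
#' `per_year` predictions of the fit exactly.
#'
#' @param fit a `method_fit` from [fit_add()], [fit_adts()] or [fit_adp()].
#' @param climate a [climate_series()] covering each requested year.
#' @param years integer years to predict.
#' @return data frame `year`, `predicted` (fractional day-of-year; `NA`
#'   with the remaining `deficit` filled in for years whose accumulation
#'   never reaches the requirement).
#' @export
predict_years <- function(fit, climate, years) {
  tml <- .year_tmean(climate, years)
  pred <- numeric(length(years))
  deficit <- rep(0, length(years))
  for (i in seq_along(years)) {
    inc <- .fit_increments(fit, tml[[i]])
    a <- .attain_from_curve(cumsum(inc), fit$s_start, fit$threshold)
    pred[i] <- a$day
    deficit[i] <- a$deficit
  }
  data.frame(year = years, predicted = pred, deficit = deficit)
}
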