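# Temperature-dependent developmental-rate equations and the
# days-transferred-to-standard-temperature (DTS) kernel.
#
# Temperatures are handled in degrees Celsius throughout the package;
# conversion to Kelvin (T + 273.15, exactly) happens only here, inside the
# Arrhenius-type evaluations.

#' Physical constants used by the thermal models
#'
#' `r_gas` is the universal gas constant in kcal mol^-1 K^-1, `t_standard`
#' the standard temperature 25 degrees C in Kelvin, and `arrhenius_scale`
#' the 1e12 factor applied to the Arrhenius pre-exponential constant so the
#' fitted intercept B stays of order one.
#'
#' @export
thermal_constants <- list(
  r_gas = 1.987e-3,
  t_standard = 298.15,
  arrhenius_scale = 1e12
)

.rate_param_names <- list(
  linear = c("a", "b"),
  arrhenius = c("B", "Ea"),
  logan = c("psi", "rho", "t_u", "z"),
  logistic = c("K", "K0", "b")
)

#' Define a temperature-dependent developmental-rate model
#'
#' Four families are supported:
#' \describe{
#'   \item{linear}{`r = a + b T`, floored at 0 below the biological zero
#'     `T0 = -a/b` (development cannot regress).}
#'   \item{arrhenius}{`r = 1e12 * exp(B - Ea / (R T_K))` with `T_K` in
#'     Kelvin, `Ea` in kcal mol^-1.}
#'   \item{logan}{`r = psi * (exp(rho T) - exp(rho t_u - (t_u - T) / z))`,
#'     floored at 0; a left-skewed bell shape with upper lethal
#'     temperature `t_u`.}
#'   \item{logistic}{`r = K / (1 + (K / K0 - 1) exp(-b T))`, a sigmoid in
#'     degrees C with asymptote `K` and initial rate `K0` at `T = 0`.}
#' }
#'
#' @param family one of `"linear"`, `"arrhenius"`, `"logan"`, `"logistic"`.
#' @param params named numeric vector (or list) of the family's parameters:
#'   linear `a, b`; arrhenius `B, Ea`; logan `psi, rho, t_u, z`;
#'   logistic `K, K0, b`.
#' @return an object of class `rate_model`.
#' @examples
#' m <- rate_model("arrhenius", c(B = -4.38, Ea = 15.04))
#' dev_rate(m, 10)
#' @export
rate_model <- function(family = c("linear", "arrhenius", "logan", "logistic"),
                       params) {
  family <- match.arg(family)
  params <- unlist(params)
  need <- .rate_param_names[[family]]
  if (!all(need %in% names(params))) {
    stop(sprintf(
      "family `%s` needs parameters: %s", family,
      paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  params <- params[need]
  if (any(!is.finite(params))) {
    stop("non-finite rate-model parameter", call. = FALSE)
  }
  if (family == "logan" && params[["z"]] == 0) {
    stop("logan parameter `z` must be non-zero", call. = FALSE)
  }
  if (family == "logistic" &&
    !(params[["K0"]] > 0 && params[["K0"]] < params[["K"]])) {
    stop("logistic requires 0 < K0 < K", call. = FALSE)
  }
  structure(list(family = family, params = params), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(
    "<rate_model: %s> %s\n", x$family,
    paste(names(x$params), signif(x$params, 6), sep = " = ", collapse = ", ")
  ))
  invisible(x)
}

# Unchecked evaluation used inside optimizer loops (params as plain vector).
.dev_rate_raw <- function(family, params, t) {
  switch(family,
    linear = pmax(0, params[["a"]] + params[["b"]] * t),
    arrhenius = {
      tk <- t + 273.15
      thermal_constants$arrhenius_scale *
        exp(params[["B"]] - params[["Ea"]] / (thermal_constants$r_gas * tk))
    },
    logan = pmax(0, params[["psi"]] * (exp(params[["rho"]] * t) -
      exp(params[["rho"]] * params[["t_u"]] -
        (params[["t_u"]] - t) / params[["z"]]))),
    logistic = pmax(0, params[["K"]] /
      (1 + (params[["K"]] / params[["K0"]] - 1) * exp(-params[["b"]] * t))),
    stop("unknown rate family: ", family, call. = FALSE)
  )
}

#' Evaluate a developmental rate (per day)
#'
#' @param model a [rate_model()].
#' @param t temperature(s), degrees C.
#' @return developmental rate(s), day^-1, finite and >= 0 (closed forms
#'   that go negative are clamped to zero).
#' @export
dev_rate <- function(model, t) {
  if (!inherits(model, "rate_model")) {
    stop("`model` must be a rate_model", call. = FALSE)
  }
  if (any(!is.finite(t))) stop("non-finite temperature", call. = FALSE)
  .dev_rate_raw(model$family, model$params, t)
}

#' Days transferred to a standardized temperature (DTS factor)
#'
#' The Arrhenius ratio of developmental rates between temperature `t` and
#' the standard temperature `t_s`:
#' `exp(e_a (T_K - t_s) / (R T_K t_s))` with `T_K = t + 273.15`. It equals
#' 1 at `T_K = t_s` and is strictly increasing in `t`; one day at
#' temperature `t` counts as `dts(t, ...)` days at the standard
#' temperature.
#'
#' @param t temperature(s), degrees C.
#' @param e_a activation energy, kcal mol^-1 (> 0 for the usual
#'   increasing-rate case; 0 gives a factor of exactly 1).
#' @param t_s standard temperature in Kelvin (default 298.15 K = 25 C).
#' @return dimensionless DTS factor(s).
#' @export
dts <- function(t, e_a, t_s = thermal_constants$t_standard) {
  if (any(t <= -273.15)) stop("temperature below absolute zero", call. = FALSE)
  tk <- t + 273.15
  exp(e_a * (tk - t_s) / (thermal_constants$r_gas * tk * t_s))
}

#' Developmental duration implied by a rate model
#'
#' The reciprocal of the developmental rate: the number of days a stage
#' would take at constant temperature `t`. A zero rate yields `Inf` with a
#' warning (explicit infinite-duration signal).
#'
#' @inheritParams dev_rate
#' @return duration(s) in days.
#' @export
reciprocal_duration <- function(model, t) {
  r <- dev_rate(model, t)
  if (any(r == 0)) {
    warning("zero developmental rate: infinite duration returned",
      call. = FALSE
    )
  }
  1 / r
}
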