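# Internal helpers shared across modules.

.rmse <- function(x) sqrt(mean(x^2))

# Signal used when an accumulation never reaches its threshold within the
# supplied window; carries the remaining deficit so callers can penalize.
.stop_non_attainment <- function(deficit, call = sys.call(-1)) {
  stop(structure(
    class = c("adpgam_non_attainment", "error", "condition"),
    list(
      message = sprintf(
        "accumulation never reached its threshold (remaining deficit: %g)",
        deficit
      ),
      call = call, deficit = deficit
    )
  ))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

.assert_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
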