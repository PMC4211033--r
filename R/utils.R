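# Internal helpers shared across modules.

# Round half away from zero (presentation rounding for integer Heart Ages;
# base round() uses banker's rounding which would map 54.5 to 54).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Inverse-CDF draw from a normal truncated to [lo, hi].
# u is Uniform(0,1) (or pnorm of a copula normal score).
qtruncnorm <- function(u, mean, sd, lo, hi) {
  if (any(sd < 0)) stop("sd must be non-negative")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  out <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  # guard against qnorm(1) at extreme u
  pmin(pmax(out, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stop_heartage <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "heartage_error")))
}
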