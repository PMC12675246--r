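# Shared internal helpers: classed conditions and numeric conventions.

stop_sarco <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sarcostage_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_validation <- function(msg) stop_sarco(msg, "sarcostage_validation_error")
stop_config     <- function(msg) stop_sarco(msg, "sarcostage_config_error")
stop_degenerate <- function(msg) stop_sarco(msg, "sarcostage_degenerate_error")

#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used when comparing
#' derived weights against published 3-decimal tables (base `round()` uses
#' round-half-even, which differs on exact halves).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Exact inverse-CDF truncated normal (no accept/reject, fully deterministic
# in the number of uniforms consumed, which keeps cohorts seed-stable).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

is_prob_vector <- function(p, tol = 1e-9) {
  is.numeric(p) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}
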