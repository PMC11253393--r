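# Shared fixtures, built in code.

# Study-condition point estimates
A0 <- 0.066
PI_TARGET <- 0.053
OR_POINT <- 3.04
A1_MEAN <- 10.5 / 80.5

# Independent calibration oracle: stats::uniroot on the same mixture, kept
# separate from the package's bisection implementation.
uniroot_p0 <- function(pi_target = PI_TARGET, a0 = A0, or_point = OR_POINT) {
  f <- function(p0) {
    q <- (or_point * p0 / (1 - p0)) / (1 + or_point * p0 / (1 - p0))
    (1 - a0) * p0 + a0 * q - pi_target
  }
  stats::uniroot(f, c(1e-12, pi_target), tol = 1e-14)$root
}

calibrated_params <- function(...) {
  model_parameters(p0 = uniroot_p0(), ...)
}

# Degenerate specs: distributions collapsed to (near) point masses at the
# study point estimates, for deterministic simulation checks.
degenerate_params <- function(...) {
  model_parameters(
    p0 = uniroot_p0(),
    a1_spec = beta_spec(10.5e9, 70e9),
    or_spec = lognormal_spec(OR_POINT, 0),
    ...
  )
}

# Brute-force percentile oracle: linear interpolation between order
# statistics, written directly from the definition.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
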