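#' Calibrate the no-anxiety misuse probability
#'
#' Solves for `p0`, the opioid-misuse probability among those without
#' anxiety, so that the baseline two-stratum mixture reproduces the target
#' overall misuse prevalence:
#' `baseline_prevalence(p0, a0, or_point) == pi_target`.
#'
#' `baseline_prevalence()` is strictly increasing in `p0`, so bisection on
#' the bracket `(0, pi_target]` converges unconditionally; the upper bracket
#' end suffices because the anxiety stratum can only raise the mixture above
#' `p0`. The odds ratio is held at its point estimate (3.04, the median of
#' the source studies) during calibration.
#'
#' @param pi_target Target overall misuse prevalence, in (0, 1).
#' @param a0 Baseline anxiety prevalence, in (0, 1).
#' @param or_point Odds-ratio point estimate (>= 1).
#' @param tolerance Convergence tolerance in prevalence units (> 0).
#' @return A `calibration_result`: list with `p0`, `achieved` (baseline
#'   prevalence at `p0`), `iterations`, `tolerance`.
#' @examples
#' calibrate_p0(0.053, 0.066, 3.04)
#' @export
calibrate_p0 <- function(pi_target, a0, or_point = 3.04,
                         tolerance = 1e-10) {
  check_probability(pi_target, "pi_target")
  check_probability(a0, "a0", open = FALSE)
  if (!is.numeric(or_point) || length(or_point) != 1L ||
      !is.finite(or_point) || or_point < 1) {
    stop("`or_point` must be a single finite value >= 1", call. = FALSE)
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("`tolerance` must be positive", call. = FALSE)
  }

  f <- function(p0) baseline_prevalence(p0, a0, or_point) - pi_target
  lo <- 0
  hi <- pi_target
  if (f(hi) < 0) {
    # cannot happen for or_point >= 1 (mixture at p0 = pi_target overshoots)
    stop("no sign change on the calibration bracket", call. = FALSE)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tolerance || (hi - lo) / 2 < .Machine$double.eps * hi) {
      break
    }
    if (fm < 0) lo <- mid else hi <- mid
    if (iter > 200L) break
  }
  structure(
    list(p0 = mid, achieved = baseline_prevalence(mid, a0, or_point),
         iterations = iter, tolerance = tolerance,
         pi_target = pi_target, a0 = a0, or_point = or_point),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibrated p0 = %.8f (baseline prevalence %.8f, target %.8f)\n",
    x$p0, x$achieved, x$pi_target))
  cat(sprintf("  %d bisection iterations, tolerance %g\n",
              x$iterations, x$tolerance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_result <- function(x, ...) {
  tibble::tibble(
    p0 = x$p0, achieved = x$achieved, pi_target = x$pi_target,
    a0 = x$a0, or_point = x$or_point,
    iterations = x$iterations, tolerance = x$tolerance
  )
}
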