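#' Odds/probability conversion
#'
#' `prob_to_odds()` maps a probability to odds `p / (1 - p)`;
#' `odds_to_prob()` is its inverse `o / (1 + o)`. Both are vectorized.
#'
#' @param p Probabilities in \[0, 1); `p = 1` has infinite odds and errors.
#' @param o Non-negative odds.
#' @return Numeric vector.
#' @examples
#' prob_to_odds(0.5)
#' odds_to_prob(prob_to_odds(0.25))
#' @export
prob_to_odds <- function(p) {
  check_prob_vec(p, upper_open = TRUE)
  p / (1 - p)
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(o) {
  if (!is.numeric(o) || any(!is.finite(o)) || any(o < 0)) {
    stop("odds must be finite and non-negative", call. = FALSE)
  }
  o / (1 + o)
}

#' Apply an odds ratio to a reference probability
#'
#' Converts `p_ref` to odds, multiplies by the odds ratio, and converts back:
#' `odds_to_prob(or * prob_to_odds(p_ref))`. Strictly increasing in `or` and
#' equal to `p_ref` at `or = 1`. Used for the misuse probability in the
#' anxiety stratum.
#'
#' @param p_ref Reference probability in \[0, 1).
#' @param or Positive odds ratio(s).
#' @return Probabilities in \[0, 1).
#' @examples
#' prob_under_or(0.04746, 3.04)
#' @export
prob_under_or <- function(p_ref, or) {
  if (!is.numeric(or) || any(!is.finite(or)) || any(or <= 0)) {
    stop("`or` must be positive and finite", call. = FALSE)
  }
  odds_to_prob(or * prob_to_odds(p_ref))
}

#' Apply a risk ratio with saturation
#'
#' Multiplies a probability by a risk ratio, capping the result at 1:
#' `min(1, rr * p_ref)`.
#'
#' @param p_ref Probabilities in \[0, 1\].
#' @param rr Positive risk ratio(s).
#' @return Probabilities in \[0, 1\].
#' @examples
#' apply_risk_ratio(0.04746, 5)
#' @export
apply_risk_ratio <- function(p_ref, rr) {
  check_prob_vec(p_ref, upper_open = FALSE)
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0)) {
    stop("`rr` must be positive and finite", call. = FALSE)
  }
  pmin(1, rr * p_ref)
}

#' Baseline opioid-misuse prevalence
#'
#' The pre-wildfire two-stratum mixture: a fraction `a0` of the population
#' has anxiety and misuses opioids with the OR-elevated probability, the rest
#' with `p0`:
#' \deqn{\pi_0 = (1 - a_0)\,p_0 + a_0\,\mathrm{prob\_under\_or}(p_0, OR).}
#'
#' @param p0 Misuse probability absent anxiety.
#' @param a0 Baseline anxiety prevalence.
#' @param or Odds ratio(s) for misuse given anxiety.
#' @return Prevalence(s) in \[0, 1).
#' @examples
#' baseline_prevalence(0.04746, 0.066, 3.04)
#' @export
baseline_prevalence <- function(p0, a0, or) {
  (1 - a0) * p0 + a0 * prob_under_or(p0, or)
}

scenario_ids <- function() c("baseline", "s1", "s2", "s3")

#' Scenario prevalence formulas
#'
#' The three post-wildfire scenarios share one pair of Monte Carlo draws —
#' the post-wildfire anxiety prevalence `a1_draw` and the misuse odds ratio
#' `or_draw` — and differ in how the anxiety mass maps to misuse
#' probabilities. With `a1_eff = max(a1_draw, a0)` (when flooring is on) and
#' `q = prob_under_or(p0, or_draw)`:
#'
#' * `baseline`: \eqn{(1-a_0)p_0 + a_0 q} — no wildfire.
#' * `s1`: \eqn{(1-a_1)p_0 + a_1 q} — wildfire only raises anxiety
#'   incidence.
#' * `s2`: \eqn{(1-a_1)p_0 + a_0 q + (a_1-a_0)\min(1, RR_2 p_0)} —
#'   wildfire-incident anxiety carries a predisposition to misuse (risk
#'   ratio), pre-existing anxiety keeps the OR-implied probability.
#' * `s3`: \eqn{(1-a_1)p_0 + a_1 \min(1, RR_3 p_0)} — worsening of
#'   pre-existing anxiety too: the risk ratio applies to the whole anxiety
#'   mass.
#'
#' @param scenario One of `"baseline"`, `"s1"`, `"s2"`, `"s3"`.
#' @param params A [model_parameters()] object with `p0` set (calibrated).
#' @param a1_draw Sampled post-wildfire anxiety prevalence(s).
#' @param or_draw Sampled odds ratio(s); recycled with `a1_draw`.
#' @return Prevalence(s) in \[0, 1\].
#' @examples
#' p <- model_parameters(p0 = 0.04746)
#' scenario_prevalence("s3", p, a1_draw = 10.5 / 80.5, or_draw = 3.04)
#' @export
scenario_prevalence <- function(scenario, params, a1_draw, or_draw) {
  scenario <- match.arg(scenario, scenario_ids())
  stopifnot(inherits(params, "model_parameters"))
  if (is.null(params$p0)) {
    stop("`params$p0` is not set; calibrate first (see `calibrate_p0()`)",
         call. = FALSE)
  }
  check_prob_vec(a1_draw, upper_open = FALSE)
  p0 <- params$p0
  a0 <- params$a0
  a1 <- if (params$floor_a1) pmax(a1_draw, a0) else a1_draw
  switch(scenario,
    baseline = baseline_prevalence(p0, a0, or_draw),
    s1 = (1 - a1) * p0 + a1 * prob_under_or(p0, or_draw),
    s2 = (1 - a1) * p0 + a0 * prob_under_or(p0, or_draw) +
      (a1 - a0) * apply_risk_ratio(p0, params$rr_s2),
    s3 = (1 - a1) * p0 + a1 * apply_risk_ratio(p0, params$rr_s3)
  )
}

#' Prevalence ratio
#'
#' Ratio of a scenario prevalence to a reference prevalence.
#'
#' @param pi_s Scenario prevalence(s).
#' @param pi_ref Reference prevalence(s); must be positive.
#' @return Positive ratio(s).
#' @examples
#' prevalence_ratio(0.072, 0.053)
#' @export
prevalence_ratio <- function(pi_s, pi_ref) {
  if (!is.numeric(pi_ref) || any(!is.finite(pi_ref)) || any(pi_ref <= 0)) {
    stop("`pi_ref` must be positive", call. = FALSE)
  }
  pi_s / pi_ref
}

check_prob_vec <- function(p, upper_open = TRUE) {
  bad <- !is.numeric(p) || any(!is.finite(p)) || any(p < 0) ||
    if (upper_open) any(p >= 1) else any(p > 1)
  if (bad) {
    stop(sprintf("probabilities must lie in %s",
                 if (upper_open) "[0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(p)
}
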