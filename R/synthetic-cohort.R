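#' Simulate an individual-level synthetic cohort
#'
#' Generates the microsimulation twin of one Monte Carlo draw: each person is
#' assigned an anxiety stratum by a single categorical draw (`none`,
#' `pre_existing`, `incident`) and then a Bernoulli misuse indicator with the
#' scenario's stratum-specific probability. The empirical misuse prevalence
#' of a large cohort converges to [scenario_prevalence()] evaluated at the
#' same `(a1, or_)`, which makes the cohort a brute-force oracle for the
#' cohort-level algebra.
#'
#' Stratum masses: `none` has probability `1 - a1`, `pre_existing` has `a0`,
#' `incident` has `a1 - a0` (for `"baseline"`, `a1` is taken equal to `a0`,
#' so the incident mass is zero). Misuse probabilities per stratum follow the
#' scenario rules: `p0` for `none`; the OR-implied probability for anxiety
#' strata under `"baseline"`/`"s1"` and for `pre_existing` under `"s2"`; the
#' capped risk-ratio probability for `incident` under `"s2"` and for both
#' anxiety strata under `"s3"`.
#'
#' @param scenario `"baseline"`, `"s1"`, `"s2"` or `"s3"`.
#' @param params A [model_parameters()] object with `p0` set.
#' @param a1 Post-wildfire anxiety prevalence; must be >= `params$a0` for
#'   post-wildfire scenarios (floor upstream). Ignored for `"baseline"`.
#' @param or_ Odds ratio for misuse given anxiety.
#' @param n Cohort size (>= 1).
#' @param seed Optional integer seed.
#' @return Tibble with columns `person_id`, `anxiety_stratum` (factor with
#'   levels none/pre_existing/incident) and `misuse` (0/1 integer).
#' @examples
#' p <- model_parameters(p0 = 0.04746)
#' cohort <- simulate_cohort("s1", p, a1 = 0.13, or_ = 3.04,
#'                           n = 1000, seed = 1)
#' summarize_cohort(cohort)
#' @export
simulate_cohort <- function(scenario, params, a1, or_, n, seed = NULL) {
  scenario <- match.arg(scenario, scenario_ids())
  stopifnot(inherits(params, "model_parameters"))
  if (is.null(params$p0)) {
    stop("`params$p0` is not set; calibrate first", call. = FALSE)
  }
  check_n_draws(n)
  if (scenario == "baseline") {
    a1 <- params$a0
  } else {
    check_probability(a1, "a1", open = FALSE)
    if (a1 < params$a0) {
      stop("`a1` must be >= `a0` for post-wildfire scenarios", call. = FALSE)
    }
  }
  p0 <- params$p0
  q_or <- prob_under_or(p0, or_)
  p_misuse <- c(
    none = p0,
    pre_existing = switch(scenario,
      baseline = q_or, s1 = q_or, s2 = q_or,
      s3 = apply_risk_ratio(p0, params$rr_s3)),
    incident = switch(scenario,
      baseline = p0, # mass is zero; value irrelevant
      s1 = q_or,
      s2 = apply_risk_ratio(p0, params$rr_s2),
      s3 = apply_risk_ratio(p0, params$rr_s3))
  )
  strata <- c("none", "pre_existing", "incident")
  probs <- c(1 - a1, params$a0, a1 - params$a0)
  draw_seeded(seed, function() {
    stratum <- sample(strata, n, replace = TRUE, prob = probs)
    misuse <- stats::rbinom(n, 1L, p_misuse[stratum])
    tibble::tibble(
      person_id = seq_len(n),
      anxiety_stratum = factor(stratum, levels = strata),
      misuse = misuse
    )
  })
}

#' Summarize a synthetic cohort
#'
#' Exact counts and proportions per anxiety stratum, overall misuse
#' prevalence, and the empirical misuse odds ratio comparing the
#' `pre_existing` stratum with `none`, with a large-sample Wald confidence
#' interval on the log-odds-ratio scale. The OR is `NA` (flagged
#' `or_defined = FALSE`) when any cell of the 2x2 table is empty.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param level Confidence level for the OR interval (default 0.95).
#' @return One-row tibble: `n`, stratum prevalences (`p_none`,
#'   `p_pre_existing`, `p_incident`), `misuse_overall`, per-stratum misuse
#'   prevalences (`misuse_none`, `misuse_pre_existing`, `misuse_incident`),
#'   `or_hat`, `or_lo`, `or_hi`, `or_defined`.
#' @export
summarize_cohort <- function(cohort, level = 0.95) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0L,
            all(c("anxiety_stratum", "misuse") %in% names(cohort)))
  n <- nrow(cohort)
  strata <- factor(cohort$anxiety_stratum,
                   levels = c("none", "pre_existing", "incident"))
  n_str <- table(strata)
  mis_str <- tapply(cohort$misuse, strata, sum, default = 0L)
  prev_str <- ifelse(n_str > 0, mis_str / n_str, NA_real_)

  or <- empirical_or(misuse_exposed = mis_str[["pre_existing"]],
                     n_exposed = n_str[["pre_existing"]],
                     misuse_ref = mis_str[["none"]],
                     n_ref = n_str[["none"]],
                     level = level)

  tibble::tibble(
    n = n,
    p_none = as.numeric(n_str[["none"]]) / n,
    p_pre_existing = as.numeric(n_str[["pre_existing"]]) / n,
    p_incident = as.numeric(n_str[["incident"]]) / n,
    misuse_overall = sum(cohort$misuse) / n,
    misuse_none = prev_str[["none"]],
    misuse_pre_existing = prev_str[["pre_existing"]],
    misuse_incident = prev_str[["incident"]],
    or_hat = or$or, or_lo = or$lo, or_hi = or$hi,
    or_defined = or$defined
  )
}

# 2x2 cross-product OR with Wald log-scale CI; flags undefined cells.
empirical_or <- function(misuse_exposed, n_exposed, misuse_ref, n_ref,
                         level = 0.95) {
  a <- misuse_exposed
  b <- n_exposed - misuse_exposed
  c_ <- misuse_ref
  d <- n_ref - misuse_ref
  if (min(a, b, c_, d) == 0) {
    return(list(or = NA_real_, lo = NA_real_, hi = NA_real_,
                defined = FALSE))
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       defined = TRUE)
}

#' Parameter-recovery experiment
#'
#' Simulates repeated cohorts at fixed true `(p0, a1, or_)`, re-estimates the
#' misuse odds ratio and the overall prevalence from each cohort, and reports
#' bias and confidence-interval coverage. With a correctly specified
#' generator the empirical OR is nearly unbiased and the nominal 95% Wald
#' interval covers the true OR in about 95% of cohorts.
#'
#' @param params A [model_parameters()] object with `p0` set.
#' @param n_cohorts Number of replicate cohorts (>= 1).
#' @param n_per_cohort Persons per cohort.
#' @param seed Integer seed; each cohort gets a deterministic subseed.
#' @param scenario Scenario generating the cohorts (default `"s1"`).
#' @param a1,or_ True parameter values; default to the Beta mean and the
#'   lognormal natural-scale mean.
#' @return List with `cohorts` (per-cohort tibble: `cohort`, `or_hat`,
#'   `or_lo`, `or_hi`, `covered`, `misuse_overall`) and `summary` (one-row
#'   tibble: `true_or`, `mean_or`, `rel_bias_or`, `coverage`,
#'   `true_prevalence`, `mean_prevalence`, `n_cohorts`, `n_per_cohort`).
#' @examples
#' p <- model_parameters(p0 = 0.04746)
#' recovery_experiment(p, n_cohorts = 20, n_per_cohort = 2000, seed = 1)$summary
#' @export
recovery_experiment <- function(params, n_cohorts, n_per_cohort, seed,
                                scenario = "s1", a1 = NULL, or_ = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  check_n_draws(n_cohorts)
  check_n_draws(n_per_cohort)
  a1 <- a1 %||% max(params$a1_spec$mean, params$a0)
  or_ <- or_ %||% params$or_spec$mean

  per <- purrr::map_dfr(seq_len(n_cohorts), function(i) {
    cohort <- simulate_cohort(scenario, params, a1 = a1, or_ = or_,
                              n = n_per_cohort,
                              seed = substream_seed(seed, 100L + i))
    s <- summarize_cohort(cohort)
    tibble::tibble(
      cohort = i, or_hat = s$or_hat, or_lo = s$or_lo, or_hi = s$or_hi,
      covered = !is.na(s$or_lo) && or_ >= s$or_lo && or_ <= s$or_hi,
      misuse_overall = s$misuse_overall
    )
  })
  ok <- !is.na(per$or_hat)
  true_prev <- scenario_prevalence(scenario, params, a1, or_)
  summary <- tibble::tibble(
    true_or = or_,
    mean_or = mean(per$or_hat[ok]),
    rel_bias_or = mean(per$or_hat[ok]) / or_ - 1,
    coverage = mean(per$covered[ok]),
    true_prevalence = true_prev,
    mean_prevalence = mean(per$misuse_overall),
    n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
    n_estimable = sum(ok)
  )
  list(cohorts = per, summary = summary)
}
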