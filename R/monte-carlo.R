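#' Run the Monte Carlo simulation
#'
#' Propagates parameter uncertainty through the scenario prevalence formulas.
#' Each iteration draws one post-wildfire anxiety prevalence from the Beta
#' specification and one misuse odds ratio from the lognormal specification
#' (independent substreams derived deterministically from the run seed), then
#' evaluates all four scenario prevalences and their prevalence ratios on the
#' same pair of draws.
#'
#' If `params$p0` is `NULL` the free parameter is first calibrated with
#' [calibrate_p0()] against `params$pi_target` at the odds-ratio point
#' estimate (`params$or_spec$mean`).
#'
#' @param params A [model_parameters()] object.
#' @return An object of class `misuse_sim`: list with
#'   * `draws` — tibble, one row per iteration, columns `draw`, `a1_draw`,
#'     `a1_eff`, `or_draw`, `prev_baseline`, `prev_s1`, `prev_s2`, `prev_s3`,
#'     `pr_s1`, `pr_s2`, `pr_s3`, `anxiety_pr`;
#'   * `params` — the input parameters with the calibrated `p0` filled in;
#'   * `calibration` — the `calibration_result`, or `NULL` when `p0` was
#'     supplied.
#' @examples
#' sim <- run_simulation(model_parameters(n_iter = 500, seed = 7))
#' tidy(sim)
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  calib <- NULL
  if (is.null(params$p0)) {
    calib <- calibrate_p0(params$pi_target, params$a0,
                          or_point = params$or_spec$mean)
    params$p0 <- calib$p0
  }
  n <- params$n_iter
  a1_draw <- sample_beta(params$a1_spec, n,
                         seed = substream_seed(params$seed, 1L))
  or_draw <- sample_lognormal(params$or_spec, n,
                              seed = substream_seed(params$seed, 2L))
  a1_eff <- if (params$floor_a1) pmax(a1_draw, params$a0) else a1_draw

  prev <- lapply(stats::setNames(nm = scenario_ids()), function(sc) {
    scenario_prevalence(sc, params, a1_draw, or_draw)
  })
  pr_ref <- if (params$pr_reference == "fixed") {
    params$pi_target
  } else {
    prev$baseline
  }

  draws <- tibble::tibble(
    draw = seq_len(n),
    a1_draw = a1_draw,
    a1_eff = a1_eff,
    or_draw = or_draw,
    prev_baseline = prev$baseline,
    prev_s1 = prev$s1,
    prev_s2 = prev$s2,
    prev_s3 = prev$s3,
    pr_s1 = prevalence_ratio(prev$s1, pr_ref),
    pr_s2 = prevalence_ratio(prev$s2, pr_ref),
    pr_s3 = prevalence_ratio(prev$s3, pr_ref),
    anxiety_pr = a1_eff / params$a0
  )
  structure(list(draws = draws, params = params, calibration = calib),
            class = "misuse_sim")
}

#' Summarize Monte Carlo draws
#'
#' Mean and central percentile uncertainty interval for each output metric.
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param draws A draws tibble (from `run_simulation()$draws`) or any data
#'   frame of numeric metric columns; a `draw` index column is ignored.
#' @param level Interval coverage in (0, 1); default 0.95 gives the
#'   2.5th–97.5th percentile band.
#' @return A tibble with columns `metric`, `mean`, `lo`, `hi`.
#' @examples
#' sim <- run_simulation(model_parameters(n_iter = 500, seed = 7))
#' summarize_draws(sim$draws)
#' @export
summarize_draws <- function(draws, level = 0.95) {
  draws <- as.data.frame(draws)
  if (nrow(draws) == 0L) stop("`draws` is empty", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must lie in (0, 1)", call. = FALSE)
  }
  metrics <- setdiff(names(draws)[vapply(draws, is.numeric, logical(1))],
                     "draw")
  alpha <- (1 - level) / 2
  purrr::map_dfr(metrics, function(m) {
    x <- draws[[m]]
    qs <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
    tibble::tibble(metric = m, mean = mean(x), lo = qs[1], hi = qs[2])
  })
}

#' @export
print.misuse_sim <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Wildfire-opioid Monte Carlo simulation: %d iterations, seed %d\n",
    x$params$n_iter, x$params$seed))
  cat(sprintf("  p0 = %.6f (%s)\n", x$params$p0,
              if (is.null(x$calibration)) "supplied"
              else sprintf("calibrated to %.3f", x$calibration$pi_target)))
  print(tidy(x), n = Inf, digits = digits)
  invisible(x)
}

#' Tidy a simulation into its summary table
#'
#' @param x A `misuse_sim` object.
#' @param level Interval coverage; see [summarize_draws()].
#' @param ... Unused.
#' @return Tibble with one row per output metric: `metric`, `mean`, `lo`,
#'   `hi` (the machine twin of the published results table, at full
#'   precision).
#' @exportS3Method generics::tidy
tidy.misuse_sim <- function(x, level = 0.95, ...) {
  summarize_draws(x$draws, level = level)
}

#' One-row overview of a simulation run
#'
#' @param x A `misuse_sim` object.
#' @param ... Unused.
#' @return One-row tibble: `n_iter`, `seed`, `p0`, `pi_target`,
#'   `pr_reference`, `floor_a1`, and the mean prevalence of each scenario.
#' @exportS3Method generics::glance
glance.misuse_sim <- function(x, ...) {
  d <- x$draws
  tibble::tibble(
    n_iter = x$params$n_iter, seed = x$params$seed,
    p0 = x$params$p0, pi_target = x$params$pi_target,
    pr_reference = x$params$pr_reference, floor_a1 = x$params$floor_a1,
    mean_baseline = mean(d$prev_baseline), mean_s1 = mean(d$prev_s1),
    mean_s2 = mean(d$prev_s2), mean_s3 = mean(d$prev_s3)
  )
}

#' Risk-ratio sensitivity sweep
#'
#' Re-runs the simulation over a grid of hypothetical risk ratios, reusing
#' the same seed so only the risk ratio varies between grid points, and
#' reports the mean Scenario 2 and Scenario 3 prevalences at each value.
#' Below the saturation cap both responses are exactly affine in the risk
#' ratio, with slopes `mean(a1_eff - a0) * p0` (S2) and `mean(a1_eff) * p0`
#' (S3) — S3 rises more steeply.
#'
#' @param params A [model_parameters()] object.
#' @param rr_grid Vector of risk ratios, all >= 1.
#' @return Tibble with columns `rr`, `mean_s2`, `mean_s3`.
#' @examples
#' sweep_risk_ratio(model_parameters(n_iter = 200, seed = 3), c(1, 3, 5))
#' @export
sweep_risk_ratio <- function(params, rr_grid) {
  stopifnot(inherits(params, "model_parameters"))
  if (!is.numeric(rr_grid) || length(rr_grid) == 0L ||
      any(!is.finite(rr_grid)) || any(rr_grid < 1)) {
    stop("`rr_grid` values must all be >= 1", call. = FALSE)
  }
  purrr::map_dfr(rr_grid, function(rr) {
    p <- params
    p$rr_s2 <- rr
    p$rr_s3 <- rr
    d <- run_simulation(p)$draws
    tibble::tibble(rr = rr, mean_s2 = mean(d$prev_s2),
                   mean_s3 = mean(d$prev_s3))
  })
}

#' Export a normalized histogram of one output metric
#'
#' Histogram table suitable for re-plotting the probability density of a
#' simulated quantity (e.g. a scenario prevalence ratio). Densities are
#' normalized so that `sum(density * (hi - lo)) == 1`.
#'
#' @param draws Draws tibble or `misuse_sim` object.
#' @param metric Name of a numeric column, e.g. `"pr_s1"`.
#' @param bins Number of equal-width bins (default 50).
#' @return Tibble with columns `lo`, `hi`, `mid`, `density`, `count`.
#' @examples
#' sim <- run_simulation(model_parameters(n_iter = 500, seed = 7))
#' export_density(sim, "pr_s1", bins = 20)
#' @export
export_density <- function(draws, metric, bins = 50) {
  if (inherits(draws, "misuse_sim")) draws <- draws$draws
  if (!metric %in% names(draws)) {
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  }
  x <- draws[[metric]]
  stopifnot(is.numeric(x), length(x) > 0L, bins >= 1)
  if (diff(range(x)) == 0) {
    # degenerate: all mass in one bin of unit nominal width
    w <- if (x[1] == 0) 1 else max(abs(x[1]) * 1e-3, .Machine$double.eps)
    return(tibble::tibble(lo = x[1] - w / 2, hi = x[1] + w / 2,
                          mid = x[1], density = 1 / w,
                          count = length(x)))
  }
  breaks <- seq(min(x), max(x), length.out = bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  tibble::tibble(lo = utils::head(h$breaks, -1L),
                 hi = utils::tail(h$breaks, -1L),
                 mid = h$mids, density = h$density, count = h$counts)
}
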