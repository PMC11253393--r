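#' Model parameter set
#'
#' Bundles every scalar input of the wildfire–anxiety–opioid model. The
#' defaults are the study conditions: baseline past-year anxiety prevalence
#' 6.6% and opioid-misuse prevalence 5.3% among U.S. young adults (ages
#' 18–25), post-wildfire anxiety prevalence ~ Beta(10.5, 70), odds ratio for
#' misuse given fire-related anxiety ~ lognormal with mean 3.04 / SD 1.07,
#' hypothetical risk ratios of 5 in Scenarios 2 and 3, and 50,000 Monte Carlo
#' iterations.
#'
#' @param a0 Baseline (pre-wildfire) past-year anxiety prevalence, in (0, 1).
#' @param pi_target Baseline opioid-misuse prevalence; the calibration target
#'   and the fixed prevalence-ratio reference, in (0, 1).
#' @param p0 Opioid-misuse probability absent anxiety — the calibrated free
#'   parameter. Leave `NULL` to have [run_simulation()] calibrate it via
#'   [calibrate_p0()].
#' @param a1_spec [beta_spec()] for post-wildfire anxiety prevalence.
#' @param or_spec [lognormal_spec()] for the misuse odds ratio given anxiety.
#' @param rr_s2 Risk ratio applied to wildfire-incident anxiety in Scenario 2
#'   (>= 1).
#' @param rr_s3 Risk ratio applied to all anxiety in Scenario 3 (>= 1).
#' @param n_iter Monte Carlo iterations (>= 1).
#' @param seed Integer run seed; per-parameter substreams are derived from it.
#' @param floor_a1 Floor each sampled post-wildfire anxiety prevalence at
#'   `a0`? Default `TRUE`: exposure is not allowed to lower anxiety
#'   prevalence.
#' @param pr_reference Denominator for prevalence ratios: `"fixed"` (the
#'   `pi_target` calibration target; default) or `"per-draw"` (the same
#'   draw's baseline prevalence, which shares the sampled odds ratio).
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' model_parameters(n_iter = 1000, seed = 42)
#' @export
model_parameters <- function(a0 = 0.066,
                             pi_target = 0.053,
                             p0 = NULL,
                             a1_spec = beta_spec(10.5, 70),
                             or_spec = lognormal_spec(3.04, 1.07),
                             rr_s2 = 5,
                             rr_s3 = 5,
                             n_iter = 50000L,
                             seed = 1L,
                             floor_a1 = TRUE,
                             pr_reference = c("fixed", "per-draw")) {
  pr_reference <- match.arg(pr_reference)
  check_probability(a0, "a0")
  check_probability(pi_target, "pi_target")
  if (!is.null(p0)) check_probability(p0, "p0")
  stopifnot(inherits(a1_spec, "beta_spec"), inherits(or_spec, "lognormal_spec"))
  if (a1_spec$mean <= 0 || a1_spec$mean >= 1) {
    stop("`a1_spec` mean must lie in (0, 1)", call. = FALSE)
  }
  for (nm in c("rr_s2", "rr_s3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1) {
      stop(sprintf("`%s` must be a single finite value >= 1", nm),
           call. = FALSE)
    }
  }
  check_n_draws(n_iter)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.logical(floor_a1), length(floor_a1) == 1L, !is.na(floor_a1))
  structure(
    list(a0 = a0, pi_target = pi_target, p0 = p0,
         a1_spec = a1_spec, or_spec = or_spec,
         rr_s2 = rr_s2, rr_s3 = rr_s3,
         n_iter = as.integer(n_iter), seed = as.integer(seed),
         floor_a1 = floor_a1, pr_reference = pr_reference),
    class = "model_parameters"
  )
}

check_probability <- function(p, name, open = TRUE) {
  ok <- is.numeric(p) && length(p) == 1L && is.finite(p) &&
    if (open) (p > 0 && p < 1) else (p >= 0 && p <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a probability in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Wildfire-opioid model parameters\n")
  cat(sprintf("  baseline anxiety a0          : %.3f\n", x$a0))
  cat(sprintf("  misuse target pi*            : %.3f\n", x$pi_target))
  cat(sprintf("  p0 (misuse, no anxiety)      : %s\n",
              if (is.null(x$p0)) "<uncalibrated>" else sprintf("%.6f", x$p0)))
  cat(sprintf("  a1 ~ Beta(%g, %g)  OR ~ lognormal(mean %g, sd %g, %s)\n",
              x$a1_spec$alpha, x$a1_spec$beta, x$or_spec$mean, x$or_spec$sd,
              x$or_spec$parameterization))
  cat(sprintf("  rr_s2 %g, rr_s3 %g, n_iter %d, seed %d\n",
              x$rr_s2, x$rr_s3, x$n_iter, x$seed))
  cat(sprintf("  floor a1 at a0: %s; PR reference: %s\n",
              x$floor_a1, x$pr_reference))
  invisible(x)
}

#' Read or write a run configuration file
#'
#' The run configuration is a YAML file whose keys mirror
#' [model_parameters()]; distribution specs appear as
#' `{family: beta|lognormal, ...}` blocks and are echoed verbatim into result
#' metadata for provenance.
#'
#' @param path File path.
#' @param params A `model_parameters` object (for writing).
#' @return `read_model_config()` returns a `model_parameters` object;
#'   `write_model_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_model_config(model_parameters(n_iter = 10), f)
#' read_model_config(f)
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec_from <- function(x, what) {
    fam <- tolower(x$family %||% "")
    if (fam == "beta") {
      beta_spec(x$alpha, x$beta)
    } else if (fam == "lognormal") {
      lognormal_spec(x$mean, x$sd,
                     x$parameterization %||% "natural_moments")
    } else {
      stop(sprintf("unknown distribution family for `%s`: '%s'", what, fam),
           call. = FALSE)
    }
  }
  model_parameters(
    a0 = cfg$a0 %||% 0.066,
    pi_target = cfg$pi_target %||% 0.053,
    p0 = cfg$p0,
    a1_spec = if (is.null(cfg$a1)) beta_spec() else spec_from(cfg$a1, "a1"),
    or_spec = if (is.null(cfg$or)) lognormal_spec() else spec_from(cfg$or, "or"),
    rr_s2 = cfg$rr_s2 %||% 5,
    rr_s3 = cfg$rr_s3 %||% 5,
    n_iter = cfg$n_iter %||% 50000L,
    seed = cfg$seed %||% 1L,
    floor_a1 = cfg$floor_a1 %||% TRUE,
    pr_reference = cfg$pr_reference %||% "fixed"
  )
}

#' @rdname read_model_config
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  cfg <- list(
    a0 = params$a0, pi_target = params$pi_target, p0 = params$p0,
    a1 = list(family = "beta", alpha = params$a1_spec$alpha,
              beta = params$a1_spec$beta),
    or = list(family = "lognormal", mean = params$or_spec$mean,
              sd = params$or_spec$sd,
              parameterization = params$or_spec$parameterization),
    rr_s2 = params$rr_s2, rr_s3 = params$rr_s3,
    n_iter = params$n_iter, seed = params$seed,
    floor_a1 = params$floor_a1, pr_reference = params$pr_reference
  )
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}
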