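#' Plot the prevalence-ratio densities of a simulation
#'
#' Kernel density of the opioid-misuse prevalence ratio under each
#' post-wildfire scenario, with a reference line at PR = 1 (the baseline
#' prevalence). The analogue of the published density figure.
#'
#' @param object A `misuse_sim` object.
#' @param metrics Columns to plot (default the three scenario PRs).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sim <- run_simulation(model_parameters(n_iter = 2000, seed = 7))
#' autoplot(sim)
#' @exportS3Method ggplot2::autoplot
autoplot.misuse_sim <- function(object,
                                metrics = c("pr_s1", "pr_s2", "pr_s3"),
                                ...) {
  stopifnot(all(metrics %in% names(object$draws)))
  long <- tidyr::pivot_longer(object$draws[, metrics, drop = FALSE],
                              dplyr::all_of(metrics),
                              names_to = "scenario", values_to = "value")
  labels <- c(pr_s1 = "Scenario 1", pr_s2 = "Scenario 2",
              pr_s3 = "Scenario 3")
  long$scenario <- dplyr::recode(long$scenario, !!!labels[metrics])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = .data$scenario,
                                     fill = .data$scenario)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "Prevalence ratio for opioid misuse post-wildfire",
                  y = "Density", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a risk-ratio sensitivity sweep
#'
#' Mean Scenario 2 and 3 misuse prevalence against the hypothetical risk
#' ratio; both responses are affine below the saturation cap, with Scenario 3
#' the steeper.
#'
#' @param sweep Tibble from [sweep_risk_ratio()].
#' @return A ggplot object.
#' @examples
#' sw <- sweep_risk_ratio(model_parameters(n_iter = 500, seed = 3), 1:5)
#' plot_rr_sweep(sw)
#' @export
plot_rr_sweep <- function(sweep) {
  stopifnot(all(c("rr", "mean_s2", "mean_s3") %in% names(sweep)))
  long <- tidyr::pivot_longer(sweep, c("mean_s2", "mean_s3"),
                              names_to = "scenario", values_to = "prevalence")
  long$scenario <- dplyr::recode(long$scenario, mean_s2 = "Scenario 2",
                                 mean_s3 = "Scenario 3")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rr, y = .data$prevalence,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hypothetical risk ratio",
                  y = "Mean opioid-misuse prevalence", colour = NULL) +
    ggplot2::theme_minimal()
}
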