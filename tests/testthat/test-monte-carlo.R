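test_that("runs are reproducible and structurally complete", {
  p <- model_parameters(n_iter = 2000, seed = 31)
  s1 <- run_simulation(p)
  s2 <- run_simulation(p)
  expect_identical(s1$draws, s2$draws)
  expect_identical(tidy(s1), tidy(s2))
  expect_equal(nrow(s1$draws), 2000)
  expect_true(all(c("draw", "a1_draw", "a1_eff", "or_draw", "prev_baseline",
                    "prev_s1", "prev_s2", "prev_s3", "pr_s1", "pr_s2",
                    "pr_s3", "anxiety_pr") %in% names(s1$draws)))
  # calibration happened and is echoed
  expect_equal(s1$params$p0, uniroot_p0(), tolerance = 1e-8)
  expect_s3_class(s1$calibration, "calibration_result")
  # different seed, different draws
  expect_false(identical(
    run_simulation(model_parameters(n_iter = 100, seed = 1))$draws$or_draw,
    run_simulation(model_parameters(n_iter = 100, seed = 2))$draws$or_draw))
  expect_error(model_parameters(n_iter = 0), "integer")
})

test_that("per-draw invariants hold across the draw table", {
  sim <- run_simulation(model_parameters(n_iter = 5000, seed = 17))
  d <- sim$draws
  expect_true(all(d$a1_eff >= 0.066))
  expect_true(all(d$a1_eff == pmax(d$a1_draw, 0.066)))
  expect_true(all(d$or_draw > 0))
  for (col in c("prev_baseline", "prev_s1", "prev_s2", "prev_s3")) {
    expect_true(all(d[[col]] > 0 & d[[col]] < 1))
  }
  expect_equal(d$pr_s1, d$prev_s1 / 0.053, tolerance = 1e-14)
  expect_equal(d$anxiety_pr, d$a1_eff / 0.066, tolerance = 1e-14)
  # mean ordering under the study defaults
  m <- colMeans(d[, c("prev_baseline", "prev_s1", "prev_s2", "prev_s3")])
  expect_true(all(diff(m) > 0))
})

test_that("degenerate distributions reproduce the deterministic worked values", {
  p <- degenerate_params(n_iter = 1)
  d <- run_simulation(p)$draws
  expect_equal(d$prev_s2, 0.06523, tolerance = 1e-4)
  expect_equal(d$prev_s3, 0.07221, tolerance = 1e-4)
  expect_equal(d$prev_baseline, 0.053, tolerance = 1e-6)
})

test_that("the per-draw PR reference option divides by the draw's baseline", {
  sim <- run_simulation(model_parameters(n_iter = 500, seed = 3,
                                         pr_reference = "per-draw"))
  d <- sim$draws
  expect_equal(d$pr_s1, d$prev_s1 / d$prev_baseline, tolerance = 1e-14)
  # flooring + OR >= 1 on a draw implies PR >= 1 under this reference
  ok <- d$or_draw >= 1
  expect_true(all(d$pr_s1[ok] >= 1 - 1e-12))
})

test_that("summaries use order-statistic interpolation and validate input", {
  s <- summarize_draws(data.frame(x = 1:100))
  expect_equal(s$lo, 3.475, tolerance = 1e-12)
  expect_equal(s$hi, 97.525, tolerance = 1e-12)
  expect_equal(s$lo, percentile_oracle(1:100, 0.025), tolerance = 1e-12)
  expect_equal(s$hi, percentile_oracle(1:100, 0.975), tolerance = 1e-12)
  # oracle cross-check on irregular data
  set.seed(5)
  x <- rlnorm(497)
  s2 <- summarize_draws(data.frame(x = x), level = 0.9)
  expect_equal(s2$lo, percentile_oracle(x, 0.05), tolerance = 1e-12)
  expect_equal(s2$hi, percentile_oracle(x, 0.95), tolerance = 1e-12)
  expect_true(all(s2$lo <= s2$hi))
  # degenerate draws: mean = lo = hi
  sd0 <- summarize_draws(data.frame(x = rep(2.5, 10)))
  expect_equal(sd0$mean, 2.5)
  expect_equal(sd0$lo, 2.5)
  expect_equal(sd0$hi, 2.5)
  expect_error(summarize_draws(data.frame(x = numeric(0))), "empty")
  expect_error(summarize_draws(data.frame(x = 1:5), level = 1), "0, 1")
})

test_that("risk-ratio sweep is affine with the steeper Scenario 3 slope", {
  p <- model_parameters(n_iter = 2000, seed = 13)
  grid <- c(1, 2, 3, 4, 5)
  sw <- sweep_risk_ratio(p, grid)
  expect_equal(nrow(sw), 5)
  # residuals from the affine fit vanish below the cap
  for (col in c("mean_s2", "mean_s3")) {
    fit <- lm(sw[[col]] ~ sw$rr)
    expect_lt(max(abs(resid(fit))), 1e-12)
    expect_gt(coef(fit)[2], 0)
  }
  slope2 <- coef(lm(mean_s2 ~ rr, data = sw))[2]
  slope3 <- coef(lm(mean_s3 ~ rr, data = sw))[2]
  expect_gt(slope3, slope2)
  # slopes equal mean(a1_eff - a0) * p0 and mean(a1_eff) * p0
  sim <- run_simulation(p)
  p0 <- sim$params$p0
  expect_equal(unname(slope2), mean(sim$draws$a1_eff - 0.066) * p0,
               tolerance = 1e-10)
  expect_equal(unname(slope3), mean(sim$draws$a1_eff) * p0,
               tolerance = 1e-10)
  # rr = 1 collapses s3 to p0 exactly
  expect_equal(sw$mean_s3[1], p0, tolerance = 1e-12)
  expect_error(sweep_risk_ratio(p, c(0.5, 2)), ">= 1")
})

test_that("density export integrates to one and flags unknown metrics", {
  sim <- run_simulation(model_parameters(n_iter = 3000, seed = 19))
  h <- export_density(sim, "pr_s1", bins = 40)
  expect_equal(sum(h$density * (h$hi - h$lo)), 1, tolerance = 1e-9)
  expect_equal(sum(h$count), 3000)
  # mode of the S1 PR density sits near 1.1
  expect_equal(h$mid[which.max(h$density)], 1.1, tolerance = 0.1)
  hd <- export_density(data.frame(x = rep(3, 50)), "x")
  expect_equal(nrow(hd), 1)
  expect_equal(sum(hd$density * (hd$hi - hd$lo)), 1, tolerance = 1e-9)
  expect_error(export_density(sim, "nope"), "unknown metric")
})

test_that("glance and autoplot expose the run at a glance", {
  sim <- run_simulation(model_parameters(n_iter = 300, seed = 2))
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_iter, 300)
  expect_equal(g$mean_s1, mean(sim$draws$prev_s1))
  pl <- ggplot2::autoplot(sim)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(plot_rr_sweep(sweep_risk_ratio(
    model_parameters(n_iter = 100, seed = 4), c(1, 3, 5))), "ggplot")
})
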