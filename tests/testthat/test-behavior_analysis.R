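make_pair <- function(theta, n = 250, seed = 1, full_obs = TRUE,
                      cost = "low") {
  conds <- list(task_config("low", cost), task_config("high", cost))
  spec <- if (full_obs) full_obs_spec("s", theta, conds, n)
          else subject_spec("s", theta = theta, conditions = conds,
                            trials_per_condition = n)
  generate_subject(spec, seed = seed)
}

test_that("policy-plane fit reports sound uncertainty and R^2", {
  sj <- make_pair(0, n = 300, seed = 5, full_obs = FALSE)
  fit <- fit_policy_plane(sj[[1]])
  expect_s3_class(fit, "gain_estimate")
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_equal(fit$n_trials, 300)
  expect_equal(dim(fit$vcov), c(2, 2))
  expect_equal(sqrt(diag(fit$vcov)),
               c(fit$position_se, fit$velocity_se), ignore_attr = TRUE)
  # cross-check against lm with no intercept
  dt <- sj[[1]]$config$dt_s
  x <- sj[[1]]$x_cm[76, ]; v <- sj[[1]]$v_cm_s[76, ]; u <- sj[[1]]$u_N[91, ]
  ref <- stats::lm(u ~ 0 + x + v)
  expect_equal(unname(coef(ref)),
               c(fit$position_gain, fit$velocity_gain), tolerance = 1e-10)
  expect_equal(summary(ref)$r.squared, fit$r_squared, tolerance = 1e-10)
  expect_error(fit_policy_plane(sj[[1]], probe_time_s = 0.9, lag_s = 0.2),
               "horizon")
})

test_that("results are invariant to trial order", {
  sj <- make_pair(0.01, n = 120, seed = 9, full_obs = FALSE)
  perm <- sample(120)
  shuffled <- subset_trials(sj[[1]], perm)
  f1 <- fit_policy_plane(sj[[1]])
  f2 <- fit_policy_plane(shuffled)
  expect_equal(f1$position_gain, f2$position_gain)
  expect_equal(f1$r_squared, f2$r_squared)
  ft_orig <- compare_policies_ftest(sj[[1]], sj[[2]])
  ft_perm <- compare_policies_ftest(shuffled, sj[[2]])
  expect_equal(ft_orig$statistic, ft_perm$statistic)
})

test_that("F-test degenerates correctly on identical data", {
  sj <- make_pair(0, n = 100, seed = 3)
  ft <- compare_policies_ftest(sj[[1]], sj[[1]])
  expect_lt(ft$statistic, 1e-8)
  expect_gt(ft$p.value, 0.999)
})

# Complete-observation subject with fixed execution noise, fitted at its
# delay-matched lag (0): the fitted slopes equal the analytic law gains, the
# regression residual is the iid execution noise (the same in both noise
# conditions, so the joint fit is homoscedastic), and at theta = 0 the
# shared-slope null is exactly true by the noise invariance of the law.
make_exec_pair <- function(theta, n, seed, motor = 0.05) {
  conds <- list(task_config("low", "low"), task_config("high", "low"))
  spec <- subject_spec("s", theta = theta, delay_steps = 0,
                       pos_noise_sd_cm = 0, vel_noise_sd_cm_s = 0,
                       motor_noise_sd = motor, conditions = conds,
                       trials_per_condition = n)
  generate_subject(spec, seed = seed)
}

test_that("F-test has nominal type-I error on risk-neutral conditions", {
  n_rep <- 150
  rejections <- 0
  for (r in seq_len(n_rep)) {
    sj <- make_exec_pair(0, n = 80, seed = 1000 + r)
    ft <- compare_policies_ftest(sj[[1]], sj[[2]], shared = "position",
                                 probe_time_s = 0.75, lag_s = 0)
    rejections <- rejections + (ft$p.value < 0.05)
  }
  rate <- rejections / n_rep
  # binomial 99% band around 0.05 at 150 replicates
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("F-test detects a risk-averse policy change with high power", {
  n_rep <- 25
  hits <- 0
  for (r in seq_len(n_rep)) {
    sj <- make_exec_pair(0.1, n = 250, seed = 2000 + r)
    ft <- compare_policies_ftest(sj[[1]], sj[[2]], shared = "position",
                                 probe_time_s = 0.75, lag_s = 0)
    hits <- hits + (ft$p.value < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("cost fraction behaves as the risk attitude dictates", {
  cfg <- task_config("low", "low")
  ts0 <- simulate_trials(cfg, null_policy(cfg), 50, seed = 1)
  cf0 <- cost_fraction(ts0)
  expect_equal(cf0$fraction, 0)

  # theta = 0 with paired noise streams: fraction is exactly noise-invariant
  cfgH <- task_config("high", "low")
  tsL <- simulate_trials(cfg, optimal_policy(cfg, 0), 200, seed = 2,
                         stream_label = "cf")
  tsH <- simulate_trials(cfgH, optimal_policy(cfgH, 0), 200, seed = 2,
                         stream_label = "cf")
  expect_equal(cost_fraction(tsL)$fraction, cost_fraction(tsH)$fraction,
               tolerance = 1e-10)

  zero_total <- simulate_trials(task_config("low", "low",
                                            process_noise_sd = 0),
                                null_policy(task_config("low", "low",
                                                        process_noise_sd = 0)),
                                5, seed = 1)
  expect_error(cost_fraction(zero_total), "undefined")
})

test_that("risk sensitivity carries a non-negative, growing expected-cost premium", {
  cfg <- task_config("high", "low")
  obs <- observation_model()
  ec0 <- extra_cost_of_risk(0, cfg, obs, n_trials = 200, seed = 5)
  expect_identical(ec0$percent_extra, 0)
  ec1 <- extra_cost_of_risk(0.015, cfg, obs, n_trials = 800, seed = 5)
  ec2 <- extra_cost_of_risk(0.03, cfg, obs, n_trials = 800, seed = 5)
  expect_gt(ec1$percent_extra, 0)
  expect_gt(ec2$percent_extra, ec1$percent_extra)
})

test_that("impact-angle analysis counts orthogonal hits and counterfactuals", {
  cfg0 <- task_config("low", "low", process_noise_sd = 0)
  ts0 <- simulate_trials(cfg0, null_policy(cfg0), 10, seed = 1)
  ia0 <- impact_angle_analysis(ts0)
  expect_equal(ia0$n_orthogonal_actual[1], 10)
  expect_equal(ia0$n_orthogonal_counterfactual[1], 10)

  # counterfactual counts depend only on the noise stream, not the policy
  cfg <- task_config("high", "low")
  obs <- observation_model()
  ts_a <- simulate_trials(cfg, optimal_policy(cfg, 0, obs), 60, seed = 4,
                          stream_label = "cfp")
  ts_b <- simulate_trials(cfg, optimal_policy(cfg, 0.02, obs), 60, seed = 4,
                          stream_label = "cfp")
  ia_a <- impact_angle_analysis(ts_a)
  ia_b <- impact_angle_analysis(ts_b)
  expect_equal(ia_a$n_orthogonal_counterfactual,
               ia_b$n_orthogonal_counterfactual)
})

test_that("delay sweep is exact for an undelayed noiseless subject", {
  cfg <- task_config("low", "low")
  spec <- full_obs_spec("d0", theta = 0, list(cfg), n_trials = 60)
  sj <- generate_subject(spec, seed = 13)
  ds <- delay_sweep(sj[[1]], lags_s = 0)
  expect_equal(ds$best_lag_s, 0)
  expect_gt(ds$profile$r_squared[1], 0.999999)
  expect_error(delay_sweep(sj[[1]], lags_s = numeric(0)), "non-empty")
})

test_that("theta inference recovers the null and reports uncertainty", {
  conds <- list(task_config("low", "low"), task_config("high", "low"))
  obs <- observation_model()
  pred <- theta_prediction_grid(conds[[1]], conds[[2]], obs,
                                n_grid = 10, n_trials = 1500, seed = 7)
  expect_s3_class(pred, "theta_predictions")
  expect_equal(nrow(pred), 21)
  spec <- subject_spec("null", theta = 0, conditions = conds)
  sj <- generate_subject(spec, seed = 23)
  rf <- infer_theta(sj[[1]], sj[[2]], pred, n_boot = 200, seed = 1)
  expect_s3_class(rf, "risk_fit")
  expect_true(rf$theta_ci[1] <= 0 && rf$theta_ci[2] >= 0)
  expect_gt(rf$theta_sd, 0)
})

test_that("pooled inference across cost levels agrees on a shared grid", {
  cfgs <- default_conditions()
  obs <- observation_model()
  grid <- default_theta_grid(cfgs, obs, n_grid = 8)
  expect_length(grid, 17)
  predL <- theta_prediction_grid(cfgs$low_noise_low_cost,
                                 cfgs$high_noise_low_cost, obs,
                                 theta_grid = grid, n_trials = 800, seed = 2)
  predH <- theta_prediction_grid(cfgs$low_noise_high_cost,
                                 cfgs$high_noise_high_cost, obs,
                                 theta_grid = grid, n_trials = 800, seed = 3)
  spec <- subject_spec("p", theta = 0.012, trials_per_condition = 250)
  sj <- generate_subject(spec, seed = 29)
  rf <- infer_theta_pooled(
    list(list(sj$low_noise_low_cost, sj$high_noise_low_cost),
         list(sj$low_noise_high_cost, sj$high_noise_high_cost)),
    list(predL, predH), n_boot = 50, seed = 1)
  expect_s3_class(rf, "risk_fit")
  expect_true(rf$theta_hat %in% grid)
})
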