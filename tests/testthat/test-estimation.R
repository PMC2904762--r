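test_that("delay augmentation has the right dimensions and identity case", {
  cfg <- task_config("low", "low")
  dyn <- discretize_dynamics(cfg)
  cost <- build_cost(cfg)
  obs <- observation_model(delay_steps = 15)
  aug <- augment_for_delay(dyn, cost, obs)
  expect_equal(nrow(aug$dyn$A), 32)
  expect_equal(dim(aug$obs$H), c(2, 32))
  expect_equal(aug$obs$delay_steps, 0L)
  # cost and noise act on the current block only
  expect_equal(aug$cost$Q_final[1:2, 1:2], cost$Q_final)
  expect_equal(sum(abs(aug$cost$Q_final)) , sum(abs(cost$Q_final)))
  expect_equal(aug$dyn$Omega[1:2, 1:2], dyn$Omega)
  expect_equal(sum(abs(aug$dyn$Omega)), sum(abs(dyn$Omega)))

  obs0 <- observation_model(delay_steps = 0)
  same <- augment_for_delay(dyn, cost, obs0)
  expect_identical(same$dyn, dyn)
  expect_identical(same$cost, cost)
})

test_that("noise-free augmented dynamics reproduce the plain trajectory", {
  cfg <- task_config("low", "low", process_noise_sd = 0)
  dyn <- discretize_dynamics(cfg)
  aug <- augment_for_delay(dyn, build_cost(cfg), observation_model(5))
  u_seq <- sin(seq_len(20))
  x <- c(0, 0); xa <- rep(0, 12)
  hist <- matrix(0, 2, 21)  # plain trajectory, column t+1 = state after t steps
  for (t in 1:20) {
    x <- drop(dyn$A %*% x + dyn$B %*% u_seq[t])
    xa <- drop(aug$dyn$A %*% xa + aug$dyn$B %*% u_seq[t])
    hist[, t + 1] <- x
  }
  expect_equal(xa[1:2], x, tolerance = 1e-14)
  # the oldest block holds the state from `delay` steps ago
  expect_equal(xa[11:12], hist[, 21 - 5], tolerance = 1e-14)
})

test_that("Kalman filter equals brute-force joint-Gaussian conditioning", {
  a <- 0.9; b <- 1; h <- 1.2; q <- 0.3; r <- 0.5; x0 <- 1
  dyn <- linear_dynamics(matrix(a), matrix(b), matrix(q))
  obs <- observation_model(delay_steps = 0, H = matrix(h),
                           Sigma_omega = matrix(r))
  u_seq <- c(0.5, -0.2, 0.1, 0.4, -0.3)
  set.seed(42)
  x <- x0; y_seq <- numeric(5)
  for (t in 1:5) {
    x <- a * x + b * u_seq[t] + rnorm(1, 0, sqrt(q))
    y_seq[t] <- h * x + rnorm(1, 0, sqrt(r))
  }
  oracle <- kalman_conditioning_oracle(a, b, h, q, r, x0, u_seq, y_seq)
  fs <- filter_state(matrix(x0), matrix(0))
  for (t in 1:5) {
    fs <- kalman_step(fs, y_seq[t], u_seq[t], dyn, obs)
    expect_lt(abs(drop(fs$x_hat) - oracle$mean[t]), 1e-8)
    expect_lt(abs(drop(fs$P) - oracle$var[t]), 1e-8)
  }
})

test_that("near-perfect observation pins the posterior to H^{-1} y", {
  dyn <- linear_dynamics(diag(2), matrix(c(0, 1), 2), diag(0.2, 2))
  H <- matrix(c(2, 0, 0, 0.5), 2, 2)
  obs <- observation_model(0, H = H, Sigma_omega = diag(1e-14, 2))
  fs <- filter_state(c(0, 0), diag(1, 2))
  y <- c(1.4, -0.3)
  fs <- kalman_step(fs, y, u = 0.2, dyn, obs)
  expect_equal(drop(fs$x_hat), drop(solve(H, y)), tolerance = 1e-5)
})

test_that("estimate covariance grows with the process noise level", {
  cfg1 <- task_config("low", "low")
  cfg2 <- task_config("low", "low",
                      process_noise_sd = sqrt(2) * cfg1$process_noise_sd)
  obs <- observation_model(delay_steps = 0)
  kf1 <- kalman_gains(discretize_dynamics(cfg1), obs, 100)
  kf2 <- kalman_gains(discretize_dynamics(cfg2), obs, 100)
  P1 <- kf1$P_filt[[101]]; P2 <- kf2$P_filt[[101]]
  expect_true(all(diag(P2) > diag(P1)))
})

test_that("risk adjustment is identity at theta = 0 and errors at breakdown", {
  P <- diag(c(0.5, 0.2)); S <- diag(c(2, 1)); x <- c(1, -1)
  expect_identical(risk_adjusted_estimate(x, P, S, 0), x)
  adj <- risk_adjusted_estimate(matrix(x), P, S, 0.1)
  expect_equal(drop(adj), drop(solve(diag(2) - 0.2 * P %*% S, x)))
  expect_error(risk_adjusted_estimate(matrix(x), P, S, 2), "breakdown")
})

test_that("coupled risk-sensitive estimator beats naive certainty equivalence", {
  # 2-step scalar partially observed system; Monte-Carlo criterion oracle
  a <- 1; b <- 1; q <- 0.4; r <- 0.5; th <- 0.25; x0 <- 1; P0 <- 0.5
  dyn <- linear_dynamics(matrix(a), matrix(b), matrix(q))
  obs <- observation_model(0, H = matrix(1), Sigma_omega = matrix(r))
  law <- riccati_risk_sensitive(dyn, cost_spec(matrix(0.2), matrix(2),
                                               matrix(1)), 2, th)
  simulate_policy <- function(coupled, nmc = 2e5, seed = 11) {
    set.seed(seed)
    x <- rnorm(nmc, x0, sqrt(P0))
    xh <- rep(x0, nmc); P <- P0
    total <- numeric(nmc)
    for (t in 1:2) {
      y <- x + rnorm(nmc, 0, sqrt(r))
      K <- P / (P + r)
      xh <- xh + K * (y - xh)
      P <- (1 - K) * P
      S <- law$cost_to_go[[t]][1]
      xc <- if (coupled) drop(risk_adjusted_estimate(rbind(xh), matrix(P),
                                                     matrix(S), th)) else xh
      u <- -drop(law$gains[[t]]) * xc
      total <- total + 0.2 * x^2 + u^2
      x <- a * x + b * u + rnorm(nmc, 0, sqrt(q))
      xh <- a * xh + b * u
      P <- a^2 * P + q
    }
    total <- total + 2 * x^2
    m <- max(th * total)
    (m + log(mean(exp(th * total - m)))) / th
  }
  expect_lt(simulate_policy(TRUE), simulate_policy(FALSE))
})

test_that("vanishing sensory noise and delay reproduce full observation", {
  # compare single trials: the process-noise draws come first in each
  # stream, so they coincide across the two policy types for trial 1
  cfg <- task_config("high", "low")
  th <- 0.01
  obs <- observation_model(delay_steps = 0, pos_noise_sd_cm = 1e-5,
                           vel_noise_sd_cm_s = 1e-4)
  pol_f <- optimal_policy(cfg, th)
  pol_p <- optimal_policy(cfg, th, obs)
  for (s in 9:12) {
    full <- run_trial(cfg, pol_f, seed = s)
    part <- run_trial(cfg, pol_p, seed = s)
    expect_identical(full$xi_N, part$xi_N)
    expect_lt(max(abs(full$x_cm - part$x_cm)), 1e-3)
    expect_lt(max(abs(full$u_N - part$u_N)), 1e-3)
  }
})
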