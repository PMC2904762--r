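# Independent oracles used across the test files. These deliberately avoid
# the package's Riccati / filter code paths: the criterion oracle integrates
# the Gaussian expectation in closed form, and the filter oracle conditions
# the joint trajectory distribution directly.

# Exact risk-sensitive criterion gamma_theta = (1/theta) log E[exp(theta C)]
# of a 2-step scalar system under linear feedback (L0, L1), starting from a
# fixed x0, with running state cost Q, terminal cost Qf and control cost R.
# Uses E[exp(beta'w + w'Aw)] = det(I - 2 Sigma A)^{-1/2}
#   * exp(beta' (I - 2 Sigma A)^{-1} Sigma beta / 2) for w ~ N(0, Sigma).
gamma_exact_2step <- function(L0, L1, theta, A, B, s2, Q, Qf, R, x0) {
  a0 <- A - B * L0
  a1 <- A - B * L1
  k1 <- Q + R * L1^2
  # C = c0 + 2 b'w + w'Mw with w = (w1, w2)
  c0 <- Q * x0^2 + R * L0^2 * x0^2 + k1 * (a0 * x0)^2 + Qf * (a1 * a0 * x0)^2
  b <- c(k1 * a0 * x0 + Qf * a1^2 * a0 * x0, Qf * a1 * a0 * x0)
  M <- matrix(c(k1 + Qf * a1^2, Qf * a1, Qf * a1, Qf), 2, 2)
  Sig <- diag(s2, 2)
  if (theta == 0) return(c0 + sum(diag(Sig %*% M)))
  G <- diag(2) - 2 * theta * Sig %*% M
  if (any(Re(eigen(G, only.values = TRUE)$values) <= 0)) return(Inf)
  beta <- 2 * theta * b
  (theta * c0 - 0.5 * log(det(G)) +
      0.5 * drop(t(beta) %*% solve(G, Sig %*% beta))) / theta
}

# Joint-Gaussian conditioning oracle for the Kalman filter on a scalar
# system x_{t+1} = a x_t + b u_t + w_t, y_t = h x_t + v_t, known x_0.
# Returns the exact posterior mean and variance of x_t given y_{1:t} for
# every t, by building the joint covariance of (x_1..x_T, y_1..y_T) as a
# linear map of the noise vector and conditioning.
kalman_conditioning_oracle <- function(a, b, h, q, r, x0, u_seq, y_seq) {
  steps <- length(u_seq)
  # x_t = mean_t + sum_{j<=t} a^(t-j) w_j ; stack coefficients
  mean_x <- numeric(steps)
  m <- x0
  for (t in seq_len(steps)) {
    m <- a * m + b * u_seq[t]
    mean_x[t] <- m
  }
  Cx <- matrix(0, steps, steps)  # coefficients of w_1..w_steps in x_t
  for (t in seq_len(steps)) for (j in seq_len(t)) Cx[t, j] <- a^(t - j)
  Sxx <- Cx %*% (q * diag(steps)) %*% t(Cx)
  Syy <- h^2 * Sxx + r * diag(steps)
  Sxy <- h * Sxx
  mean_y <- h * mean_x
  post_mean <- numeric(steps)
  post_var <- numeric(steps)
  for (t in seq_len(steps)) {
    S22 <- Syy[1:t, 1:t, drop = FALSE]
    s12 <- Sxy[t, 1:t, drop = FALSE]
    gain <- s12 %*% solve(S22)
    post_mean[t] <- mean_x[t] + gain %*% (y_seq[1:t] - mean_y[1:t])
    post_var[t] <- Sxx[t, t] - gain %*% t(s12)
  }
  list(mean = post_mean, var = post_var)
}

# Small helper: a complete-observation subject specification (the model the
# task's qualitative predictions are derived from).
full_obs_spec <- function(id, theta, conditions, n_trials = 250) {
  subject_spec(id, theta = theta, delay_steps = 0,
               pos_noise_sd_cm = 0, vel_noise_sd_cm_s = 0,
               conditions = conditions, trials_per_condition = n_trials)
}
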