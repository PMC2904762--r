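#' Observation model with sensory noise and sensorimotor delay
#'
#' The controller does not see the true state: it receives the ball's
#' position and velocity corrupted by sensory noise and delayed by a
#' visuomotor latency (default 15 steps of 10 ms = 150 ms, the approximate
#' time to respond to a visual perturbation). Interface units are cm and
#' cm/s; internally the covariance is converted to SI.
#'
#' @param delay_steps integer sensorimotor delay in time steps (>= 0).
#' @param pos_noise_sd_cm sd of position observation noise (cm).
#' @param vel_noise_sd_cm_s sd of velocity observation noise (cm/s).
#' @param H observation matrix on the (delayed) physical state; default
#'   identity (both components observed).
#' @param Sigma_omega optional full sensory-noise covariance in SI units;
#'   overrides the two sd arguments.
#' @return Object of class `observation_model`.
#' @export
observation_model <- function(delay_steps = 15,
                              pos_noise_sd_cm = 0.5,
                              vel_noise_sd_cm_s = 5,
                              H = NULL,
                              Sigma_omega = NULL) {
  delay_steps <- as.integer(delay_steps)
  if (delay_steps < 0) stop("delay_steps must be >= 0")
  H <- H %||% diag(2)
  Sigma_omega <- Sigma_omega %||%
    diag(c((pos_noise_sd_cm / 100)^2, (vel_noise_sd_cm_s / 100)^2),
         nrow(H))
  Sigma_omega <- as.matrix(Sigma_omega)
  if (!is_psd(Sigma_omega)) stop("Sigma_omega must be symmetric PSD")
  structure(list(H = as.matrix(H), Sigma_omega = symmetrize(Sigma_omega),
                 delay_steps = delay_steps),
            class = "observation_model")
}

#' Augment a system for sensorimotor delay
#'
#' Stacks the current physical state with its last `d` lags so that a
#' `d`-step-delayed observation becomes an undelayed observation of the
#' oldest block of the augmented state. Process noise and control enter only
#' the current block; costs act only on the current block; the observation
#' matrix reads the oldest block. With `delay_steps = 0` the inputs are
#' returned unchanged.
#'
#' @param dyn a [linear_dynamics()].
#' @param cost a [cost_spec()].
#' @param obs an [observation_model()].
#' @return List with augmented `dyn`, `cost` and `obs` (the returned `obs`
#'   has `delay_steps = 0` and an `H` matching the augmented state).
#' @export
augment_for_delay <- function(dyn, cost, obs) {
  d <- obs$delay_steps
  n <- nrow(dyn$A)
  if (d == 0) {
    H <- obs$H
    if (ncol(H) != n) stop("observation matrix does not match the state")
    return(list(dyn = dyn, cost = cost, obs = obs))
  }
  na <- n * (d + 1)
  A_aug <- matrix(0, na, na)
  A_aug[1:n, 1:n] <- dyn$A
  # shift register: block j+1 <- block j
  for (j in seq_len(d)) {
    rows <- j * n + 1:n
    cols <- (j - 1) * n + 1:n
    A_aug[rows, cols] <- diag(n)
  }
  B_aug <- rbind(dyn$B, matrix(0, na - n, ncol(dyn$B)))
  Omega_aug <- matrix(0, na, na)
  Omega_aug[1:n, 1:n] <- dyn$Omega
  dyn_aug <- linear_dynamics(A_aug, B_aug, Omega_aug, dt_s = dyn$dt_s,
                             force_noise_sd = dyn$force_noise_sd)

  pad <- function(Q) {
    Qa <- matrix(0, na, na)
    Qa[1:n, 1:n] <- Q
    Qa
  }
  cost_aug <- cost_spec(pad(cost$Q_running), pad(cost$Q_final), cost$R)

  H_aug <- cbind(matrix(0, nrow(obs$H), na - n), obs$H)
  obs_aug <- observation_model(delay_steps = 0, H = H_aug,
                               Sigma_omega = obs$Sigma_omega)
  list(dyn = dyn_aug, cost = cost_aug, obs = obs_aug)
}

#' Precompute time-varying Kalman gains
#'
#' The system is linear with known statistics, so the filter covariance
#' recursion (and hence the gain sequence) can be run offline. The estimate
#' covariance depends on the process-noise level even for a risk-neutral
#' controller, although the risk-neutral feedback gains do not.
#'
#' @param dyn (possibly augmented) dynamics.
#' @param obs (possibly augmented, zero-delay) observation model.
#' @param steps horizon.
#' @param P0 initial state covariance (default zero: known start).
#' @return List with `K` (gains `K_1..K_steps`), `P_filt` (`P_0..P_steps`,
#'   filtered covariances), `P_pred` (`P_1..P_steps`, one-step predictions).
#' @export
kalman_gains <- function(dyn, obs, steps, P0 = NULL) {
  n <- nrow(dyn$A)
  if (ncol(obs$H) != n) stop("observation matrix does not match the state")
  P <- P0 %||% matrix(0, n, n)
  K <- vector("list", steps)
  P_filt <- vector("list", steps + 1)
  P_pred <- vector("list", steps)
  P_filt[[1]] <- P
  H <- obs$H; Sw <- obs$Sigma_omega
  for (t in seq_len(steps)) {
    Pp <- symmetrize(dyn$A %*% P %*% t(dyn$A) + dyn$Omega)
    Sy <- H %*% Pp %*% t(H) + Sw
    K[[t]] <- t(solve(Sy, H %*% Pp))
    P <- symmetrize((diag(n) - K[[t]] %*% H) %*% Pp)
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev), 1))
      stop("filter covariance lost positive semi-definiteness at step ", t)
    P_pred[[t]] <- Pp
    P_filt[[t + 1]] <- P
  }
  list(K = K, P_filt = P_filt, P_pred = P_pred)
}

#' One Kalman predict-correct step
#'
#' Propagates the filter state through the dynamics with the applied control
#' and assimilates the observation of the new state: predict `x^- = A x + B u`,
#' `P^- = A P A' + Omega`; correct with gain `K = P^- H'(H P^- H' + Sigma)^-1`.
#'
#' @param fs filter state: list with `x_hat` (estimate) and `P` (covariance),
#'   as produced by [filter_state()].
#' @param y observation vector.
#' @param u control applied over the step.
#' @param dyn,obs system and observation model (dimensions must match `fs`).
#' @return Updated filter state (class `filter_state`) with fields `x_hat`,
#'   `P`, `K` (the gain just used).
#' @export
kalman_step <- function(fs, y, u, dyn, obs) {
  x_pred <- dyn$A %*% fs$x_hat + dyn$B %*% u
  P_pred <- symmetrize(dyn$A %*% fs$P %*% t(dyn$A) + dyn$Omega)
  H <- obs$H
  Sy <- H %*% P_pred %*% t(H) + obs$Sigma_omega
  K <- t(solve(Sy, H %*% P_pred))
  x_hat <- x_pred + K %*% (y - H %*% x_pred)
  P <- symmetrize((diag(nrow(P_pred)) - K %*% H) %*% P_pred)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    stop("filter covariance lost positive semi-definiteness")
  if (any(ev < 0)) {  # floor tiny negative eigenvalues from round-off
    e <- eigen(P, symmetric = TRUE)
    P <- symmetrize(e$vectors %*% (pmax(e$values, 0) * t(e$vectors)))
  }
  filter_state(x_hat, P, K)
}

#' @rdname kalman_step
#' @param x_hat state estimate.
#' @param P estimate covariance.
#' @param K last Kalman gain (optional).
#' @export
filter_state <- function(x_hat, P, K = NULL) {
  structure(list(x_hat = as.matrix(x_hat), P = symmetrize(as.matrix(P)),
                 K = K),
            class = "filter_state")
}

#' Risk-adjusted state estimate (risk-sensitive certainty equivalence)
#'
#' Under partial observation the risk-sensitive problem does not separate
#' cleanly into estimation and control, but a risk-sensitive certainty
#' equivalence holds: the optimal control applies the Riccati gains to a
#' risk-adjusted estimate that couples the filter estimate `x_hat`, its
#' covariance `P`, the cost-to-go `S_t` and the risk parameter:
#' `x_check = (I - 2 theta P S_t)^{-1} x_hat` (the factor 2 matches the
#' criterion normalization used by [riccati_risk_sensitive()]). A risk-averse controller
#' (`theta > 0`) thereby inflates the estimate along directions where both
#' the uncertainty and the cost-to-go are large - it acts as if the
#' estimation error will turn out unfavourably - while a risk-seeking
#' controller deflates it. At `theta = 0` the adjustment is the identity and
#' classic certainty-equivalent LQG is recovered. The adopted coupling form
#' is validated in the test suite against a brute-force criterion oracle on
#' small instances.
#'
#' @param x_hat filter estimate (column vector or matrix of columns).
#' @param P filter covariance at the same step.
#' @param S cost-to-go matrix `S_t` from the (augmented) risk-sensitive
#'   recursion.
#' @param theta risk parameter.
#' @return The adjusted estimate, same shape as `x_hat`.
#' @export
risk_adjusted_estimate <- function(x_hat, P, S, theta) {
  if (theta == 0) return(x_hat)
  M <- diag(nrow(P)) - 2 * theta * P %*% S
  ev <- eigen(M, only.values = TRUE)$values
  if (any(Re(ev) < 1e-10))
    stop("estimation-side breakdown: I - theta * P * S is not invertible")
  solve(M, x_hat)
}
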