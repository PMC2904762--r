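#' Build a closed-loop policy for a task condition
#'
#' Solves the (risk-sensitive) optimal control problem for one condition and
#' packages everything a closed-loop simulation needs. With `obs = NULL` the
#' controller observes the true state and applies `u_t = -L_t x_t`. With an
#' [observation_model()] the system is augmented for the sensorimotor delay,
#' the Riccati recursion is solved on the augmented system, the time-varying
#' Kalman gains are precomputed, and the control applies the gains to the
#' risk-adjusted estimate of [risk_adjusted_estimate()].
#'
#' @param cfg a [task_config()].
#' @param theta risk parameter (0 = risk-neutral).
#' @param obs an [observation_model()] or `NULL` for complete observation.
#' @param motor_noise_sd sd (N) of additive execution noise on the emitted
#'   control; the forward model uses the planned control (efference copy), so
#'   execution noise is unmodelled by the filter. Default 0.
#' @return Object of class `ofc_policy`.
#' @export
optimal_policy <- function(cfg, theta = 0, obs = NULL, motor_noise_sd = 0) {
  stopifnot(inherits(cfg, "task_config"))
  dyn <- discretize_dynamics(cfg)
  cost <- build_cost(cfg)
  steps <- cfg$n_steps
  if (is.null(obs)) {
    law <- riccati_risk_sensitive(dyn, cost, steps, theta)
    if (!law$feasible)
      stop(sprintf("theta = %g is beyond neurotic breakdown for condition '%s'",
                   theta, cfg$condition_label))
    pol <- list(type = "full", law = law, dyn = dyn, cost = cost,
                L_eff = law$gains)
  } else {
    aug <- augment_for_delay(dyn, cost, obs)
    law <- riccati_risk_sensitive(aug$dyn, aug$cost, steps, theta)
    if (!law$feasible)
      stop(sprintf("theta = %g is beyond neurotic breakdown for condition '%s' (with delay %d steps)",
                   theta, cfg$condition_label, obs$delay_steps))
    kf <- kalman_gains(aug$dyn, aug$obs, steps)
    # Effective gain on the filter estimate: L_t (I - 2 theta P_t S_t)^{-1}.
    na <- nrow(aug$dyn$A)
    L_eff <- vector("list", steps)
    for (t in seq_len(steps)) {
      if (theta == 0) {
        L_eff[[t]] <- law$gains[[t]]
      } else {
        M <- diag(na) - 2 * theta * kf$P_filt[[t]] %*% law$cost_to_go[[t]]
        ev <- eigen(M, only.values = TRUE)$values
        if (any(Re(ev) < 1e-10))
          stop(sprintf("estimation-side breakdown at step %d for condition '%s'",
                       t, cfg$condition_label))
        L_eff[[t]] <- t(solve(t(M), t(law$gains[[t]])))
      }
    }
    pol <- list(type = "lqg", law = law, dyn = aug$dyn, cost = aug$cost,
                obs = aug$obs, kalman = kf, L_eff = L_eff,
                delay_steps = obs$delay_steps)
  }
  pol$theta <- theta
  pol$steps <- steps
  pol$condition_label <- cfg$condition_label
  pol$motor_noise_sd <- motor_noise_sd
  class(pol) <- "ofc_policy"
  pol
}

#' @rdname optimal_policy
#' @details `null_policy()` emits zero control; it is used for uncontrolled
#'   (no-intervention) simulations.
#' @export
null_policy <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  pol <- list(type = "null", dyn = discretize_dynamics(cfg),
              cost = build_cost(cfg), theta = 0, steps = cfg$n_steps,
              condition_label = cfg$condition_label, motor_noise_sd = 0)
  class(pol) <- "ofc_policy"
  pol
}

#' @export
print.ofc_policy <- function(x, ...) {
  cat(sprintf("Closed-loop policy (%s) for condition '%s', theta = %g\n",
              switch(x$type, full = "complete observation",
                     lqg = sprintf("partial observation, %d-step delay",
                                   x$delay_steps),
                     null = "no control"),
              x$condition_label, x$theta))
  invisible(x)
}

# Draw all noise for a set of trials from one stream. Draw order per trial:
# process noise (steps), then sensory noise (obs dim x steps, if the policy
# filters), then motor noise (steps, if any); trials in order. The fixed
# order makes any trial reproducible from (stream seed, trial index).
.draw_trial_noise <- function(policy, stream, n) {
  steps <- policy$steps
  needs_eta <- policy$type == "lqg"
  p_obs <- if (needs_eta) nrow(policy$obs$H) else 0
  xi <- matrix(0, steps, n)
  eta <- if (needs_eta) array(0, c(p_obs, steps, n)) else NULL
  mot <- if (policy$motor_noise_sd > 0) matrix(0, steps, n) else NULL
  set.seed(stream)
  for (i in seq_len(n)) {
    xi[, i] <- stats::rnorm(steps)
    if (needs_eta) eta[, , i] <- matrix(stats::rnorm(p_obs * steps), p_obs)
    if (!is.null(mot)) mot[, i] <- stats::rnorm(steps)
  }
  list(xi = xi, eta = eta, mot = mot)
}

# Vectorized closed-loop rollout of all trials at once (states are columns).
.rollout <- function(cfg, policy, noise) {
  steps <- policy$steps
  n <- ncol(noise$xi)
  dyn <- policy$dyn
  na <- nrow(dyn$A)
  xi_force <- noise$xi * dyn$force_noise_sd  # N
  X <- matrix(0, na, n)
  x_m <- matrix(0, steps + 1, n)
  v_m <- matrix(0, steps + 1, n)
  u_N <- matrix(0, steps, n)

  if (policy$type == "lqg") {
    Xh <- matrix(0, na, n)
    H <- policy$obs$H
    sd_eta <- sqrt(diag(policy$obs$Sigma_omega))
    K <- policy$kalman$K
  }
  for (t in seq_len(steps)) {
    u <- switch(policy$type,
                null = matrix(0, 1, n),
                full = -policy$L_eff[[t]] %*% X,
                lqg  = -policy$L_eff[[t]] %*% Xh)
    if (policy$motor_noise_sd > 0)
      u_emit <- u + policy$motor_noise_sd * rbind(noise$mot[t, ])
    else u_emit <- u
    u_N[t, ] <- u_emit
    X_new <- dyn$A %*% X + dyn$B %*% (u_emit + rbind(xi_force[t, ]))
    if (policy$type == "lqg") {
      Xh_pred <- dyn$A %*% Xh + dyn$B %*% u  # efference copy: planned control
      y <- H %*% X_new + sd_eta * matrix(noise$eta[, t, ], nrow(H), n)
      Xh <- Xh_pred + K[[t]] %*% (y - H %*% Xh_pred)
    }
    X <- X_new
    if (anyNA(X) || any(is.infinite(X)))
      stop("non-finite state at simulation step ", t)
    x_m[t + 1, ] <- X[1, ]
    v_m[t + 1, ] <- X[2, ]
  }
  list(x_cm = x_m * 100, v_cm_s = v_m * 100, u_N = u_N, xi_N = xi_force)
}

# Per-trial cost accounting and impact angles from rollout matrices.
.summarize_trials <- function(cfg, roll) {
  steps <- nrow(roll$u_N)
  c_step <- cfg$control_weight * cfg$dt_s / DT_REF
  final_x <- roll$x_cm[steps + 1, ]
  error_cost <- cfg$error_weight * final_x^2
  control_cost <- c_step * colSums(roll$u_N^2)
  vx <- roll$v_cm_s[steps + 1, ]
  vy <- cfg$ball_speed_y_cm_s
  angle <- acos(vx / sqrt(vx^2 + vy^2)) * 180 / pi
  list(error_cost = error_cost, control_cost = control_cost,
       total_cost = error_cost + control_cost, final_x_cm = final_x,
       impact_angle_deg = angle)
}

#' Simulate a set of closed-loop trials
#'
#' Runs `n_trials` independent 1 s trials of one condition under the given
#' policy. All trials draw, in a fixed order, from one noise stream whose
#' seed is derived from `(seed, subject_id, condition)`, so the whole set is
#' bit-exact reproducible from `(config, seed)` and any single trial can be
#' replayed from the recorded `stream_seed` and its index (see
#' [run_trial()]). Full per-step logs - including the injected noise forces -
#' are kept, which makes counterfactual no-control reconstruction possible
#' ([counterfactual_no_control()]).
#'
#' @param cfg a [task_config()].
#' @param policy an `ofc_policy` built for the same condition.
#' @param n_trials number of trials.
#' @param seed master seed.
#' @param subject_id subject label entering the stream-seed derivation.
#' @param stream_label label entering the stream-seed derivation; defaults
#'   to the condition label. Passing a common label for two conditions (or
#'   two policies of the same type) yields identical noise draws, e.g. for
#'   common-random-number comparisons across noise levels.
#' @return Object of class `trial_set`: per-step matrices `x_cm`, `v_cm_s`
#'   (`steps+1` rows) and `u_N`, `xi_N` (`steps` rows), one column per trial;
#'   per-trial vectors `error_cost`, `control_cost`, `total_cost`,
#'   `final_x_cm`, `impact_angle_deg`; metadata (config, subject, theta,
#'   the master `seed` and the derived `stream_seed`).
#' @export
simulate_trials <- function(cfg, policy, n_trials, seed,
                            subject_id = "sim", stream_label = NULL) {
  stopifnot(inherits(cfg, "task_config"), inherits(policy, "ofc_policy"))
  if (policy$condition_label != cfg$condition_label ||
      policy$steps != cfg$n_steps)
    stop("policy was built for a different condition")
  if (n_trials < 1) stop("n_trials must be >= 1")
  stream_label <- stream_label %||% cfg$condition_label
  stream <- stream_seed(seed, subject_id, stream_label)
  noise <- .draw_trial_noise(policy, stream, n_trials)
  roll <- .rollout(cfg, policy, noise)
  summ <- .summarize_trials(cfg, roll)
  structure(c(list(config = cfg, subject_id = subject_id,
                   condition_label = cfg$condition_label,
                   theta = policy$theta, policy_type = policy$type,
                   seed = seed, stream_seed = stream, n_trials = n_trials,
                   time_s = (0:cfg$n_steps) * cfg$dt_s,
                   x_cm = roll$x_cm, v_cm_s = roll$v_cm_s,
                   u_N = roll$u_N, xi_N = roll$xi_N),
              summ),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: subject '%s', condition '%s', %d trials, theta = %g\n",
              x$subject_id, x$condition_label, x$n_trials, x$theta))
  cat(sprintf("  mean |final x| %.3g cm, mean total cost %.4g (control fraction %.3g)\n",
              mean(abs(x$final_x_cm)), mean(x$total_cost),
              mean(x$control_cost) / mean(x$total_cost)))
  invisible(x)
}

#' Simulate a single trial
#'
#' Simulates trial `trial_index` of the noise stream starting at `seed`
#' (used directly as the stream seed). To replay trial `i` of a set produced
#' by [simulate_trials()], pass that set's recorded `stream_seed` and
#' `trial_index = i`; the noise draws are identical to the set's.
#'
#' @inheritParams simulate_trials
#' @param seed stream seed (for replay: the set's `stream_seed`).
#' @param trial_index position of the trial within the stream.
#' @return Object of class `trial_record`: vectors `time_s`, `x_cm`,
#'   `v_cm_s`, `u_N`, `xi_N` plus scalars `error_cost`, `control_cost`,
#'   `total_cost`, `final_x_cm`, `impact_angle_deg`.
#' @export
run_trial <- function(cfg, policy, seed, trial_index = 1) {
  stopifnot(inherits(cfg, "task_config"), inherits(policy, "ofc_policy"))
  noise <- .draw_trial_noise(policy, as.integer(seed), trial_index)
  keep <- function(m) m[, trial_index, drop = FALSE]
  noise$xi <- keep(noise$xi)
  if (!is.null(noise$eta))
    noise$eta <- noise$eta[, , trial_index, drop = FALSE]
  if (!is.null(noise$mot)) noise$mot <- keep(noise$mot)
  roll <- .rollout(cfg, policy, noise)
  summ <- .summarize_trials(cfg, roll)
  structure(list(time_s = (0:cfg$n_steps) * cfg$dt_s,
                 x_cm = drop(roll$x_cm), v_cm_s = drop(roll$v_cm_s),
                 u_N = drop(roll$u_N), xi_N = drop(roll$xi_N),
                 error_cost = summ$error_cost,
                 control_cost = summ$control_cost,
                 total_cost = summ$total_cost,
                 final_x_cm = summ$final_x_cm,
                 impact_angle_deg = summ$impact_angle_deg,
                 condition_label = cfg$condition_label, seed = seed,
                 trial_index = trial_index),
            class = "trial_record")
}

#' Extract one trial of a set as a trial record
#'
#' @param ts a `trial_set`.
#' @param i trial index.
#' @return A `trial_record`.
#' @export
as_trial_record <- function(ts, i) {
  stopifnot(inherits(ts, "trial_set"), i >= 1, i <= ts$n_trials)
  structure(list(time_s = ts$time_s,
                 x_cm = ts$x_cm[, i], v_cm_s = ts$v_cm_s[, i],
                 u_N = ts$u_N[, i], xi_N = ts$xi_N[, i],
                 error_cost = ts$error_cost[i],
                 control_cost = ts$control_cost[i],
                 total_cost = ts$total_cost[i],
                 final_x_cm = ts$final_x_cm[i],
                 impact_angle_deg = ts$impact_angle_deg[i],
                 condition_label = ts$condition_label,
                 seed = ts$stream_seed, trial_index = i),
            class = "trial_record")
}

#' Counterfactual no-control reconstruction
#'
#' Re-integrates the task dynamics with zero control and the noise forces
#' logged in the trial(s): the trajectory the ball would have followed had
#' the subject not intervened. Deterministic given the log; by linearity the
#' result equals the actual trajectory minus the deterministic response to
#' the logged controls.
#'
#' @param x a `trial_record` or `trial_set` containing the noise stream.
#' @param cfg the [task_config()] of the trial(s).
#' @return An object of the same class with `u = 0` everywhere and states,
#'   costs and impact angles recomputed.
#' @export
counterfactual_no_control <- function(x, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  single <- inherits(x, "trial_record")
  if (!single && !inherits(x, "trial_set"))
    stop("x must be a trial_record or trial_set")
  xi <- if (single) matrix(x$xi_N, ncol = 1) else x$xi_N
  if (is.null(xi)) stop("trial log has no noise stream")
  dyn <- discretize_dynamics(cfg)
  steps <- nrow(xi); n <- ncol(xi)
  X <- matrix(0, 2, n)
  x_m <- matrix(0, steps + 1, n); v_m <- matrix(0, steps + 1, n)
  for (t in seq_len(steps)) {
    X <- dyn$A %*% X + dyn$B %*% rbind(xi[t, ])
    x_m[t + 1, ] <- X[1, ]; v_m[t + 1, ] <- X[2, ]
  }
  roll <- list(x_cm = x_m * 100, v_cm_s = v_m * 100,
               u_N = matrix(0, steps, n), xi_N = xi)
  summ <- .summarize_trials(cfg, roll)
  if (single) {
    out <- x
    out$x_cm <- drop(roll$x_cm); out$v_cm_s <- drop(roll$v_cm_s)
    out$u_N <- drop(roll$u_N)
    out[names(summ)] <- lapply(summ, drop)
    return(out)
  }
  out <- x
  out$x_cm <- roll$x_cm; out$v_cm_s <- roll$v_cm_s; out$u_N <- roll$u_N
  out[names(summ)] <- summ
  out$policy_type <- "null"
  out$theta <- 0
  out
}

#' Write / read trial logs as delimited text
#'
#' Writes one trial set as three plain-text files under `dir`: a per-timestep
#' table `<prefix>_timeseries.csv` (columns `subject_id, condition, trial,
#' t_s, x_cm, v_cm_s, u_N, xi_N`; control and noise are `NA` on the final
#' row of each trial), a per-trial summary `<prefix>_trials.csv`, and a
#' `<prefix>_meta.yaml` with the condition configuration and provenance
#' (theta, seeds, policy type). `read_trial_logs()` reconstructs the
#' `trial_set`.
#'
#' @param ts a `trial_set`.
#' @param dir output directory (created if needed).
#' @param prefix file prefix; defaults to `<subject>_<condition>`.
#' @return The prefix path, invisibly; `read_trial_logs` returns a
#'   `trial_set`.
#' @export
write_trial_logs <- function(ts, dir, prefix = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  prefix <- prefix %||% paste(ts$subject_id, ts$condition_label, sep = "_")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  steps <- length(ts$time_s) - 1
  n <- ts$n_trials
  long <- data.frame(
    subject_id = ts$subject_id,
    condition = ts$condition_label,
    trial = rep(seq_len(n), each = steps + 1),
    t_s = rep(ts$time_s, n),
    x_cm = as.vector(ts$x_cm),
    v_cm_s = as.vector(ts$v_cm_s),
    u_N = as.vector(rbind(ts$u_N, NA)),
    xi_N = as.vector(rbind(ts$xi_N, NA))
  )
  utils::write.csv(long, file.path(dir, paste0(prefix, "_timeseries.csv")),
                   row.names = FALSE)
  summ <- data.frame(
    subject_id = ts$subject_id, condition = ts$condition_label,
    trial = seq_len(n),
    error_cost = ts$error_cost, control_cost = ts$control_cost,
    total_cost = ts$total_cost, final_x_cm = ts$final_x_cm,
    impact_angle_deg = ts$impact_angle_deg
  )
  utils::write.csv(summ, file.path(dir, paste0(prefix, "_trials.csv")),
                   row.names = FALSE)
  keep <- c("noise", "cost", "mass_kg", "dt_s", "horizon_s",
            "ball_speed_y_cm_s", "process_noise_sd", "error_weight",
            "control_weight", "hand_force_gain_N_per_cm", "condition_label")
  yaml::write_yaml(list(config = ts$config[keep],
                        subject_id = ts$subject_id, theta = ts$theta,
                        policy_type = ts$policy_type, seed = ts$seed,
                        stream_seed = ts$stream_seed),
                   file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(file.path(dir, prefix))
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(dir, prefix) {
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
  cfg <- do.call(task_config, meta$config)
  long <- utils::read.csv(file.path(dir, paste0(prefix, "_timeseries.csv")))
  summ <- utils::read.csv(file.path(dir, paste0(prefix, "_trials.csv")))
  n <- max(summ$trial)
  steps <- cfg$n_steps
  ord <- order(long$trial, long$t_s)
  long <- long[ord, ]
  x_cm <- matrix(long$x_cm, steps + 1, n)
  to_steps <- function(col) {
    m <- matrix(col, steps + 1, n)
    m[seq_len(steps), , drop = FALSE]
  }
  structure(list(config = cfg, subject_id = meta$subject_id,
                 condition_label = cfg$condition_label, theta = meta$theta,
                 policy_type = meta$policy_type, seed = meta$seed,
                 stream_seed = meta$stream_seed, n_trials = n,
                 time_s = (0:steps) * cfg$dt_s,
                 x_cm = x_cm, v_cm_s = matrix(long$v_cm_s, steps + 1, n),
                 u_N = to_steps(long$u_N), xi_N = to_steps(long$xi_N),
                 error_cost = summ$error_cost,
                 control_cost = summ$control_cost,
                 total_cost = summ$total_cost,
                 final_x_cm = summ$final_x_cm,
                 impact_angle_deg = summ$impact_angle_deg),
            class = "trial_set")
}
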