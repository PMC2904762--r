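#' Lagged policy-plane regression
#'
#' Estimates a subject's feedback gains in one condition by regressing the
#' control signal emitted at `probe_time_s + lag_s` (default 0.9 s) onto the
#' ball's x-position and x-velocity at `probe_time_s` (default 0.75 s), one
#' observation per trial, with no intercept (the target is at zero, so the
#' policy plane passes through the origin). The lag absorbs the sensorimotor
#' delay. R-squared is computed against the zero-prediction baseline, as
#' appropriate for a through-the-origin fit.
#'
#' @param ts a `trial_set`.
#' @param probe_time_s state probe time (s).
#' @param lag_s lag between state and control (s).
#' @return Object of class `gain_estimate`: `position_gain` (N/cm),
#'   `velocity_gain` (N/(cm/s)), standard errors, coefficient covariance
#'   `vcov`, `r_squared`, `probe_time_s`, `lag_s`, `n_trials`.
#' @export
fit_policy_plane <- function(ts, probe_time_s = 0.75, lag_s = 0.15) {
  stopifnot(inherits(ts, "trial_set"))
  d <- .probe_data(ts, probe_time_s, lag_s)
  if (ts$n_trials <= 2) stop("need more than 2 trials to fit the plane")
  X <- cbind(x = d$x, v = d$v)
  if (qr(X)$rank < 2)
    stop("degenerate predictors: position and velocity are collinear")
  fit <- stats::lm.fit(X, d$u)
  beta <- fit$coefficients
  res <- fit$residuals
  dof <- ts$n_trials - 2
  sigma2 <- sum(res^2) / dof
  XtX_inv <- chol2inv(chol(crossprod(X)))
  vc <- sigma2 * XtX_inv
  r2 <- 1 - sum(res^2) / sum(d$u^2)
  structure(list(position_gain = unname(beta[1]),
                 velocity_gain = unname(beta[2]),
                 position_se = sqrt(vc[1, 1]), velocity_se = sqrt(vc[2, 2]),
                 vcov = vc, r_squared = r2, sigma = sqrt(sigma2),
                 probe_time_s = probe_time_s, lag_s = lag_s,
                 n_trials = ts$n_trials,
                 condition_label = ts$condition_label,
                 subject_id = ts$subject_id),
            class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf("Policy plane (%s, %s): u(%.2f s) ~ state(%.2f s), %d trials\n",
              x$subject_id, x$condition_label, x$probe_time_s + x$lag_s,
              x$probe_time_s, x$n_trials))
  cat(sprintf("  position gain %.4g +/- %.2g N/cm, velocity gain %.4g +/- %.2g N/(cm/s), R^2 = %.3f\n",
              x$position_gain, x$position_se, x$velocity_gain, x$velocity_se,
              x$r_squared))
  invisible(x)
}

# State at the probe time and control one lag later, one point per trial.
.probe_data <- function(ts, probe_time_s, lag_s) {
  dt <- ts$config$dt_s
  i_state <- round(probe_time_s / dt) + 1
  i_u <- round((probe_time_s + lag_s) / dt) + 1
  if (i_state < 1 || i_state > nrow(ts$x_cm))
    stop("probe_time_s outside the trial horizon")
  if (i_u < 1 || i_u > nrow(ts$u_N))
    stop("probe_time_s + lag_s outside the control horizon")
  list(x = ts$x_cm[i_state, ], v = ts$v_cm_s[i_state, ], u = ts$u_N[i_u, ])
}

#' Nested-model F-test for a shared gain across two conditions
#'
#' Tests whether two conditions share the same position (or velocity) gain.
#' The full model fits both conditions jointly with separate position and
#' velocity slopes (4 predictors); the reduced model constrains the chosen
#' slope to be shared (3 predictors). The test compares the residual sums of
#' squares with an F statistic on (1, n_a + n_b - 4) degrees of freedom.
#'
#' @param ts_a,ts_b two `trial_set`s fitted at the same probe settings.
#' @param shared which slope the reduced model shares: `"position"` or
#'   `"velocity"`.
#' @param probe_time_s,lag_s probe settings (see [fit_policy_plane()]).
#' @return List with `statistic` (F), `df`, `p.value`, `shared`, and the
#'   residual sums of squares of both models.
#' @export
compare_policies_ftest <- function(ts_a, ts_b,
                                   shared = c("position", "velocity"),
                                   probe_time_s = 0.75, lag_s = 0.15) {
  shared <- match.arg(shared)
  da <- .probe_data(ts_a, probe_time_s, lag_s)
  db <- .probe_data(ts_b, probe_time_s, lag_s)
  na <- length(da$u); nb <- length(db$u)
  u <- c(da$u, db$u)
  xa <- c(da$x, numeric(nb)); xb <- c(numeric(na), db$x)
  va <- c(da$v, numeric(nb)); vb <- c(numeric(na), db$v)
  X_full <- cbind(xa, xb, va, vb)
  X_red <- if (shared == "position") cbind(xa + xb, va, vb)
           else cbind(xa, xb, va + vb)
  sse <- function(X) sum(stats::lm.fit(X, u)$residuals^2)
  sse_f <- sse(X_full); sse_r <- sse(X_red)
  df2 <- na + nb - 4
  f <- max(0, (sse_r - sse_f)) / (sse_f / df2)
  list(statistic = f, df = c(1, df2),
       p.value = stats::pf(f, 1, df2, lower.tail = FALSE),
       shared = shared, sse_full = sse_f, sse_reduced = sse_r)
}

#' Model-predicted gain differences over a risk-parameter grid
#'
#' For each `theta` on a grid, simulates the risk-sensitive controller
#' closed-loop in a low-noise and a high-noise condition (same estimator
#' settings as the synthetic subjects) and applies the same policy-plane
#' estimator as is applied to data, yielding the predicted
#' (position-gain difference, velocity-gain difference) between the noise
#' conditions. This prediction manifold is the lookup table for
#' [infer_theta()]; computing it once per condition pair and reusing it
#' across subjects is much cheaper than re-simulating per subject.
#'
#' The default grid places `n_grid` log-spaced points per branch between
#' 0.5% and 90% of the feasibility (breakdown) boundary of the risk-averse
#' branch, mirrored onto the risk-seeking branch (which has no breakdown of
#' its own), plus `theta = 0`.
#'
#' @param cfg_low,cfg_high the low- and high-noise [task_config()]s (same
#'   cost level).
#' @param obs [observation_model()] of the simulated subject (`NULL` for
#'   complete observation).
#' @param theta_grid explicit grid, or `NULL` for the default.
#' @param n_grid points per branch of the default grid.
#' @param n_trials simulated trials per condition and grid point.
#' @param probe_time_s,lag_s estimator settings.
#' @param motor_noise_sd execution noise of the simulated subject.
#' @param seed RNG seed for the prediction simulations.
#' @return Object of class `theta_predictions`: data frame with columns
#'   `theta`, `d_pos`, `d_vel` plus the settings as attributes.
#' @export
theta_prediction_grid <- function(cfg_low, cfg_high, obs = NULL,
                                  theta_grid = NULL, n_grid = 50,
                                  n_trials = 1000,
                                  probe_time_s = 0.75, lag_s = 0.15,
                                  motor_noise_sd = 0, seed = 1) {
  if (is.null(theta_grid))
    theta_grid <- default_theta_grid(list(cfg_low, cfg_high), obs, n_grid)
  rows <- lapply(theta_grid, function(th) {
    g <- lapply(list(cfg_low, cfg_high), function(cfg) {
      pol <- optimal_policy(cfg, theta = th, obs = obs,
                            motor_noise_sd = motor_noise_sd)
      ts <- simulate_trials(cfg, pol, n_trials, seed,
                            subject_id = "theta_grid")
      fit_policy_plane(ts, probe_time_s, lag_s)
    })
    data.frame(theta = th,
               d_pos = g[[2]]$position_gain - g[[1]]$position_gain,
               d_vel = g[[2]]$velocity_gain - g[[1]]$velocity_gain)
  })
  out <- do.call(rbind, rows)
  attr(out, "probe_time_s") <- probe_time_s
  attr(out, "lag_s") <- lag_s
  attr(out, "n_trials") <- n_trials
  attr(out, "conditions") <- c(cfg_low$condition_label,
                               cfg_high$condition_label)
  class(out) <- c("theta_predictions", "data.frame")
  out
}

#' Default risk-parameter grid for a set of conditions
#'
#' Log-spaced grid with `n_grid` points per branch between 0.5% and
#' `frac` times the smallest feasibility boundary across the given
#' conditions (the risk-seeking branch, which has no breakdown of its own,
#' is mirrored), plus `theta = 0`. Using one grid across all conditions of
#' a design lets per-pair inferences be pooled.
#'
#' @param conditions list of [task_config()]s.
#' @param obs observation model or `NULL`.
#' @param n_grid points per branch.
#' @param frac fraction of the breakdown boundary to reach.
#' @return Numeric vector of `2 * n_grid + 1` theta values.
#' @export
default_theta_grid <- function(conditions, obs = NULL, n_grid = 50,
                               frac = 0.9) {
  th_max <- frac * min(vapply(conditions, policy_breakdown_theta,
                              numeric(1), obs = obs))
  branch <- exp(seq(log(th_max * 0.005), log(th_max), length.out = n_grid))
  c(-rev(branch), 0, branch)
}

#' Pool risk-parameter inference over several condition pairs
#'
#' Joint inference over all noise-condition pairs of a design (e.g. the low-
#' and high-control-cost pairs): the per-pair Mahalanobis distance profiles
#' are summed over a common theta grid and minimized jointly. This uses all
#' four conditions of a subject and classifies weak risk attitudes more
#' reliably than either pair alone.
#'
#' @param pairs list of condition pairs, each a list/pair `(ts_low, ts_high)`
#'   of `trial_set`s (low- vs high-noise at one cost level).
#' @param predictions list of `theta_predictions` tables, one per pair, all
#'   sharing the same theta grid (see [default_theta_grid()]).
#' @inheritParams infer_theta
#' @return A `risk_fit` (as in [infer_theta()]).
#' @export
infer_theta_pooled <- function(pairs, predictions, n_boot = 1000, seed = 1,
                               conf = 0.95) {
  stopifnot(length(pairs) == length(predictions), length(pairs) >= 1)
  grids <- lapply(predictions, `[[`, "theta")
  for (g in grids[-1])
    if (!isTRUE(all.equal(g, grids[[1]])))
      stop("all prediction tables must share one theta grid")
  theta <- grids[[1]]
  probe <- attr(predictions[[1]], "probe_time_s")
  lag <- attr(predictions[[1]], "lag_s")

  per_pair <- Map(function(pair, pred) {
    fl <- fit_policy_plane(pair[[1]], probe, lag)
    fh <- fit_policy_plane(pair[[2]], probe, lag)
    list(dl = .probe_data(pair[[1]], probe, lag),
         dh = .probe_data(pair[[2]], probe, lag),
         W = tryCatch(solve(fl$vcov + fh$vcov), error = function(e) diag(2)),
         pred = as.matrix(pred[, c("d_pos", "d_vel")]),
         d_obs = c(fh$position_gain - fl$position_gain,
                   fh$velocity_gain - fl$velocity_gain))
  }, pairs, predictions)

  profile_for <- function(d_list) {
    D <- 0
    for (i in seq_along(per_pair)) {
      dev <- sweep(per_pair[[i]]$pred, 2, d_list[[i]])
      D <- D + rowSums((dev %*% per_pair[[i]]$W) * dev)
    }
    D
  }
  D <- profile_for(lapply(per_pair, `[[`, "d_obs"))
  i_hat <- which.min(D)

  coef_of <- function(d, idx) {
    X <- cbind(d$x[idx], d$v[idx])
    drop(qr.solve(crossprod(X), crossprod(X, d$u[idx])))
  }
  set.seed(seed)
  theta_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ds <- lapply(per_pair, function(pp) {
      il <- sample.int(length(pp$dl$u), replace = TRUE)
      ih <- sample.int(length(pp$dh$u), replace = TRUE)
      coef_of(pp$dh, ih) - coef_of(pp$dl, il)
    })
    theta_boot[b] <- theta[which.min(profile_for(ds))]
  }
  alpha <- (1 - conf) / 2
  structure(list(theta_hat = theta[i_hat],
                 theta_sd = stats::sd(theta_boot),
                 theta_ci = unname(stats::quantile(theta_boot,
                                                   c(alpha, 1 - alpha))),
                 theta_boot = theta_boot,
                 gain_diff_position = per_pair[[1]]$d_obs[1],
                 gain_diff_velocity = per_pair[[1]]$d_obs[2],
                 extrapolated = i_hat == 1L || i_hat == length(theta),
                 condition_pair = unlist(lapply(pairs, function(p)
                   c(p[[1]]$condition_label, p[[2]]$condition_label))),
                 subject_id = pairs[[1]][[1]]$subject_id),
            class = "risk_fit")
}

#' Feasibility boundary of the risk parameter for a condition
#'
#' Largest risk-averse `theta` for which a full closed-loop policy (control
#' recursion and, under partial observation, the estimator coupling) can be
#' built for the condition, found by bisection.
#'
#' @param cfg a [task_config()].
#' @param obs observation model or `NULL`.
#' @param tol relative bisection tolerance.
#' @return The positive breakdown boundary.
#' @export
policy_breakdown_theta <- function(cfg, obs = NULL, tol = 1e-3) {
  feasible <- function(th)
    tryCatch({optimal_policy(cfg, theta = th, obs = obs); TRUE},
             error = function(e) FALSE)
  hi <- 1
  while (feasible(hi)) hi <- hi * 2
  lo <- hi / 2
  if (!feasible(lo)) {
    lo <- 0
    while (!feasible(hi) && hi > 1e-12) hi <- hi / 2
    lo <- hi; hi <- hi * 2
  }
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Infer a subject's risk parameter from gain differences
#'
#' Compares the observed differences in position and velocity gains between
#' a low-noise and a high-noise condition with the differences predicted by
#' the risk-sensitive controller over a `theta` grid
#' ([theta_prediction_grid()]), and returns the grid `theta` minimizing the
#' Mahalanobis distance under the regression-coefficient covariance of the
#' observed differences (Euclidean distance if that covariance is
#' degenerate). Uncertainty comes from a bootstrap over trials.
#'
#' @param ts_low,ts_high the subject's trial sets in the two noise
#'   conditions (same cost level).
#' @param predictions a `theta_predictions` table for the condition pair.
#' @param n_boot bootstrap resamples over trials.
#' @param seed bootstrap seed.
#' @param conf confidence level of the bootstrap interval.
#' @return Object of class `risk_fit`: `theta_hat`, `theta_sd`, `theta_ci`,
#'   `gain_diff_position`, `gain_diff_velocity`, `extrapolated` (TRUE when
#'   the best grid point is an endpoint, i.e. the observed differences lie
#'   outside the predicted manifold), `condition_pair`.
#' @export
infer_theta <- function(ts_low, ts_high, predictions, n_boot = 1000,
                        seed = 1, conf = 0.95) {
  stopifnot(inherits(predictions, "theta_predictions"))
  probe <- attr(predictions, "probe_time_s")
  lag <- attr(predictions, "lag_s")
  fl <- fit_policy_plane(ts_low, probe, lag)
  fh <- fit_policy_plane(ts_high, probe, lag)
  d_obs <- c(fh$position_gain - fl$position_gain,
             fh$velocity_gain - fl$velocity_gain)
  Sigma <- fl$vcov + fh$vcov
  W <- tryCatch(solve(Sigma), error = function(e) diag(2))
  pred <- as.matrix(predictions[, c("d_pos", "d_vel")])
  nearest <- function(d) {
    dev <- sweep(pred, 2, d)
    which.min(rowSums((dev %*% W) * dev))
  }
  i_hat <- nearest(d_obs)
  theta_hat <- predictions$theta[i_hat]
  extrapolated <- i_hat == 1L || i_hat == nrow(pred)

  dl <- .probe_data(ts_low, probe, lag)
  dh <- .probe_data(ts_high, probe, lag)
  boot_coef <- function(d, idx) {
    X <- cbind(d$x[idx], d$v[idx])
    qr.solve(crossprod(X), crossprod(X, d$u[idx]))
  }
  set.seed(seed)
  theta_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    il <- sample.int(length(dl$u), replace = TRUE)
    ih <- sample.int(length(dh$u), replace = TRUE)
    db <- drop(boot_coef(dh, ih) - boot_coef(dl, il))
    theta_boot[b] <- predictions$theta[nearest(db)]
  }
  alpha <- (1 - conf) / 2
  structure(list(theta_hat = theta_hat,
                 theta_sd = stats::sd(theta_boot),
                 theta_ci = unname(stats::quantile(theta_boot,
                                                   c(alpha, 1 - alpha))),
                 theta_boot = theta_boot,
                 gain_diff_position = d_obs[1],
                 gain_diff_velocity = d_obs[2],
                 extrapolated = extrapolated,
                 condition_pair = c(ts_low$condition_label,
                                    ts_high$condition_label),
                 subject_id = ts_low$subject_id),
            class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf("Risk-parameter fit for subject '%s' (%s vs %s):\n",
              x$subject_id, x$condition_pair[1], x$condition_pair[2]))
  cat(sprintf("  theta_hat = %.4g (sd %.3g, CI [%.4g, %.4g])%s\n",
              x$theta_hat, x$theta_sd, x$theta_ci[1], x$theta_ci[2],
              if (x$extrapolated) " [extrapolated: observed differences outside the predicted manifold]" else ""))
  invisible(x)
}

#' Contribution of control cost to total cost
#'
#' The mean control cost divided by the mean total cost of a trial set, with
#' a delta-method standard error over trials. For a risk-neutral controller
#' this fraction is independent of the noise level; it increases with noise
#' for a risk-averse controller and decreases for a risk-seeking one.
#'
#' @param ts a `trial_set`.
#' @return List with `fraction`, `se`, `n_trials`.
#' @export
cost_fraction <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  if (ts$n_trials < 1) stop("empty trial set")
  mt <- mean(ts$total_cost)
  if (mt == 0) stop("total cost is zero on all trials; fraction undefined")
  f <- mean(ts$control_cost) / mt
  se <- stats::sd(ts$control_cost - f * ts$total_cost) /
    (mt * sqrt(ts$n_trials))
  list(fraction = f, se = se, n_trials = ts$n_trials)
}

#' Extra expected cost incurred by risk sensitivity
#'
#' Simulates a risk-sensitive and a risk-neutral controller under identical
#' noise streams (paired seeds) and returns the percentage increase in mean
#' total cost of the risk-sensitive scheme relative to the risk-neutral one.
#' The risk-neutral controller minimizes expected cost, so this is the price
#' of the risk attitude; it is 0 exactly at `theta = 0` and grows with
#' `|theta|`.
#'
#' @param theta risk parameter.
#' @param cfg a [task_config()].
#' @param obs observation model (default: 150 ms delay with the standard
#'   sensory noise, as in the subject simulations).
#' @param n_trials Monte-Carlo trials per controller.
#' @param seed master seed (shared by both controllers).
#' @return List with `percent_extra`, `mean_cost_theta`,
#'   `mean_cost_neutral`, `n_trials`.
#' @export
extra_cost_of_risk <- function(theta, cfg, obs = observation_model(),
                               n_trials = 2000, seed = 1) {
  pol_t <- optimal_policy(cfg, theta = theta, obs = obs)
  pol_0 <- optimal_policy(cfg, theta = 0, obs = obs)
  ts_t <- simulate_trials(cfg, pol_t, n_trials, seed, subject_id = "paired")
  ts_0 <- simulate_trials(cfg, pol_0, n_trials, seed, subject_id = "paired")
  m_t <- mean(ts_t$total_cost); m_0 <- mean(ts_0$total_cost)
  list(percent_extra = 100 * (m_t - m_0) / m_0,
       mean_cost_theta = m_t, mean_cost_neutral = m_0, n_trials = n_trials)
}

#' Orthogonal-impact counts, actual versus counterfactual
#'
#' Counts how many trials hit the target line orthogonally (impact angle
#' within `90 +/- tolerance_deg`) in the actual trajectories and in the
#' counterfactual no-control trajectories reconstructed from the logged
#' noise, plus the variants restricted to central impacts
#' (`|final x| <= center_window_cm`). If control served to orthogonalize the
#' impact, actual counts should exceed counterfactual ones; a risk-averse
#' feedback controller instead adds x-velocity near the end of the trial and
#' reduces orthogonal impacts.
#'
#' @param ts a `trial_set` with logged noise.
#' @param tolerance_deg half-width of the orthogonality band (degrees).
#' @param center_window_cm half-width of the central-impact window (cm).
#' @return Data frame with one row per analysis (`all`, `central`) and
#'   columns `n_orthogonal_actual`, `n_orthogonal_counterfactual`, `n_actual`,
#'   `n_counterfactual`.
#' @export
impact_angle_analysis <- function(ts, tolerance_deg = 5,
                                  center_window_cm = 2.5) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(ts$xi_N)) stop("trial set has no noise stream")
  cf <- counterfactual_no_control(ts, ts$config)
  ortho <- function(s) abs(s$impact_angle_deg - 90) <= tolerance_deg
  central <- function(s) abs(s$final_x_cm) <= center_window_cm
  oa <- ortho(ts); oc <- ortho(cf)
  ca <- central(ts); cc <- central(cf)
  data.frame(
    analysis = c("all", "central"),
    n_orthogonal_actual = c(sum(oa), sum(oa & ca)),
    n_orthogonal_counterfactual = c(sum(oc), sum(oc & cc)),
    n_actual = c(ts$n_trials, sum(ca)),
    n_counterfactual = c(ts$n_trials, sum(cc))
  )
}

#' R-squared of the policy-plane fit as a function of the lag
#'
#' Re-runs [fit_policy_plane()] for each candidate sensorimotor lag (state
#' probed at `probe_time_s`, control read one lag later) and returns the
#' R-squared profile; its peak estimates the subject's visuomotor delay.
#' Given several trial sets (e.g. a subject's four conditions, or a whole
#' cohort) the profiles are averaged before locating the peak: the
#' single-condition peak is noticeably biased by the closed-loop structure
#' (recent controls are known to the controller, recent process noise is
#' not, and the balance of the two shifts with the condition's control
#' power), while the biases largely cancel in the across-condition average.
#'
#' @param ts a `trial_set`, or a list of them.
#' @param lags_s candidate lags (s); all must keep `probe_time_s + lag`
#'   within the control horizon.
#' @param probe_time_s state probe time (s).
#' @return List with `profile` (data frame `lag_s`, `r_squared`; the average
#'   profile when several sets are given), `best_lag_s`, and `by_set` (matrix
#'   of per-set profiles, when several sets are given).
#' @export
delay_sweep <- function(ts, lags_s = seq(0.05, 0.24, by = 0.01),
                        probe_time_s = 0.75) {
  if (length(lags_s) < 1) stop("lags_s must be non-empty")
  sets <- if (inherits(ts, "trial_set")) list(ts) else ts
  if (!all(vapply(sets, inherits, TRUE, "trial_set")))
    stop("ts must be a trial_set or a list of trial_sets")
  by_set <- vapply(sets, function(s)
    vapply(lags_s, function(l)
      fit_policy_plane(s, probe_time_s, l)$r_squared, numeric(1)),
    numeric(length(lags_s)))
  by_set <- matrix(by_set, nrow = length(lags_s))
  r2 <- rowMeans(by_set)
  out <- list(profile = data.frame(lag_s = lags_s, r_squared = r2),
              best_lag_s = lags_s[which.max(r2)])
  if (length(sets) > 1) out$by_set <- by_set
  out
}
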