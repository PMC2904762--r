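#' Task configuration for one experimental condition
#'
#' Defines the ball-steering task: a virtual ball travels at constant
#' y-velocity towards a target line which it reaches exactly at the horizon,
#' while its x-motion is a frictionless point mass driven by the sum of a
#' Brownian random force and the player's control force. Crossing the line
#' off-center incurs a quadratic error cost (weight `error_weight` per cm^2)
#' and control incurs a cumulative quadratic cost (weight `control_weight`
#' per N^2 per reference time step).
#'
#' The interface works in the task's display units (cm, cm/s) with forces in
#' N; internally dynamics are propagated in SI units (m, m/s, N) and
#' converted at the interface. `process_noise_sd` is the standard deviation
#' of the random force (N) per step at the reference step of 10 ms; at other
#' step sizes the per-step force is rescaled by `sqrt(dt_ref/dt)` so that the
#' displacement statistics of the ball are invariant to the discretization.
#' The control-cost weight is likewise defined per reference step and scaled
#' by `dt/dt_ref`, keeping the integrated control cost discretization
#' invariant.
#'
#' @param noise `"low"` or `"high"` process-noise level. The default high
#'   level is five times the low level, so the uncontrolled final positional
#'   error is five times larger in the high-noise condition.
#' @param cost `"low"` or `"high"` control-cost level.
#' @param mass_kg ball mass (kg).
#' @param dt_s simulation time step (s).
#' @param horizon_s trial duration (s); `horizon_s / dt_s` must be integral.
#' @param ball_speed_y_cm_s constant y-velocity of the ball (cm/s).
#' @param process_noise_sd sd of the per-step random force (N) at the 10 ms
#'   reference step; overrides the level chosen by `noise`.
#' @param error_weight terminal positional cost weight (points per cm^2).
#' @param control_weight control cost weight (points per N^2 per reference
#'   step); overrides the level chosen by `cost`.
#' @param hand_force_gain_N_per_cm gain mapping hand displacement (cm) to
#'   control force (N); affects only how hand displacement is reported, not
#'   the control problem itself.
#' @param condition_label optional label; defaults to
#'   `"<noise>_noise_<cost>_cost"`.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(noise = c("low", "high"),
                        cost = c("low", "high"),
                        mass_kg = 1,
                        dt_s = 0.01,
                        horizon_s = 1,
                        ball_speed_y_cm_s = 15,
                        process_noise_sd = NULL,
                        error_weight = 1,
                        control_weight = NULL,
                        hand_force_gain_N_per_cm = NULL,
                        condition_label = NULL) {
  noise <- match.arg(noise)
  cost <- match.arg(cost)
  process_noise_sd <- process_noise_sd %||%
    switch(noise, low = 1, high = 5)
  control_weight <- control_weight %||%
    switch(cost, low = 0.1, high = 0.3)
  hand_force_gain_N_per_cm <- hand_force_gain_N_per_cm %||%
    switch(noise, low = 10, high = 50)
  condition_label <- condition_label %||%
    sprintf("%s_noise_%s_cost", noise, cost)

  if (!is.numeric(dt_s) || dt_s <= 0) stop("dt_s must be positive")
  if (!is.numeric(mass_kg) || mass_kg <= 0) stop("mass_kg must be positive")
  n_steps <- horizon_s / dt_s
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("horizon_s must be an integer multiple of dt_s")
  if (process_noise_sd < 0) stop("process_noise_sd must be >= 0")
  if (error_weight < 0) stop("error_weight must be >= 0")
  if (control_weight <= 0) stop("control_weight must be > 0")

  cfg <- list(
    noise = noise,
    cost = cost,
    mass_kg = mass_kg,
    dt_s = dt_s,
    horizon_s = horizon_s,
    n_steps = as.integer(round(n_steps)),
    ball_speed_y_cm_s = ball_speed_y_cm_s,
    target_distance_cm = ball_speed_y_cm_s * horizon_s,
    process_noise_sd = process_noise_sd,
    error_weight = error_weight,
    control_weight = control_weight,
    hand_force_gain_N_per_cm = hand_force_gain_N_per_cm,
    condition_label = condition_label
  )
  class(cfg) <- "task_config"
  cfg
}

# Reference discretization (s) at which process_noise_sd and control_weight
# are defined.
DT_REF <- 0.01

#' @export
print.task_config <- function(x, ...) {
  cat("Ball-steering task condition:", x$condition_label, "\n")
  cat(sprintf("  mass %.3g kg, dt %.3g s, horizon %.3g s (%d steps)\n",
              x$mass_kg, x$dt_s, x$horizon_s, x$n_steps))
  cat(sprintf("  process noise sd %.3g N (per 10 ms step), w_p %.3g /cm^2, c %.3g /N^2\n",
              x$process_noise_sd, x$error_weight, x$control_weight))
  invisible(x)
}

#' The four conditions of the two-noise by two-cost design
#'
#' @param ... arguments passed on to [task_config()] (applied to all four
#'   conditions).
#' @return Named list of four `task_config` objects.
#' @export
default_conditions <- function(...) {
  out <- list()
  for (noise in c("low", "high")) {
    for (cost in c("low", "high")) {
      cfg <- task_config(noise = noise, cost = cost, ...)
      out[[cfg$condition_label]] <- cfg
    }
  }
  out
}

#' Explicit-Euler discretization of the task dynamics
#'
#' Builds the discrete-time linear system for the ball's x-motion: the state
#' is `(position, velocity)` in SI units (m, m/s), the control is the force
#' in N, and the process noise is the Brownian random force entering the
#' velocity channel. Position is updated with the pre-update velocity,
#' matching the task's own integrator. The per-step noise covariance `Omega`
#' scales so that trajectory statistics do not depend on the step size.
#'
#' @param cfg a [task_config()].
#' @return An object of class `linear_dynamics` with fields `A` (2x2), `B`
#'   (2x1), `Omega` (2x2 per-step state-noise covariance), `dt_s`,
#'   `force_noise_sd` (per-step sd of the random force at this `dt_s`).
#' @export
discretize_dynamics <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  dt <- cfg$dt_s
  m <- cfg$mass_kg
  A <- matrix(c(1, 0, dt, 1), 2, 2)
  B <- matrix(c(0, dt / m), 2, 1)
  sd_step <- cfg$process_noise_sd * sqrt(DT_REF / dt)
  Omega <- tcrossprod(B) * sd_step^2
  linear_dynamics(A, B, Omega, dt_s = dt, force_noise_sd = sd_step)
}

#' Construct a discrete-time linear-Gaussian system
#'
#' @param A state-transition matrix.
#' @param B control-input matrix.
#' @param Omega per-step process-noise covariance (symmetric PSD).
#' @param dt_s optional time step for bookkeeping.
#' @param force_noise_sd optional per-step force-noise sd (task systems).
#' @return `linear_dynamics` object.
#' @export
linear_dynamics <- function(A, B, Omega, dt_s = NULL, force_noise_sd = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); Omega <- as.matrix(Omega)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (nrow(B) != n) stop("B must have as many rows as A")
  if (!all(dim(Omega) == c(n, n))) stop("Omega must match the state dimension")
  if (!is_psd(Omega)) stop("Omega must be symmetric positive semi-definite")
  structure(list(A = A, B = B, Omega = symmetrize(Omega), dt_s = dt_s,
                 force_noise_sd = force_noise_sd),
            class = "linear_dynamics")
}

#' Quadratic cost specification for the task
#'
#' Only the final positional error is penalized: the running state cost is
#' zero, the terminal state cost carries the positional weight, and every
#' control step carries the control weight. Weights are converted to the SI
#' state units used internally (the positional weight is per cm^2 at the
#' interface, hence multiplied by 1e4 for a state in m), and the per-step
#' control weight is scaled by `dt/dt_ref` so the integrated control cost is
#' invariant to the discretization.
#'
#' @param cfg a [task_config()].
#' @return An object of class `cost_spec` with fields `Q_running`, `Q_final`,
#'   `R` (all matrices).
#' @export
build_cost <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$control_weight <= 0)
    stop("control_weight must be > 0 (R must be invertible)")
  Q_final <- matrix(c(cfg$error_weight * 1e4, 0, 0, 0), 2, 2)
  cost_spec(Q_running = matrix(0, 2, 2), Q_final = Q_final,
            R = matrix(cfg$control_weight * cfg$dt_s / DT_REF, 1, 1))
}

#' Construct a quadratic cost specification
#'
#' @param Q_running per-step state cost matrix (symmetric PSD).
#' @param Q_final terminal state cost matrix (symmetric PSD).
#' @param R control cost matrix (symmetric positive definite).
#' @return `cost_spec` object.
#' @export
cost_spec <- function(Q_running, Q_final, R) {
  Q_running <- as.matrix(Q_running); Q_final <- as.matrix(Q_final)
  R <- as.matrix(R)
  if (!is_psd(Q_running) || !is_psd(Q_final))
    stop("Q matrices must be symmetric positive semi-definite")
  ev <- eigen(symmetrize(R), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("R must be positive definite")
  structure(list(Q_running = symmetrize(Q_running),
                 Q_final = symmetrize(Q_final),
                 R = symmetrize(R)),
            class = "cost_spec")
}

#' Read / write experiment configuration files
#'
#' The experiment configuration is a hierarchical YAML file with one block
#' per condition holding [task_config()] fields. The packaged default
#' (`system.file("extdata", "default_experiment.yaml", package = "rsofc")`)
#' reproduces the two-noise by two-cost design.
#'
#' @param path file path.
#' @return `read_experiment_config` returns a named list of `task_config`
#'   objects.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$conditions)) stop("config file has no 'conditions' block")
  out <- lapply(names(raw$conditions), function(nm) {
    fields <- raw$conditions[[nm]]
    fields$condition_label <- fields$condition_label %||% nm
    do.call(task_config, fields)
  })
  names(out) <- names(raw$conditions)
  out
}

#' @rdname read_experiment_config
#' @param conditions named list of `task_config` objects.
#' @export
write_experiment_config <- function(conditions, path) {
  keep <- c("noise", "cost", "mass_kg", "dt_s", "horizon_s",
            "ball_speed_y_cm_s", "process_noise_sd", "error_weight",
            "control_weight", "hand_force_gain_N_per_cm", "condition_label")
  blocks <- lapply(conditions, function(cfg) cfg[keep])
  yaml::write_yaml(list(conditions = blocks), path)
  invisible(path)
}
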