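#' Specify a synthetic subject
#'
#' A synthetic subject is a risk-sensitive optimal controller with an
#' individual risk parameter `theta`, sensory noise, a sensorimotor delay
#' (default 150 ms) and optionally additive execution noise, run through the
#' two-noise by two-cost experimental design with 250 analyzed trials per
#' condition. Generated data carries its ground truth in metadata, so
#' parameter-recovery experiments can be closed-loop.
#'
#' @param subject_id subject label.
#' @param theta risk parameter (positive = risk-averse).
#' @param delay_steps sensorimotor delay in 10 ms steps (default 15).
#' @param pos_noise_sd_cm,vel_noise_sd_cm_s sensory noise (cm, cm/s).
#' @param motor_noise_sd additive execution noise on the emitted control (N);
#'   default 0 (an ideal controller). A small value leaves the regression
#'   fits with realistic residual variance.
#' @param conditions list of the four [task_config()]s (default the packaged
#'   2x2 design).
#' @param trials_per_condition analyzed trials per condition (default 250).
#' @param training_trials extra leading trials per condition, labeled
#'   `"training"` in the logs for exclusion symmetry with a training phase;
#'   the generator emits steady-state behavior throughout (no learning is
#'   simulated). Default 0.
#' @return Object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, theta = 0, delay_steps = 15,
                         pos_noise_sd_cm = 0.5, vel_noise_sd_cm_s = 5,
                         motor_noise_sd = 0,
                         conditions = default_conditions(),
                         trials_per_condition = 250,
                         training_trials = 0) {
  if (trials_per_condition < 1) stop("trials_per_condition must be >= 1")
  if (length(conditions) < 1) stop("at least one condition is required")
  structure(list(subject_id = subject_id, theta = theta,
                 delay_steps = as.integer(delay_steps),
                 pos_noise_sd_cm = pos_noise_sd_cm,
                 vel_noise_sd_cm_s = vel_noise_sd_cm_s,
                 motor_noise_sd = motor_noise_sd,
                 conditions = conditions,
                 trials_per_condition = as.integer(trials_per_condition),
                 training_trials = as.integer(training_trials)),
            class = "subject_spec")
}

#' Observation model of a subject specification
#'
#' @param spec a [subject_spec()].
#' @return An [observation_model()], or `NULL` if the spec has no delay and
#'   no sensory noise (complete observation).
#' @export
subject_observation_model <- function(spec) {
  if (spec$delay_steps == 0 && spec$pos_noise_sd_cm == 0 &&
      spec$vel_noise_sd_cm_s == 0)
    return(NULL)
  observation_model(delay_steps = spec$delay_steps,
                    pos_noise_sd_cm = spec$pos_noise_sd_cm,
                    vel_noise_sd_cm_s = spec$vel_noise_sd_cm_s)
}

#' Generate one synthetic subject's data
#'
#' Solves the risk-sensitive partially observed control problem for each
#' condition of the design and simulates the subject's trials. Fails with an
#' explicit message naming the offending condition if `theta` lies beyond
#' the neurotic-breakdown boundary there.
#'
#' @param spec a [subject_spec()].
#' @param seed master seed; each trial gets its own derived stream.
#' @return Named list of `trial_set`s, one per condition, each carrying the
#'   ground-truth `theta` and seeds in its metadata.
#' @export
generate_subject <- function(spec, seed) {
  stopifnot(inherits(spec, "subject_spec"))
  obs <- subject_observation_model(spec)
  n_total <- spec$trials_per_condition + spec$training_trials
  out <- lapply(spec$conditions, function(cfg) {
    pol <- tryCatch(
      optimal_policy(cfg, theta = spec$theta, obs = obs,
                     motor_noise_sd = spec$motor_noise_sd),
      error = function(e)
        stop(sprintf("subject '%s', condition '%s': %s",
                     spec$subject_id, cfg$condition_label, conditionMessage(e)),
             call. = FALSE))
    ts <- simulate_trials(cfg, pol, n_total, seed,
                          subject_id = spec$subject_id)
    ts$phase <- rep(c("training", "test"),
                    c(spec$training_trials, spec$trials_per_condition))
    ts
  })
  names(out) <- vapply(spec$conditions, `[[`, "", "condition_label")
  out
}

#' Generate a cohort of synthetic subjects
#'
#' @param specs list of [subject_spec()]s.
#' @param seed master seed (per-trial streams are derived from it together
#'   with the subject and condition labels, so subjects are independent).
#' @return Named list (by subject id) of [generate_subject()] outputs.
#' @export
generate_cohort <- function(specs, seed) {
  out <- lapply(specs, generate_subject, seed = seed)
  names(out) <- vapply(specs, `[[`, "", "subject_id")
  out
}

#' Keep only the analyzed (non-training) trials of a set
#'
#' @param ts a `trial_set` produced by [generate_subject()].
#' @return The `trial_set` restricted to trials labeled `"test"` (all trials
#'   if the set has no phase labels).
#' @export
analyzed_trials <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(ts$phase) || all(ts$phase == "test")) return(ts)
  subset_trials(ts, which(ts$phase == "test"))
}

#' Subset a trial set by trial indices
#'
#' @param ts a `trial_set`.
#' @param idx trial indices to keep.
#' @return The restricted `trial_set`.
#' @export
subset_trials <- function(ts, idx) {
  stopifnot(inherits(ts, "trial_set"))
  out <- ts
  for (f in c("x_cm", "v_cm_s", "u_N", "xi_N"))
    out[[f]] <- ts[[f]][, idx, drop = FALSE]
  for (f in c("error_cost", "control_cost", "total_cost", "final_x_cm",
              "impact_angle_deg"))
    out[[f]] <- ts[[f]][idx]
  if (!is.null(ts$phase)) out$phase <- ts$phase[idx]
  out$n_trials <- length(idx)
  out
}
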