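#' Finite-horizon risk-neutral optimal feedback law (LQR)
#'
#' Backward Riccati recursion for the discrete-time linear-quadratic
#' regulator. Starting from the terminal cost-to-go `S_T = Q_final`, each
#' backward step computes the feedback gain
#' `L_t = (R + B' S_{t+1} B)^{-1} B' S_{t+1} A` and the cost-to-go
#' `S_t = Q_t + A' S_{t+1} (A - B L_t)`. The optimal control is
#' `u_t = -L_t x_t`. The process-noise covariance does not enter the
#' recursion, so the risk-neutral law is identical for every noise level.
#'
#' @param dyn a [linear_dynamics()].
#' @param cost a [cost_spec()].
#' @param steps number of control steps (horizon).
#' @return An object of class `control_law`: `gains` (list of `L_t`,
#'   `t = 0..steps-1`, element `i` is the gain applied at step `i - 1`),
#'   `cost_to_go` (list of `S_t`, `t = 0..steps`), `theta`, `feasible`.
#' @seealso [riccati_risk_sensitive()] for the risk-sensitive generalization.
#' @export
riccati_neutral <- function(dyn, cost, steps) {
  riccati_risk_sensitive(dyn, cost, steps, theta = 0)
}

#' Finite-horizon risk-sensitive optimal feedback law (LEQG)
#'
#' Computes the linear feedback law minimizing the exponential-of-quadratic
#' criterion `gamma_theta = (1/theta) log E[exp(theta C)]`, where `C` is the
#' quadratic trial cost. For small `theta` this is approximately
#' `E[C] + (theta/2) Var[C]`: positive `theta` penalizes cost variance
#' (risk-averse), negative `theta` values it (risk-seeking), and `theta = 0`
#' recovers the risk-neutral law exactly.
#'
#' The recursion modifies the standard backward step by passing the
#' cost-to-go through the process noise: `S~_{t+1} = (S_{t+1}^{-1} -
#' 2 theta Omega)^{-1}` (computed as `S (I - 2 theta Omega S)^{-1}` so
#' singular terminal costs are handled), then `L_t` and `S_t` as in the
#' risk-neutral recursion with `S~_{t+1}` in place of `S_{t+1}`. The factor
#' 2 ties the recursion to this package's criterion normalization
#' `(1/theta) log E[exp(theta C)]`; it is verified against a brute-force
#' criterion oracle in the test suite. For a risk-averse
#' controller the inflation grows with the noise covariance, so larger
#' position gains are applied under larger noise; a risk-seeking controller
#' shows the opposite pattern. When `theta` is so large that
#' `I - 2 theta Omega S_{t+1}` loses positive definiteness the criterion
#' diverges ("neurotic breakdown"); the recursion then stops and returns
#' `feasible = FALSE` rather than indefinite cost-to-go matrices.
#'
#' @inheritParams riccati_neutral
#' @param theta risk parameter; positive = risk-averse, negative =
#'   risk-seeking in this package's convention. (Whittle's convention is the
#'   mirror image: his risk-averse branch has negative sign; flip the sign of
#'   `theta` to translate.)
#' @return A `control_law`; check `feasible` before use.
#' @export
riccati_risk_sensitive <- function(dyn, cost, steps, theta) {
  stopifnot(inherits(dyn, "linear_dynamics"), inherits(cost, "cost_spec"))
  if (!is.finite(theta)) stop("theta must be finite")
  steps <- as.integer(steps)
  if (steps < 1) stop("steps must be >= 1")
  A <- dyn$A; B <- dyn$B; Omega <- dyn$Omega
  n <- nrow(A)
  Q <- cost$Q_running; Qf <- cost$Q_final; R <- cost$R
  if (!all(dim(Qf) == n)) stop("cost dimensions do not match the dynamics")

  S <- vector("list", steps + 1)
  L <- vector("list", steps)
  S[[steps + 1]] <- Qf
  I_n <- diag(n)
  for (t in steps:1) {
    S_next <- S[[t + 1]]
    if (theta != 0) {
      M <- I_n - 2 * theta * Omega %*% S_next
      ev <- eigen(M, only.values = TRUE)$values
      if (any(Re(ev) < 1e-10)) {
        return(structure(list(gains = NULL, cost_to_go = NULL, theta = theta,
                              feasible = FALSE, breakdown_step = t),
                         class = "control_law"))
      }
      S_next <- symmetrize(S_next %*% solve(M))
    }
    G <- R + t(B) %*% S_next %*% B
    L[[t]] <- solve(G, t(B) %*% S_next %*% A)
    S[[t]] <- symmetrize(Q + t(A) %*% S_next %*% (A - B %*% L[[t]]))
  }
  structure(list(gains = L, cost_to_go = S, theta = theta, feasible = TRUE),
            class = "control_law")
}

#' @export
print.control_law <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("Infeasible control law: neurotic breakdown at backward step %d (theta = %g)\n",
                x$breakdown_step, x$theta))
    return(invisible(x))
  }
  cat(sprintf("Finite-horizon feedback law: %d steps, theta = %g (%s)\n",
              length(x$gains), x$theta,
              if (x$theta > 0) "risk-averse" else if (x$theta < 0)
                "risk-seeking" else "risk-neutral"))
  cat("  final-step gain L:", format(x$gains[[length(x$gains)]], digits = 5), "\n")
  invisible(x)
}

#' Monte-Carlo estimate of the risk-sensitive criterion of a feedback law
#'
#' Rolls out the fully observed closed loop `u_t = -L_t x_t` under the
#' process noise and evaluates `gamma_theta = (1/theta) log E[exp(theta C)]`
#' (the sample mean of `C` at `theta = 0`) over `n_mc` independent
#' trajectories, using a log-sum-exp so large `theta` does not overflow. This
#' is the model-free optimality oracle: the Riccati law of
#' [riccati_risk_sensitive()] should minimize this criterion over linear
#' feedback laws.
#'
#' @param law a `control_law`, a list of gain matrices (one per step), or a
#'   single gain matrix recycled over all steps.
#' @param dyn,cost system and cost.
#' @param theta risk parameter of the criterion (need not match the law's).
#' @param n_mc number of Monte-Carlo rollouts.
#' @param seed RNG seed.
#' @param steps horizon; defaults to the length of the law.
#' @param x0 initial state (default zero).
#' @return List with `criterion`, `mean_cost`, `var_cost`, `n_mc`. An
#'   infinite `criterion` is evidence that `theta` is beyond breakdown for
#'   this law.
#' @export
risk_criterion <- function(law, dyn, cost, theta, n_mc, seed, steps = NULL,
                           x0 = NULL) {
  stopifnot(n_mc >= 1)
  gains <- if (inherits(law, "control_law")) {
    if (!law$feasible) stop("law is infeasible")
    law$gains
  } else if (is.list(law)) law else NULL
  n <- nrow(dyn$A)
  m <- ncol(dyn$B)
  if (is.null(gains)) {
    if (is.null(steps)) stop("steps must be given with a constant gain")
    gains <- rep(list(matrix(law, m, n)), steps)
  }
  steps <- length(gains)
  x0 <- x0 %||% numeric(n)

  set.seed(seed)
  X <- matrix(x0, n, n_mc)
  costs <- numeric(n_mc)
  Q <- cost$Q_running; R <- cost$R; Qf <- cost$Q_final
  for (t in seq_len(steps)) {
    U <- -gains[[t]] %*% X
    costs <- costs + colSums(X * (Q %*% X)) + colSums(U * (R %*% U))
    X <- dyn$A %*% X + dyn$B %*% U + rmvn_cols(n_mc, dyn$Omega)
  }
  costs <- costs + colSums(X * (Qf %*% X))
  crit <- if (theta == 0) mean(costs) else log_mean_exp(theta * costs) / theta
  list(criterion = crit, mean_cost = mean(costs),
       var_cost = stats::var(costs), n_mc = n_mc)
}

#' Locate the neurotic-breakdown boundary in theta
#'
#' Bisection search for the largest `|theta|` on the given branch for which
#' the risk-sensitive Riccati recursion stays feasible over the horizon.
#'
#' @param dyn,cost,steps as in [riccati_risk_sensitive()].
#' @param branch `"averse"` (positive theta) or `"seeking"` (negative theta).
#'   On the risk-seeking branch the recursion never breaks down for this
#'   task's deflating update; the search is then capped at `upper`.
#' @param upper initial upper bound on `|theta|` (expanded if feasible).
#' @param tol relative bisection tolerance.
#' @return The feasibility boundary for `|theta|` (signed by branch).
#' @export
breakdown_theta <- function(dyn, cost, steps, branch = c("averse", "seeking"),
                            upper = 1, tol = 1e-3) {
  branch <- match.arg(branch)
  sgn <- if (branch == "averse") 1 else -1
  feasible_at <- function(th)
    riccati_risk_sensitive(dyn, cost, steps, sgn * th)$feasible
  hi <- upper
  n_expand <- 0
  while (feasible_at(hi)) {
    hi <- hi * 2
    n_expand <- n_expand + 1
    if (n_expand > 60) return(sgn * hi)  # no breakdown on this branch
  }
  lo <- if (n_expand > 0) hi / 2 else 0
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (feasible_at(mid)) lo <- mid else hi <- mid
  }
  sgn * lo
}
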