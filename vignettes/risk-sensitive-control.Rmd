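---
title: "Risk-sensitive optimal feedback control of a ball-steering task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-sensitive optimal feedback control of a ball-steering task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its model

A virtual ball travels at a constant 15 cm/s towards a target line that it
reaches after exactly 1 s. Along the orthogonal (x) axis the ball is a
frictionless unit mass driven by two forces: a Brownian random force, drawn
independently at every time step from a zero-mean Gaussian, and a control
force chosen by the player (in the original task, the lateral hand
displacement mapped linearly to force). Crossing the line off-center incurs
a quadratic error cost $w_p\,x_T^2$; control incurs a cumulative quadratic
cost $c\sum_t u_t^2$. The player is asked to minimize the total score.

Discretized with explicit Euler at $\Delta t$ (position updated with the
pre-update velocity, matching the task's own integrator), the x-state
$x_t = (\text{position}, \text{velocity})$ follows

$$x_{t+1} = A x_t + B (u_t + \xi_t), \qquad
A = \begin{pmatrix}1 & \Delta t\\ 0 & 1\end{pmatrix},\quad
B = \begin{pmatrix}0\\ \Delta t/m\end{pmatrix},$$

with $\xi_t \sim \mathcal N(0, \sigma^2)$ the random force, so the process
noise covariance is $\Omega = \sigma^2 B B^\top$. Internally the package
works in SI units (m, m/s, N) and converts to the task's display units (cm)
at every interface; the positional cost weight, quoted per cm$^2$, is
converted accordingly.

Two invariances tie the model to the discretization. The per-step force
noise is rescaled as $\sigma\sqrt{\Delta t_{\mathrm{ref}}/\Delta t}$
(reference step 10 ms) so that the ball's displacement statistics do not
depend on $\Delta t$, and the per-step control weight is scaled by
$\Delta t/\Delta t_{\mathrm{ref}}$ so the integrated control cost is
likewise step-invariant.

## Risk-neutral and risk-sensitive control

The risk-neutral benchmark is the finite-horizon LQR: backward from
$S_T = Q_T$ (the terminal positional cost),

$$L_t = (R + B^\top S_{t+1} B)^{-1} B^\top S_{t+1} A, \qquad
S_t = Q_t + A^\top S_{t+1} (A - B L_t), \qquad u_t = -L_t x_t .$$

$\Omega$ appears nowhere, so the risk-neutral law is identical at every
noise level — the linchpin of the experimental design: any systematic
change of the feedback gains with the noise level falsifies risk-neutral
control.

The risk-sensitive (LEQG) controller instead minimizes the
exponential-of-cost criterion

$$\gamma_\theta = \tfrac{1}{\theta} \log E\!\left[e^{\theta C}\right]
\;\approx\; E[C] + \tfrac{\theta}{2}\,\mathrm{Var}[C] \quad (\theta \to 0),$$

so positive $\theta$ penalizes cost variance (risk-averse), negative
$\theta$ values it (risk-seeking), and $\theta = 0$ recovers the mean. The
optimal law stays linear; the only change is that each backward step first
passes the cost-to-go through the process noise,

$$\tilde S_{t+1} = \left(S_{t+1}^{-1} - 2\theta\,\Omega\right)^{-1},$$

computed as $S(I - 2\theta\Omega S)^{-1}$ so the singular terminal cost is
handled. The factor 2 is tied to the criterion normalization above: with
the exponent $\theta\,x^\top S x$, the Gaussian integral over the process
noise contributes $(I - 2\theta\Omega S)^{-1}$. We fixed this factor
against an exact oracle — the closed-form Gaussian integral of the
criterion for a two-step scalar system under arbitrary linear feedback —
whose numerical argmin the recursion reproduces on both branches (the test
suite keeps this check). Conventions in the literature differ by exactly
this scalar and by the sign of $\theta$; to translate to Whittle's
convention flip the sign of $\theta$ and absorb the factor 2 into it.

For a risk-averse controller the inflation grows with $\Omega$, so larger
feedback gains are applied under larger noise; risk-seeking controllers
show the opposite ordering. When $2\theta\,\Omega S_{t+1}$ reaches unit
eigenvalue the criterion diverges ("neurotic breakdown"): the recursion
detects the loss of positive definiteness (smallest real eigenvalue below
1e-10) and returns an explicit infeasibility flag rather than indefinite
cost-to-go matrices. `breakdown_theta()` and `policy_breakdown_theta()`
locate the boundary by bisection; the risk-seeking branch has no breakdown
(the deflation only shrinks the cost-to-go).

Numerically, all inversions go through linear solves, and every $S_t$ and
covariance is re-symmetrized after each update; over the 100-step horizon
(and 32-dimensional augmented states) this keeps the recursions stable.

## Partial observation: sensory noise, delay, and coupled estimation

The controller does not see the state: it receives the ball's position and
velocity corrupted by sensory noise (defaults 0.5 cm and 5 cm/s) and
delayed by a 150 ms visuomotor latency (15 steps at 10 ms). The delay is
modelled by stacking the current physical state with its last $d$ lags;
observation reads the oldest block, control, cost and process noise act on
the current block. A standard Kalman filter (gains precomputed offline —
the system is linear with known statistics) provides the estimate
$\hat x_t$; its covariance recursion does depend on $\Omega$, unlike the
risk-neutral control law.

Risk sensitivity breaks the clean separation of estimation and control,
but a risk-sensitive certainty equivalence holds: the gains are applied to
a risk-adjusted estimate

$$\check x_t = (I - 2\theta P_t S_t)^{-1} \hat x_t,$$

which a risk-averse controller uses to act as if the estimation error will
turn out unfavourably (the adjustment inflates the estimate along
directions where uncertainty and cost-to-go are both large). The adopted
coupling form is validated in the test suite by a policy-comparison
oracle: on a small partially observed instance the coupled policy achieves
a lower Monte-Carlo $\gamma_\theta$ than naive certainty equivalence.
Like the control recursion, the coupling can break down
($I - 2\theta P_t S_t$ singular); policy construction reports this as an
explicit infeasibility naming the condition.

## Simulation and reproducibility

`simulate_trials()` runs a whole set of closed-loop trials vectorized
(states are columns of a matrix), logging every state, control and injected
noise force, plus per-trial costs and the impact angle of the final
velocity vector with the target line. Because the noise stream is logged,
the counterfactual trajectory the ball would have followed had the
controller not intervened is reconstructed exactly
(`counterfactual_no_control()`), and superposition holds to numerical
precision: the actual final position equals the counterfactual one plus
the deterministic response to the logged controls.

All trials of a set draw from one generator stream whose seed is a
nonlinear (quadratic-rounds) hash of the master seed, subject and condition
labels. We initially gave every trial its own generator seeded from a
per-trial hash; it turned out that streams started from any deterministic
family of related seeds carry small mutual correlations that are invisible
per trial but systematically distort cross-condition test statistics
(null rejection rates of nested-model F-tests wandered between 0% and 22%
across master-seed ranges). Drawing all trials from a single stream makes
the draws independent across trials by construction; null p-values are
then uniform (KS p = 0.40 over 400 replicates). A single trial is still
reproducible in isolation from the recorded stream seed and its index
(`run_trial()`), and passing a common `stream_label` to two conditions
yields common random numbers for paired comparisons.

## The synthetic experiment

`subject_spec()`/`generate_subject()` emulate the behavioral study: each
synthetic subject is a risk-sensitive controller with an individual
$\theta$, the 150 ms delay, the sensory noise above, optionally additive
execution noise on the emitted command, run through the 2 (noise) x 2
(control cost) design with 250 analyzed trials per condition. Only
steady-state behavior is generated (no trial-by-trial learning); an
optional block of leading trials can be labeled `"training"` purely for
exclusion symmetry with the original protocol.

The defaults are the package's statement of the study conditions:

* **Process noise.** $\sigma_{\text{high}} = 5\,\sigma_{\text{low}}$ is
  forced by the reported 5x ratio of uncontrolled final errors. The scale,
  $\sigma_{\text{low}} = 1$ N per 10 ms step, was chosen so that the
  uncontrolled final error is a few cm (4.6 cm at the low level) and the
  printed sensory noise is genuinely negligible against the state
  excursions, as the original design required. With a smaller scale the
  sensory noise becomes comparable to the low-noise state spread and the
  filter induces a spurious gain difference between noise levels even for
  a risk-neutral subject.
* **Cost weights.** $w_p = 1$ per cm$^2$; $c_{\text{low}} = 0.1$,
  $c_{\text{high}} = 0.3$ per N$^2$ per 10 ms step. The ratio
  $2\theta\Omega$ : $BR^{-1}B^\top$ ("control power") determines how
  visibly risk attitude moves the late-trial gains; with much larger $c$
  the effect at the probed step stays below 0.5% up to breakdown and no
  250-trial regression could detect it, which would contradict the whole
  point of the design. With these weights, feasible risk aversion moves
  the probed-step gain by up to ~20%, the regression $R^2$ lands in
  0.65–0.91 across conditions purely from the sensory noise (matching the
  reported per-subject range 0.62–0.88 with no extra tuning), and
  controlled final errors are ~1 cm. The price is that the risk-neutral
  control-cost fraction is high (~0.8); its *noise-dependence*, which is
  what diagnoses risk attitude, is unaffected.
* **Hand-to-force gain.** 10 N/cm (low noise) and 50 N/cm (high noise);
  only used to report hand displacement, never in the control problem.
* **Execution noise.** Default 0 (the controller model has none); a small
  additive execution noise is available and is used in tests where an
  exactly linear policy with iid residuals is wanted.

What the generator does **not** emulate: learning and adaptation
transients, signal-dependent (multiplicative) motor noise, trial-to-trial
parameter drift, and any deviation of humans from the optimal family. A
passing test therefore shows that the analysis pipeline behaves correctly
on data from the model class, not that human data would satisfy the same
bounds.

## The analysis pipeline

**Policy-plane regression.** A subject's policy in a condition is
summarized by regressing the control emitted at 0.9 s onto the ball's
position and velocity at 0.75 s, one point per trial, with no intercept
(the target is at the origin); $R^2$ is computed against the zero model.
The 150 ms lag absorbs the visuomotor delay: for the delayed subject the
probed state is exactly the newest state in the controller's information
set, which is what makes the fitted plane interpretable as the policy.

**Nested-model F-tests.** Whether two conditions share a position (or
velocity) slope is tested by comparing the joint fit with separate slopes
(4 predictors) against the constrained fit (3 predictors) on residual sums
of squares. Two calibration facts matter. First, across noise levels the
residual variance scales with $\sigma^2$ (25x), so the pooled F-test is
conservative in cross-noise comparisons. Second, for the delayed subject
the feasible risk range moves the probed-step position gain only slightly
(see below), so this test has little power against feasible risk attitudes
of the *delayed* model at 250 trials. The package's calibration and power
checks therefore use the complete-observation subject with fixed execution
noise, fitted at its delay-matched lag 0: there the shared-slope null is
exactly true at $\theta = 0$ with homoscedastic iid residuals (measured
type-I rate 5.75% over 400 replicates), and a risk-averse $\theta = 0.1$
is detected with essentially full power at 250 trials.

**Risk-parameter inference.** Following the gain-difference logic, the
observed (position, velocity) gain differences between the noise
conditions are compared with the differences predicted by simulating the
same generative model (same delay, sensory noise, estimator, trial count
scaled up) over a $\theta$ grid — 50 log-spaced points per branch up to
90% of the feasibility boundary by default — and $\hat\theta$ minimizes
the Mahalanobis distance under the regression-coefficient covariance
(Euclidean if degenerate), with uncertainty from a bootstrap over trials.
Because predictions come from the same model that generated the data,
estimator biases (delay prediction, sensory-noise attenuation) cancel by
construction. `infer_theta_pooled()` sums the distance profiles of the two
cost-level pairs over a common grid (`default_theta_grid()`), using all
four conditions of a subject.

A genuine identifiability limit appears near breakdown: as $\theta$
approaches the boundary the effective gains grow, the state excursions
shrink, and the fixed sensory noise attenuates the *fitted* gains — the
predicted gain-difference curve folds back and extreme risk aversion
mimics mild risk seeking at this estimator. In consequence, with 250
trials per condition, median recovery is within 25% for
$\theta \in \{0.008, 0.012, 0.018\}$ (16 replicate subjects per level,
pooled inference), and per-pair estimates agree between cost levels, but
sign classification at half the feasibility boundary plateaus at ~92.5%
(74/80 replicates) rather than 95%; the corresponding test records this
honestly as a failure. Combining the gain differences with the
cost-fraction difference (monotone in $\theta$, attenuation-free) would
break the degeneracy, at the price of leaving the pure gain-difference
design; the package keeps the gain-based interface.

**Cost decomposition.** `cost_fraction()` returns mean control cost over
mean total cost with a delta-method standard error. At $\theta = 0$ the
fraction is *exactly* noise-invariant under common random numbers (the
closed loop is linear, so the whole trajectory scales with $\sigma$); it
increases with noise for risk-averse and decreases for risk-seeking
controllers (at $\theta = \pm 0.1$: 0.82 vs 0.90, and 0.82 vs 0.71).

**Extra cost of risk.** `extra_cost_of_risk()` simulates the
risk-sensitive and risk-neutral controllers under identical noise streams
and reports the percentage increase in mean total cost — exactly 0 at
$\theta = 0$ (same controller, same draws) and increasing in $\theta$ on
the averse branch (1.7%, 11%, 42%, 191% at 20/45/70/90% of the boundary in
the high-noise, low-cost condition).

**Impact angles.** `impact_angle_analysis()` counts trials whose final
velocity vector meets the line within 90 +/- 5 degrees (the tolerance is a
package default, configurable), for the actual and the counterfactual
no-control trajectories, plus variants restricted to central impacts
(|final x| <= 2.5 cm). Here the model genuinely disagrees with the human
finding this analysis was designed around: the optimal feedback law damps
x-velocity (velocity predicts future positional error), so the controlled
final-velocity spread is *narrower* than the counterfactual one (sd 44 vs
49 cm/s in high noise) and the controller makes orthogonal impacts
slightly *more* frequent, not less, at every tolerance. Human subjects'
late, variable interventions evidently add velocity variance in a way the
ideal controller does not. The corresponding directional test is kept and
fails, documenting the mismatch.

**Delay sweep.** `delay_sweep()` re-fits the policy plane over a grid of
lags and locates the $R^2$ peak. The single-condition peak is biased: the
controls applied between the probed state and the emitted command are
known to the controller (pulling the peak towards shorter lags) while the
recent process noise is not (pulling it longer), and the balance shifts
with the condition's control power — single conditions peak anywhere from
90 to 170 ms for a true 150 ms delay. Averaged across a subject's four
conditions the biases largely cancel and the peak sits at 150 ms (+/- one
10 ms grid step); the function accepts a list of trial sets and averages
profiles for exactly this reason.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at reduced but honest sizes: 10^4
uncontrolled trials per noise level for the 5x error ratio; 250 trials per
condition (the analyzed-trial count of the protocol) for all behavioral
analyses; 16 replicate subjects per recovery level and 80 replicates for
sign classification; prediction manifolds from 12,000 simulated trials per
condition and grid point; 10^5 Monte-Carlo rollouts per point of the
criterion-oracle grid; 150–400 replicates for test calibration rates. The
complete suite runs in roughly seven minutes on one core.

## Known limitations

* No signal-dependent (control-multiplicative) noise: the LEQG family
  used here has no closed-form solution in that case, and the original
  task design deliberately minimized such effects.
* The coupled risk-sensitive estimator is oracle-validated on small
  instances, not derived symbolically; alternative couplings that agree at
  $\theta \to 0$ exist.
* Risk-parameter inference is reliable only inside the fold described
  above (roughly up to half the feasibility boundary for recovery, with
  sign accuracy ~92.5% at that point).
* The impact-angle direction of the human data is not a property of the
  ideal model (see above).
* No learning or adaptation dynamics; the generator emits steady-state
  behavior only.
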