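---
title: "Identifying the cost of time behind reaching vigour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying the cost of time behind reaching vigour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotreach)
```

## The scientific question

People choose how fast to move even when nobody asks them to hurry, and the
choice is strikingly idiosyncratic: in a simple horizontal arm-pointing
task, some individuals are several times more *vigorous* — faster for a
given movement amplitude — than others. `cotreach` implements a
model-based account of these choices. Movement durations are assumed to
arise from a trade-off between a biomechanical **effort cost** $L(T)$,
which decreases with movement time, and a **cost of time** (CoT) $G(T)$,
which grows with it: the planned duration minimizes $L(T) + G(T)$. The
package provides the forward model (predicting durations and velocity
profiles from a CoT), the inverse model (identifying an individual's CoT
from their amplitude–duration behaviour), the surrounding measurement
pipeline (filtering, segmentation, vigour scoring, variance decomposition,
trait regressions), and a synthetic-cohort generator so that every stage
can be validated end to end without access to raw recordings.

## The plant and the effort cost

The arm is a single rigid segment rotating about the shoulder in the
horizontal plane:

$$\tau = I\ddot\theta + b\dot\theta,$$

with $\theta$ the shoulder angle (radians internally; degrees only at I/O
boundaries), $I$ the moment of inertia about the shoulder (kg·m²) and $b$
a viscous friction coefficient (default 0.8 N·m·s/rad, exposed over
$[0,1]$). Inertia is estimated per participant from anthropometric-table
coefficients for the whole upper limb as one segment: mass fraction 0.050
of body mass and radius of gyration 0.645 of segment length about the
proximal joint, so $I = 0.050\,M\,(0.645\,L)^2$. Both coefficients are
arguments of `estimate_inertia()`, so a segment-wise summation can be
swapped in; the single-segment choice matches the task (fully extended
arm) and keeps the mapping monotone in body size. Gravity and muscle
dynamics are deliberately out of scope: the task is horizontal and the
theory operates at the level of planned kinematics.

The control variable is the angle jerk $u = \dddot\theta$, and the default
effort cost is the integral of squared torque with a small jerk
regularizer,

$$L(T) = \int_0^T \tau^2 + \varepsilon u^2 \, dt,$$

with $\varepsilon = 0.005$ by default (configurable over
$[10^{-4}, 10^{-1}]$). Squared torque alone under-predicts peak
velocities; the jerk term restores bell-shaped profiles, and the
peak-to-mean velocity ratio moves monotonically from the
minimum-acceleration-like regime (~1.5) to the minimum-jerk value (1.875)
as $\varepsilon$ grows — a property the test suite checks. Two variants
are provided for robustness analyses: squared torque change
($\int \dot\tau^2 dt$, no free parameter) and pure squared jerk (an
inertia-independent, "subjective" effort measure).

With state $x = (\theta, \dot\theta, \ddot\theta)^\top$ the plant is a
chain of integrators $\dot x = Ax + Bu$ and every effort variant is a
quadratic form $\int u R u + x^\top Q x + 2 x^\top S u\, dt$; for the
torque+jerk cost $Q$ has rows $(0,0,0)$, $(0, b^2, Ib)$, $(0, Ib, I^2)$
and $R = \varepsilon$. The torque-change variant carries a state–control
cross term $S = (0, 0, Ib)^\top$.

## Solving the fixed-time problem exactly

The rest-to-rest fixed-time problem (boundary conditions
$x(0) = 0$, $x(T) = (\text{amplitude}, 0, 0)$) is linear-quadratic, and
its Pontryagin extremal satisfies a constant-coefficient linear ODE in
$\theta$ alone:

$$R\,\theta^{(6)} - Q_{33}\,\theta^{(4)} + Q_{22}\,\theta^{(2)} = 0,$$

which covers all three effort variants (the cross terms drop out of the
stationarity condition). The optimal angle therefore lies in a
six-dimensional exponential-polynomial space spanned by the roots of the
characteristic polynomial. `solve_fixed_time()` builds that basis
explicitly, anchoring growing exponentials at the final time so every
basis function is bounded on $[0, T]$, and solves the $6\times 6$ boundary
system directly. This is exact (no shooting, no collocation error) and
remains well-conditioned for stiff cost ratios where a matrix-exponential
shooting map loses all precision: with $\varepsilon = 0.005$ the
Hamiltonian boundary map's condition number reaches $10^{12}$ at
$T = 2.5$ s, while the anchored basis stays near unit condition. The
solver refuses durations below 10 ms and reports a conditioning error
rather than returning garbage if the boundary system degenerates.

Costates come from the same closed form, giving two quantities the
package leans on:

* the minimal effort $L^*(T) = -\tfrac12 p_1 \cdot \text{amplitude}$
  (with $p_1$ the constant first costate), cross-checked in the tests
  against Simpson quadrature of the running cost on a 501-point grid;
* the **maximized Hamiltonian**, constant along the extremal, which
  equals $-\,dL^*/dT$. This is exactly the infinitesimal time cost
  $g(T)$ that the inverse procedure samples. The tests verify the
  Hamiltonian against central finite differences of $L^*$ to better than
  $10^{-4}$ relative error across all effort modes, amplitudes 5–95° and
  durations 0.4–2.5 s, and against the pure-jerk closed forms
  $L^* = 720 A^2/T^5$, $g = 3600 A^2/T^6$ to machine precision.

`solve_free_time()` minimizes $L^*(T) + G(T)$ over a bracket (default
0.2–5 s) by scanning 60 log-spaced candidates and refining the best
bracket with `optimize()` to $10^{-4}$ s. A minimum at a bracket edge is
reported with a warning: it means the chosen cost of time is too weak to
produce an interior time/effort trade-off, not that the solver failed.

## The inverse procedure

Because $g(T)$ equals the maximized Hamiltonian of the fixed-time
problem, each observed movement of amplitude $A$ and duration $T$ yields
one sample of the participant's time-cost density. Durations are first
smoothed by the affine amplitude–duration fit $T = aA + b$ (vigour is
defined as $1/a$, in deg/s), then `sample_cot()` evaluates $g$ along the
fitted line — by default on 40 amplitudes spanning 5–95°. The integrated
CoT is modeled as a three-parameter sigmoid

$$G(T) = \alpha - \frac{\alpha}{1 + (T/\delta)^\beta},$$

with asymptote $\alpha$, relative steepness $\beta$ and inflection time
$\delta$ ($G(\delta) = \alpha/2$); an asymmetric variant raises the
denominator to the outer power 0.1. Since the data are samples of $g$,
`fit_sigmoid()` fits the analytic density (the derivative of $G$) by
Levenberg–Marquardt with a deterministic multi-start: $\delta_0$ at the
median sampled duration, $\beta_0 \in \{2, 5, 8\}$, $\alpha_0$ from the
peak heuristic $\max(g)\cdot 4\delta_0/\beta_0$, and box bounds
$\alpha \in (0, 10^6]$, $\beta \in (0.5, 30]$, $\delta \in (0.05, 10]$ s
that bracket every plausible value. $\alpha$ is optimized on the log
scale (it spans orders of magnitude across individuals), and 95%
confidence intervals are asymptotic, from the Jacobian at the optimum.
Downstream analyses always use $\log\alpha$.

Two caveats are worth stating plainly. First, the effort cost is defined
up to a positive factor $\lambda$: scaling the effort integrand scales
every $g$ sample and hence the identified $G$ by $\lambda$ while leaving
all behavioural predictions unchanged. Absolute $\alpha$ values are
therefore only meaningful relative to the package's SI effort convention
(N·m, rad, s). Second, $\alpha$ is an extrapolated asymptote: a
multiplicative shift of the whole duration line (exactly what
session-level variability does) rescales the sampled $g$ curve roughly
like the shift to the $-3$rd power, and no estimator can undo a pure
scale change of its data. The shape parameters $\beta$ and $\delta$ are
noise-stable; $\alpha$ is not, and the package's validation quantifies
this rather than hiding it.

## Measurement pipeline

Recordings are long-format shoulder-angle time series at 250 Hz.
`lowpass_filter()` applies a fifth-order Butterworth at 10 Hz forward and
backward (zero phase); the signal is detrended to its endpoint chord and
odd-reflection padded first, because a plain forward–backward pass leaves
zero-state transients at both ends that differentiate into large spurious
velocity spikes. Velocity is obtained by central differences.
`fit_movement()` then fits the three-parameter minimum-jerk velocity
template (scale $a$, onset $t_0$, offset $t_f$; this parameterization
integrates to $-a$, so $a$ is signed) by least squares, using 16
deterministic Nelder–Mead starts on a grid of $(t_0, t_f)$ candidates
seeded from the velocity support. Trials with peak speed below 0.05 rad/s
are flagged `no_movement`; fits with $R^2$ below 0.5 are flagged
`poor_fit` and excluded downstream. Duration is $t_f - t_0$; amplitude is
the angle change between the fitted endpoints.

Vigour is scored per block (20 trials), per session and per participant
(pooled), always regressing duration on the *stimulus* amplitude (the
measured excursion is kept for quality control). The three-level variance
decomposition of block-level relative vigour uses the empty
random-intercept model $y_{ijk} = \beta_0 + u_k + v_{jk} + e_{ijk}$
fitted by REML (`lme4::lmer`), reporting each level's share of the total
variance with parametric-bootstrap confidence intervals (simulate from
the fitted model, refit; 200 draws by default in the pipeline).
Participants observed in a single session still inform the individual and
block variances — the likelihood handles the unbalanced design naturally
— and a fully single-session cohort fixes the session variance at zero
with a warning. Trait analyses are simple one-predictor OLS regressions
(traits × {relative vigour, $\log\alpha$, $\beta$}), with no
multiple-testing correction, matching how such analyses are conventionally
reported for this design.

## What the synthetic cohort emulates

`generate_cohort()` and `simulate_session()` produce data with the
statistical structure the analysis assumes:

* **Design**: 38 participants by default; 21 with one session, 2/7/1/7
  with 2/3/4/5 sessions; 5 blocks of 20 trials per session; two trials
  (one leftward, one rightward) for each of the ten amplitudes 5–95° in
  randomized order; inter-stimulus intervals growing linearly from 3.6 s
  at 5° to 4.2 s at 95°; sampling at 250 Hz.
* **Anthropometry and traits**: truncated-normal body mass
  (68.7 ± 12.7 kg) and arm length (0.721 ± 0.048 m); boredom proneness
  and impulsivity jointly normal with correlation 0.55, mapped to
  questionnaire-plausible ranges.
* **Behaviour**: each participant draws an affine amplitude–duration
  relationship — log-normal slope (median 0.0075 s/deg, log-SD 0.45),
  normal intercept (0.63 ± 0.15 s), slope–intercept correlation 0.81 —
  and boredom loads on the vigour latent.
* **Ground-truth CoT**: identified from that behaviour by the package's
  own exact inverse procedure, over an amplitude grid extended to 125°.
  The extension matters: the sigmoid's tail is lighter than the time-cost
  density implied by an affine line continued to ever-larger amplitudes,
  and fitting only up to 95° leaves the interior free-time minimum at the
  top amplitude on a knife edge. Identifying over the extended grid
  pushes that knife edge outside the stimulus range, so the forward model
  reproduces each participant's target line (slopes to a few percent)
  with interior optima everywhere. A consequence worth knowing: the
  co-variations among $\log\alpha$, $\beta$, $\delta$ and inertia are
  *emergent* — vigorous participants come out with larger $\alpha$ and
  $\beta$ and smaller $\delta$, and $\alpha$ scales with inertia because
  the effort cost does — rather than being imposed as a covariance
  matrix.
* **Noise**: durations are perturbed by multiplicative log-normal factors
  at the session (SD 0.17), block (SD 0.20) and trial (SD 0.06) levels;
  the trajectory is re-solved at the perturbed duration, so noisy trials
  remain dynamically consistent. Because vigour is a reciprocal slope,
  log-vigour inherits the level variances directly;
  `calibrate_duration_noise()` maps a desired block/session/participant
  variance split (default 17/11/72) to session and block SDs given the
  participant-level spread the behaviour distribution produces, and the
  defaults were set with it. Measurement noise is additive on the angle
  (SD 0.002 rad) and movement onset follows a truncated-normal reaction
  latency (0.30 ± 0.04 s).

What the generator does **not** emulate: marker-level 3D data and
reconstruction error, fatigue or familiarization drift, asymmetries
between leftward and rightward movements, endpoint corrections and
submovements, and any trial-to-trial dependence beyond the three
exchangeable noise levels. Passing recovery tests on this generator
therefore validates the estimators under the model's own assumptions —
correct filtering and segmentation, unbiased variance decomposition,
identifiable CoT parameters — not the adequacy of those assumptions for
any particular laboratory's recordings.

## Numerical choices and degenerate inputs

* Quadrature: composite Simpson on 501 uniform samples per movement
  (cross-check only; effort itself is closed-form).
* Free-time search: bracket $[0.2, 5]$ s, 60 log-spaced candidates,
  refinement tolerance $10^{-4}$ s; edge minima warn and flag.
* Sigmoid fitting: three $\beta$ starts; non-convergence from every start
  raises an error; all-zero or constant $g$ samples return an
  `unidentifiable` flag instead of a fit.
* Segmentation: template support constrained to at least four samples;
  ties between multi-start optima resolved by lowest SSE, then a final
  polish from the best start.
* Zero amplitude short-circuits to the zero trajectory with zero cost.
* Empty-model HLM: singular fits (legitimate when a level's variance is
  truly zero) are accepted, not errors.

The test suite runs the full validation at reduced problem sizes chosen
to keep each block in seconds-to-a-minute territory: 20 synthetic
participants for CoT recovery, 200 replicates of the 425-observation
repeated-measures design for the variance decomposition, 60 Monte-Carlo
draws for the sigmoid CI calibration, and 3-participant cohorts for the
pipeline determinism checks. The acceptance script recomputes the
velocity-shape calibration (ten fixed-time solves) in under a second.

## Known limitations

* The absolute scale of $\alpha$ (and $G$) is convention-bound via the
  $\lambda$ degeneracy, and $\alpha$ is additionally the least
  noise-stable parameter by a wide margin; conclusions should rest on
  $\beta$ and $\delta$, as the trait analyses here do.
* Under the package's SI conventions and single-segment inertia, the
  peak-to-mean velocity ratio at $\varepsilon = 0.005$ is ≈1.73 for
  cohort-mean parameters; values near 1.87 require either a larger
  $\varepsilon$ (~0.1) or a substantially smaller effective inertia
  (~0.2 kg·m², e.g. a radius of gyration about the segment's center of
  mass instead of the proximal joint). The acceptance machinery reports
  the computed value; users calibrating against their own recordings
  should treat $\varepsilon$ and the inertia coefficients as the knobs
  they are.
* The segmentation assumes one movement per inter-stimulus window; it
  will happily fit the largest submovement of a corrective sequence.
* The CoT is identified per participant from pooled sessions; it cannot
  separate slow drifts of vigour within a participant from measurement
  noise.
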