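---
title: "Goal functions for in-place motor tasks: models, calibration, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal functions for in-place motor tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalfun)
```

## The model

A goal function makes a virtual motor task analyzable by linking movement
to outcome explicitly: a scalar performance error

$$e = f(\vec{u}, \vec{p}) = V\big(S(\vec{u}) + \vec{x}_{e1},\ \vec{p}\big)$$

where $\vec{u}$ are the *execution variables* — the few movement
quantities at the moment of execution that fully determine the trial
outcome — $S$ is the *execution mapping* from $\vec{u}$ and the
pre-execution virtual-object state $\vec{x}_{e1}$ to the post-execution
state, and $V$ applies the virtual physics and target geometry in
$\vec{p}$ to produce the error. Because tasks are redundant, the
zero-error set (the *solution manifold*) is typically a curve or surface
rather than a point, and a block of trials forms a cloud in execution
space whose location, spread, and internal covariation each carry a
distinct performance cost.

The package's assumptions, shared by all three tasks:

* the execution variables captured at the execution instant fully
  determine the outcome (no post-hoc physics depends on the rest of the
  movement);
* virtual physics are deterministic and closed-form (ballistic flight
  under gravity; small-angle point-mass pendulum);
* a trial whose virtual object cannot reach the target plane (or whose
  pendulum would pass inversion) is a *gross miss*, represented by an
  infinite-error sentinel and handled by the filtering and
  cost-decomposition layers, never silently dropped.

Conventions: right-handed frame, $+y$ up, $-z$ forward (away from the
subject), $+x$ toward the dominant side, origin at the mid-stance ground
point. SI units internally (m, m/s, rad); degrees appear only in
configuration files and in the punching-bag error, which is reported in
degrees because swing error is an orientation mismatch.

## Task physics

**Bow-and-arrow (BA).** Execution variables: lateral chest excursion
normalized by the baseline lateral chest limit, and bowstring draw
normalized by upper limb length. The bow yaw angle is linear in chest
excursion, $\theta_{bow} = (x_{chest}/x_{max})\,\theta_{bow,max}$ with
$\theta_{bow,max} = 15^\circ$, clamped to $[0, \theta_{bow,max}]$ —
the clamp covers over-leaning beyond the baseline maximum, where a
physical bow mount would hit its stop; it is switchable
(`ba_bow_angle(clamp =)`) since the linear form alone says nothing about
that region. The arrow leaves the bow centre with ground-plane speed
$k\,d_{pull}$ along the bow direction; flight time to the target plane
(perpendicular to the optimal arrow path) is
$t = d_{target} / (\lVert v\rVert \cos(\theta^{*} - \theta_{bow}))$,
the in-plane lateral offset is $d_{target}\tan(\theta^{*}-\theta_{bow})$,
and the vertical offset is the gravity drop relative to the bullseye
height. Radial error includes both components by default; the vertical
term can be excluded (`include_drop = FALSE`) since a ground-plane-only
reading of the geometry is also defensible.

**Reach-and-strike (RS).** The ball velocity is $k$ times the hand
velocity at impact. With forward $= -z$, the flight time to the vertical
target plane is $t = 4.0 / (-v_z)$; error is the planar distance from
the bullseye 1.0 m above the launch height. Strikes with $v_z \ge 0$ are
gross misses.

**Punching bag (PB).** A hit at height $d$ with ground-plane speed
$\lVert v \rVert$ gives the bag angular speed
$\omega = k\,d\,\lVert v\rVert$ and a swing azimuth along the hand
velocity. The peak amplitude follows from the mass-free energy balance
$\tfrac{1}{2}L^2\omega^2 = gL(1-\cos\theta_{max})$; energy beyond
inversion is a gross miss. The small-angle time course
$\theta(t) = \theta_{max}\cos(\omega_n t + \phi)$ uses the natural
frequency $\omega_n = \sqrt{g/L}$ — note this reuses the symbol
$\omega$ in the source material for two different quantities (initial
angular speed vs oscillation frequency); the package keeps them as
separate arguments. The scalar error is the axis-angle magnitude of the
relative rotation between the desired and observed peak orientations,
each built as a twist-free tilt of the hanging bag; the magnitude is
evaluated in the `atan2` quaternion form because the `acos` form loses
half the significant digits near zero error (it turns machine epsilon
into ~1e-6 degrees, which matters for certifying that optimal executions
have zero error).

*Azimuth convention.* Swing azimuth is measured from straight forward,
positive toward the dominant side. The PB strike crosses the body from
the non-dominant side, so the dominant-lateral hand-velocity direction is
negative $x$ for this task: azimuth $= \mathrm{atan2}(-v_x, -v_z)$. This
is the convention under which the default search grid's all-negative
velocity region maps to azimuths of 0–90° toward the dominant side and
the desired swing direction is $30^\circ$. The raw quadrant-correct
$\mathrm{atan2}(v_z, v_x)$ is also returned by `pb_execution_mapping()`
(a two-argument arctangent is used because the one-argument form is
singular at $v_x = 0$).

## Calibration of the shipped constants

Several scaling constants and geometric quantities are free parameters
of the design rather than measured quantities. They are required
configuration with shipped defaults fixed by a deterministic calibration
rule: *the documented optimal execution must map to exactly zero error,
and optimal executions must sit inside the default search grids.*

| constant | default | role of the calibration |
|---|---|---|
| $k_{BA}$ | 20 m/s per unit draw | draw of 0.65 gives 13 m/s, so flight times are short and the draw grid `[0, 1.5]` spans both gross and accurate shots |
| $d_{target}$ (BA) | 10 m | bow-to-bullseye distance |
| $r_t$ (BA) | 0.5 m | target radius for filters/adjustment |
| bullseye height (BA) | launch height $-\ \tfrac{1}{2}g t_{opt}^2$ | places the bullseye at the drop of the calibrated optimal shot, so the optimum is an exact zero while gravity still acts on every arrow |
| $\theta^{*}$ (BA) | condition fraction $\times\ 15^\circ$ | leaning to the condition's excursion (65/80/95 % of baseline) aims the bow exactly at the bullseye |
| $k_{RS}$ | 1 (dimensionless) | a forward strike of 6 m/s solves the two-point ballistic problem with $u = (0, 4.7705, -6)$, inside the default grid |
| $k_{PB}$ | 0.1 m$^{-1}$ | desired angular speed reached at mid-bag hits with ~3 m/s strikes, inside the default grid |
| $\theta_{max,des}$ (PB) | 20° | desired swing amplitude (the desired-bag display in the source design does not pin it down) |
| $\phi_{des}$ (PB) | 30° toward dominant | desired swing azimuth |
| $r_t$ (PB) | 10° | angular target radius |

The calibration is implemented in the environment constructors
(`ba_environment()` etc.), not hard-coded into the error functions, so
alternative geometries remain first-class.

## TNC-cost numerics

Each cost is *observed mean error minus optimized-set mean error*, the
optimized set being the best of a family of candidate manipulations of
the observed block:

* **T-cost** shifts the centroid to every lattice point of a per-task
  search grid without changing the distribution about the centroid. The
  default grids are, per execution variable as (start, step, stop): BA
  chest `[0, 0.0033, 1.2]`, draw `[0, 0.01, 1.5]`; RS `vx`
  `[-2, 0.02, 2]`, `vy` `[-1, 0.1, 7]`, `vz` `[-11.5, 0.0656, -1]`; PB
  `vx` `[0, -0.0296, -5]`, `vz` `[0, -0.08, -8]`, `d`
  `[2.875, 0.0056, 3.458]`. The RS grid has ~2.6 M lattice points, so
  the default mode coarsens each axis by 8, finds the coarse argmin, and
  rescans the full resolution in the surrounding window; `mode =
  "exact"` scans everything and the two are verified to agree on small
  grids. T-cost can be marginally negative (bounded by the grid
  resolution) when the observed centroid is off-lattice.
* **N-cost** enumerates shrink factors 1.00, 0.99, …, 0.00 applied to
  the deviations about the centroid (ties resolve to the largest
  factor). Shrink is restricted to $[0, 1]$ — "shortening" only, no
  expansion. Per-variable N-costs shrink one column's deviations only.
* **C-cost** is a greedy hill-climb over pairings: in each batch every
  pair of trials is examined in index order, candidate swaps exchange
  their second-variable values and then (three-variable tasks) their
  third-variable values, and a swap is accepted iff the set's mean error
  strictly decreases; termination when a batch accepts nothing. Fixed
  iteration order makes the result deterministic; a seeded randomized
  order is available (`randomize = TRUE`). Column marginals are
  preserved exactly. The batch semantics pair variables independently
  (v2 swaps, then v3 swaps) rather than jointly swapping (v2, v3)
  blocks; on small two-variable instances the greedy optimum matches the
  exhaustive $n!$ pairing optimum on well over 90 % of random blocks.

Gross-miss trials are excluded from all TNC computations and counted in
the diagnostics — a single infinite error would otherwise poison every
candidate mean.

## The three adjustment steps

**Step 1, velocity scaling.** The smallest scalar $k_v \ge 1$ bringing
the scaled centroid of the velocity-based execution variables into the
operating region. $k_v$ is a scalar (uniform velocity scaling preserves
the direction structure of the strike); a per-axis vector can be passed
to `scale_velocities()` directly if needed. The operating-region bound
is a *named vector over the bound axes only*, each with a sign
orientation: a forward-strike bound of $-11$ m/s means "at least as
negative as". A literal elementwise inequality over all axes with a zero
lateral bound would be unsatisfiable for any block whose mean lateral
velocity is negative — which typical strike data are — so unbound axes
are simply not constrained. The floor $k_v \ge 1$ means adjustment never
slows a subject down.

**Step 2, target resizing.** Centroid bias is first removed with the
T-cost optimization; the N-cost of the T-adjusted set then measures the
error floor attributable to motor noise alone (assuming bias is
trainable), and the radius is the smallest
$r_t \ge r_{t,baseline}$ with $N / r_t < e_{max}$. Two readings
resolved here: $e_{max}$ is treated as *dimensionless* (error normalized
by target radius) because both constraint inequalities divide by $r_t$;
and $N$ is *not* recomputed per candidate radius because the task error
metrics are radius-independent distances/angles — under that property
the answer is the algebraic $N/e_{max}$, nudged up to satisfy the strict
inequality.

**Step 3, visual error modification.** Each execution is decomposed
into its nearest solution-manifold point $u^{*}$ and fluctuation
$d = u - u^{*}$, and the displayed execution is
$u_r = u^{*} + c \odot d$. For $c \in [0,1]^m$ the fluctuation norm
never grows. The modification vector is selected by a largest-first grid
search over $c \in \{1.00, 0.95, \ldots, 0\}$ under a policy: uniform
(all components), single-axis (one component, the rest 1 — this can be
*infeasible* when the unaffected axes already contribute more normalized
error than $e_{max}$, and the selector then reports infeasibility rather
than raising), or magnitude-preserving.

*Magnitude-preserving variant.* The printed full-vector rescaling
$u_s = \lVert u\rVert\,(u^{*}+c\odot d)/\lVert u^{*}+c\odot d\rVert$
mixes units when position variables are present (PB mixes m/s and m) and
perturbs the hit height, which in simulation changes the swing amplitude
by ~0.2° — contradicting the variant's purpose of keeping swing height
fixed. The package therefore applies the norm constraint over the
*modified* components only (those with $c_j \ne 1$), passing the rest
through unchanged. This reduces to the full-vector form when every
component is modified, preserves $\lVert u_s\rVert = \lVert u\rVert$
exactly in all cases, and for PB with $c = (c_1, c_1, 1)$ preserves the
ground-plane speed and hit height — hence the angular speed and peak
swing amplitude — exactly, while strictly shrinking the
swing-direction error.

*Projection.* Task goal functions carry parameterized projections: the
BA manifold is the single point (optimal excursion, optimal draw); the
RS manifold is the 1-D curve $v_x = 0$, $v_y = v_y(v_z)$ solving the
two-point ballistic problem; the PB manifold is the 1-D curve of hits
along the bag whose speed yields the desired angular speed in the
desired direction. Each reduces projection to a 1-D minimization. A
generic multi-start penalized Nelder-Mead search seeded from a coarse
lattice (`method = "generic"`) covers arbitrary goal functions and is
cross-checked against the parameterized projections in the tests. The
projection metric is plain Euclidean in execution-variable units by
default; per-variable weights (e.g. `1/sd`) are accepted for mixed-unit
tasks, a choice the design leaves genuinely open.

*Sequencing.* Parameters are computed from one prior block: Step 2 uses
the Step-1-scaled executions, Step 3 uses the scaled executions and the
Step-2 radius. `apply_adjustment()` re-applies stored parameters
deterministically. Misfired trials carry no meaningful execution and are
excluded from all three computations.

## Metrics and filters

For target tasks, hits are 2-D coordinates in the target plane relative
to the bullseye. MRE is the mean hit distance (accuracy); BVE is the
root-mean-square distance of hits from their own centroid (consistency);
centroid bias is the distance from bullseye to hit centroid. For the
mean-of-norms MRE the decomposition $MRE^2 = bias^2 + BVE^2$ does *not*
hold; it holds exactly for the RMS radial error (`rmse_radial()`,
provided as an auxiliary), and the triangle bound
$MRE \le bias + BVE$ always holds. Execution-space centroid bias is the
observed centroid minus the T-cost argmin centroid, per variable.

The trial filters run in fixed order: gross errors above 15 × target
radius first (target tasks; sentinel trials always), then errors more
than 3 SD from the mean of the *stage-1 survivors*. Computing the
stage-2 reference statistics on stage-1 survivors (rather than on
whatever is currently unexcluded) makes the filter idempotent by
construction.

Trajectory windows are computed on the sampled grid with no
interpolation — tracker data is discrete and no interpolation rule is
part of the design — so window boundaries land on samples, and a strike
whose only on-target sample is the strike itself scores one sample
period. The pre-strike lateral-velocity summary reports both the signed
mean and the mean magnitude, since both readings of "average lateral
movement speed" are useful and the source material uses each in
different places.

## Synthetic data

`generate_block()` draws trials from a multivariate normal around a
strategy centroid, truncated to the physical domain (PB hit heights must
land on the bag), with misfires flagged at a configured rate. The model
emulates unstructured trial-to-trial variability about a single motor
strategy; it deliberately does **not** model serial correlation across
trials, fatigue or attention drift, biomechanical coupling between
execution variables beyond the supplied covariance, or multimodal
strategy switching — so tests passing on synthetic blocks demonstrate
the *algorithms*, not claims about real movement data.
`generate_learning_series()` adds practice structure: geometric decay of
the centroid's offset from a drift target (bias reduction) and of the
noise SD (TTV reduction), which gives parameter-recovery ground truth
(T-cost falls with bias decay, N-cost with noise decay).
`generate_trajectory()` builds a pre-strike hand trajectory as a
sub-threshold bell-shaped wind-up (peak 15 % of strike speed, below the
20 % movement-window threshold) followed by a strike plateau with a
linearly decaying lateral drift; keeping the wind-up below threshold
makes the >20 %-speed window exactly the plateau, so the movement-window
metrics have closed-form ground truth and the terminal sample equals the
strike velocity exactly.

Reproducibility: Mersenne-Twister, seeded per call from the spec seed
plus a block-index offset, so identical seeds give identical blocks on
any platform.

## Problem sizes and determinism in the shipped tests

The test suite exercises blocks of 8–60 trials (matching the 25–30
trials per condition a practice block yields), 100-shot oracle
comparisons per ballistic task against a fixed-step (1e-4 s) RK4
integrator with bisection onto the target plane, exhaustive $n!$
covariation oracles at $n \le 6$, 100-seed parameter-recovery
simulations, and 50-block end-to-end adjustment runs on reduced exact
search grids. All stochastic tests fix their seeds; all optimizations
use fixed iteration orders, so the suite is deterministic.

## Known limitations

* The ballistic tasks ignore drag and spin; the pendulum is a point mass
  with a small-angle time course (the *peak amplitude* uses the exact
  energy balance, but the displayed oscillation would be approximate for
  large swings).
* PB contact is encoded entirely by the hit-height variable; there is no
  3-D collision model (the execution variables already presuppose a
  hit).
* The C-cost hill-climb is a local search; on two-variable blocks it can
  rarely land a small gap above the exhaustive pairing optimum (the
  tests measure and bound this).
* T-cost resolution is bounded by the search grid; planted biases are
  recovered to within one grid step, not exactly.
* Statistical modeling of multi-subject practice data (mixed models,
  etc.) is out of scope; `block_metrics()` emits one flat row per block
  for export to a statistics environment.
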