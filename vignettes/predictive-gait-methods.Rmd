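---
title: "Methods: muscle-driven predictive simulation of walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-driven predictive simulation of walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

predgait generates *de novo* periodic walking motions for a muscle-driven
planar musculoskeletal model by solving a trajectory-optimization problem:
find muscle excitations and the gait-cycle duration that minimize an
effort/energy cost subject to musculoskeletal dynamics, half-cycle
left-right symmetry, and a prescribed average speed. This vignette
documents the model, the numerical formulation, the synthetic data that
stand in for experimental inputs, and the design decisions taken where the
problem statement was genuinely open.

## The musculoskeletal model

The model is a sagittal-plane rigid-body tree: a single head-arms-torso
(HAT) segment on a 3-DoF planar base (`pelvis_tx`, `pelvis_ty`,
`pelvis_tilt`), and per leg a thigh, shank, hindfoot and toe segment
connected by hinge joints (hip, knee, ankle, metatarsophalangeal). With
toes that is 11 generalized coordinates; the locked-toes variant replaces
the MTP hinges by welds at the neutral angle, giving 9. Segment masses
follow standard anthropometric fractions and sum to the subject-scale body
mass (62 kg at 1.70 m stature); lengths scale linearly with stature.

Nine Hill-type muscles per leg (glutei, iliopsoas, hamstrings, rectus
femoris, vasti, biceps femoris short head, gastrocnemius, soleus, tibialis
anterior) actuate hip, knee and ankle through via-point paths. The toe
joints carry **no muscles**: they are driven purely by a linear rotational
spring (25 Nm rad^-1^) and damper (2 Nm s rad^-1^) on top of the
exponential end-range torques present at every leg joint. Damping at the
muscle-driven joints is small (0.1 Nm s rad^-1^) because those joints
already receive damping through the muscle force-velocity property; the
passively driven toes need the larger value. The toe hinge axis is
perpendicular to the sagittal plane, which for a planar model is the only
choice and matches the axis orientation that worked best in the
three-dimensional setting this framework mirrors.

The exponential end-range coefficients are not published for this model
family, so the fixture uses an Anderson/Pandy-style form
`T = k1 exp(k2 (q_lo - q)) - k1 exp(k2 (q - q_hi))` with small `k1` (2 Nm)
and per-joint soft limits; they are stand-ins whose only load-bearing role
is to keep joints inside physiological ranges.

### Muscle-tendon mechanics

Fibers use smooth active force-length (sum of Gaussians), logarithmic
force-velocity and exponential passive-elasticity curves. The constants
live in one block (`predgait:::.hill_const`); the force-velocity offset
`d4` is computed at load so the isometric value is exactly 1. The tendon
force-length law is exponential:

    ltilde = log(5 (ftilde + 0.25 - s)) / k + 0.995

with dimensionless stiffness `k` (generic value 35). The shift `s` is
defined by the requirement that the normalized force at the slack length
(`ltilde = 1`) is independent of `k`; anchoring `s(35) = 0` gives the
closed form `s = 0.2 (exp(0.175) - exp(0.005 k))` implemented in
`tendon_shift()`. The tendon-stiffness study scales `k` for the triceps
surae only, recomputing `s` per condition.

Contraction dynamics are implicit: the normalized tendon force is a state,
its scaled time derivative a control, and the fiber-tendon force balance
(`hill_equilibrium()`) a path constraint, with a constant-thickness
pennation rule and a small normalized fiber damping (beta = 0.01) for
well-posedness. Activation dynamics are first-order bilinear
(tau_act = 15 ms, tau_deact = 60 ms) with a tanh blend (sharpness 40)
between the two time constants so the rate is differentiable.

Tendon slack lengths of the fixture are computed from the path geometry so
each fiber sits at its optimal length in a mid-gait posture; this keeps
all muscles on sensible portions of their characteristic curves for any
physiological joint excursion.

### Muscle geometry polynomials

Inside the optimal-control problem, muscle-tendon lengths are multivariate
polynomials in the spanned joint angles, fitted to exact via-point path
lengths *jointly* with moment-arm samples entered as derivative
observations. Moment arms are therefore minus the analytic polynomial
gradient by construction, and lengthening velocity follows by the chain
rule (`v_MT = -sum_j r_j qdot_j`) rather than a separate fit. Fits use a
tensor grid over the coordinate ranges with at least ten observations per
coefficient; the gastrocnemius fit reproduces the exact path to well under
1 mm.

### Contact

Foot-ground contact is a smooth Hunt-Crossley sphere-plane law: normal
force `k delta^(3/2) (1 + 1.5 c delta_dot)` with the penetration ramp
regularized by `smooth_pos` (eps = 1e-5 m) and the dissipation factor
clamped smoothly at zero, plus smoothed Coulomb friction
(mu = 0.8, viscous 0.5 s/m, transition velocity 0.1 m/s) opposing the
contact-point slip velocity. Each foot carries three spheres (heel and
metatarsal heads on the hindfoot, one on the toe segment); the 6-sphere
layout is reserved for 3D configurations. Sphere stiffness (4.5e5 N
m^-3/2) was chosen so that quiet standing penetrates less than 5 mm - the
static-equilibrium bound the synthetic fixture is validated against - and
sits at the soft end of that admissible range because softer contact
produced smoother, more human-like force transfer in the predicted gaits.

## The optimal-control problem

The cost is the distance-normalized integral of squared terms: whole-body
muscle metabolic rate, muscle activations, joint accelerations, passive
torques and (in models that have them) arm-actuator excitations, plus a
small penalty (weight 0.001) on the remaining controls to suppress
singular arcs. Metabolic rate is a smoothed phenomenological
(Bhargava-style) model: activation and maintenance heat with
fast/slow-twitch weighting, velocity-sign-dependent shortening/lengthening
heat, signed mechanical work, a smooth 1 W/kg total-heat floor, and every
conditional replaced by a tanh blend of sharpness b = 100; the unsmoothed
piecewise model is retained as an oracle and the two agree to better than
1% away from the switching surfaces.

The weight values (`ocp_config()` defaults) are not taken from any
publication - the source problem statement does not print them - and were
chosen once by the convention that each normalized term is O(1) on a
typical gait at the default speed; they are echoed into every result file.
Outcome *directions* across model variants are treated as weight-robust;
absolute cost-of-transport magnitudes are weight-sensitive and should be
read as fixture-scale numbers, not subject-scale predictions.

### Transcription

A half gait cycle is discretized with the 3-stage Radau IIA scheme
(collocation points (4-sqrt(6))/10, (4+sqrt(6))/10, 1; order 5, stiffly
accurate). States (coordinates, velocities, activations, tendon forces)
live at every mesh and collocation point; coordinate accelerations and
tendon-force derivatives are stage controls; excitations are piecewise
constant per mesh interval; the half-cycle duration is free within
[0.25, 0.8] s. Constraints are the collocation defects, the Hill
equilibrium and skeletal-dynamics residuals at every collocation point,
periodicity through the left-right mirror map (all states except the
forward pelvis translation), and the speed equality
`tx(tf) - tx(0) = v tf`. Skeletal dynamics are evaluated as an implicit
residual `M(q) u_a + bias - tau_applied` by a vectorized planar recursive
Newton-Euler pass, so no mass-matrix factorization appears inside the
NLP. All variables are affinely scaled to O(1) and the closed-form size
census is exposed as `transcription_census()`.

### Solving

No sparse interior-point NLP solver (the CasADi + IPOPT stack of the
Python ecosystem) exists in the supported R environment, so the package
carries its own solver (`predgait:::solve_alm`): Levenberg-Marquardt
feasibility restoration onto the dynamics manifold, then
augmented-Lagrangian outer iterations with projected damped-Newton inner
steps built from the objective's Gauss-Newton Hessian and the sparse
constraint Jacobian (Matrix package Cholesky factorizations), with a
restoration safeguard and a final polish that drives the scaled
constraint violation to ~1e-8. Constraint Jacobians exploit the pointwise
structure of the transcription: one vectorized evaluation per variable
"slot" yields a full Jacobian stripe via central differences, while the
defect, periodicity and speed rows are assembled analytically.

Two initial guesses are used, as in the source study: a **cold start**
(static standing posture translating forward at the target speed, muscle
states constant) and a **hot start** (reference joint-angle curves
resampled onto the collocation grid, with the pelvis height adjusted per
frame so the vertical contact force supports body weight). For fine
meshes the solver first solves a coarse mesh from the declared guess and
interpolates (mesh continuation); the initial guess is still the declared
cold/hot start, and the continuation is a solver implementation detail.
The multi-guess driver returns the lower-cost solution and keeps the
alternative's summary; ties prefer the cold start, deterministically.

Convergence semantics: `tol` controls the stationarity test of the inner
iterations and the outer progress test; `feas_tol` (1e-6) bounds the
scaled constraint violation, so periodicity and speed hold to ~1e-6 or
better in reported solutions.

## Synthetic data

No subject data ship with the package. `make_reference_gait()` emulates
the *shape* of averaged overground walking data at 1.33 m/s: periodic
spline templates for joint angles and torques (stance knee flexion bump,
double ankle rocker, late-stance toe extension), a two-Gaussian
double-hump vertical GRF rescaled so the per-foot cycle impulse equals
half the body-weight impulse, S-shaped fore-aft GRF, and
rectified-Gaussian EMG envelopes in normalized units (they exist to
exercise comparison/plotting paths and are never converted to forces).
Mean and SD come from averaging 10 cycles perturbed by smooth random
harmonics, mirroring "averaged over 10 gait cycles" datasets;
left signals are exact half-cycle shifts of right signals. Template
control points and SD scales are fixture constants, not claims about any
subject. What a green test against these data establishes is that the
pipeline runs end-to-end and reproduces *directional* findings; it cannot
establish subject-level quantitative agreement, which requires the real
3D model and data that are out of scope here.

## Desk-scale versus full-scale settings

The source study used 50-125 mesh intervals per half cycle and multi-hour
3D solves. The fixture defaults are desk-scale: 25 mesh intervals for the
headline solve and 8-12 for studies and convergence tables, each solve
minutes on one CPU. The mesh-refinement and tolerance-sensitivity
machinery (`convergence_study()`) is the same code that would run at
full scale.

## Known limitations

- The planar fixture cannot reproduce 3D outcomes (hip ab/adduction,
  arm swing); absolute COT values are fixture-scale.
- The predicted gaits show shorter double-support phases than human
  walking across the contact parameters explored; stance fractions
  hover near 0.5 rather than 0.6. We report this honestly rather than
  tuning for it; see the acceptance suite.
- Tendon-stiffness sweep directions: stride length increases as the
  triceps-surae tendon is softened, matching the three-dimensional
  finding this framework mirrors, but the fixture's cost of transport
  *decreases* with softening (tendon energy return dominates at planar
  scale) where the 3D study reports an increase. Lengthening the
  fixture's Achilles tendons toward more realistic slack-to-fiber
  ratios did not flip the direction; the corresponding acceptance check
  is left failing with this analysis rather than re-tuned.
- The cold start (translating standing posture) is preserved as
  specified, but the desk-scale solver cannot reach a feasible walking
  solution from it: feasibility restoration falls into an airborne
  pseudo-minimum, and the friction-homotopy stage (Coulomb coefficients
  ramped from zero) recovers stepping but not full convergence within
  the time budget. Cold/hot agreement is therefore not demonstrated at
  desk scale (the reference workflow itself reports cold/hot divergence
  at its coarsest mesh).
- The augmented-Lagrangian solver is a local method without inertia
  correction; different guesses may land in different local optima,
  which is also true of the interior-point reference workflow.
- Polynomial muscle geometry is only valid inside the fitted coordinate
  ranges; bounds keep the solver inside the fit domain.
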