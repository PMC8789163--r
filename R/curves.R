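## Hill-type muscle-tendon characteristic curves.
##
## The tendon force-length law is the exponential curve
##   ltilde = log(5 * (ftilde + 0.25 - s)) / k + 0.995,
## where k is the dimensionless tendon stiffness (generic value 35) and s is a
## shift chosen so that the force at the slack length (ltilde = 1) does not
## depend on k.  The active/passive force-length and force-velocity curves are
## the standard smooth (C-infinity) formulations used with this tendon law;
## their constants live in `.hill_const` so alternates can be swapped in one
## place.

.hill_const <- list(
  ## active force-length: sum of three Gaussians b1*exp(-0.5*(l-b2)^2/(b3+b4*l)^2)
  fl_b1 = c(0.814483478343008, 0.433004984392647, 0.100),
  fl_b2 = c(1.055033428970575, 0.716775413397760, 1.000),
  fl_b3 = c(0.162384573599574, -0.029947116970696, 0.353553390593274),
  fl_b4 = c(0.063303448465465, 0.200356847296188, 0.000),
  ## force-velocity: d1*log(d2*v + d3 + sqrt((d2*v + d3)^2 + 1)) + d4
  fv_d1 = -0.318323436899127,
  fv_d2 = -8.149156043475250,
  fv_d3 = -0.374121508647863,
  ## passive force-length: (exp(kpe*(l-1)/e0) - 1)/(exp(kpe) - 1)
  pfl_kpe = 4.0,
  pfl_e0 = 0.6,
  ## generic tendon stiffness and curve constants
  k_generic = 35,
  tendon_c1 = 0.2,
  tendon_c2 = 0.995,
  tendon_c3 = 0.25
)
## Anchor the isometric force-velocity value at exactly 1 (computed, not
## hard-coded, so the anchor survives any change to d1..d3).
.hill_const$fv_d4 <- local({
  x <- .hill_const$fv_d3
  1 - .hill_const$fv_d1 * log(x + sqrt(x * x + 1))
})

#' Tendon force-length shift for a scaled tendon stiffness
#'
#' Returns the shift `s` that keeps the normalized tendon force at the slack
#' length (`ltilde = 1`) identical to the generic curve (`k = 35`, `s = 0`),
#' so that changing tendon stiffness does not change the force at slack.
#' Closed form: `s = 0.2 * (exp(0.005 * 35) - exp(0.005 * k))`.
#'
#' @param k dimensionless tendon stiffness (> 0); the generic value is 35.
#' @return shift `s` (dimensionless).
#' @export
#' @examples
#' tendon_shift(35)   # 0: the generic curve is its own reference
#' tendon_shift(14)   # ~0.023748
tendon_shift <- function(k) {
  stopifnot(all(k > 0))
  cc <- .hill_const
  cc$tendon_c1 * (exp(cc$k_generic * (1 - cc$tendon_c2)) -
                  exp(k * (1 - cc$tendon_c2)))
}

#' Normalized tendon force from normalized tendon length
#'
#' Algebraic inverse of the tendon force-length law:
#' `ftilde = 0.2 * exp(k * (ltilde - 0.995)) - 0.25 + s`.
#' Strictly increasing and smooth in `ltilde`.
#'
#' @param lt normalized tendon length (length / slack length), > 0.
#' @param k dimensionless tendon stiffness (default generic 35).
#' @param s curve shift (default `tendon_shift(k)`).
#' @return normalized tendon force (force / maximal isometric force).
#' @export
tendon_force <- function(lt, k = .hill_const$k_generic, s = tendon_shift(k)) {
  cc <- .hill_const
  cc$tendon_c1 * exp(k * (lt - cc$tendon_c2)) - cc$tendon_c3 + s
}

#' Normalized tendon length from normalized tendon force
#'
#' Direct evaluation of the tendon law
#' `ltilde = log(5 * (ftilde + 0.25 - s)) / k + 0.995`.
#'
#' @param ft normalized tendon force; must satisfy `ft > s - 0.25` so the
#'   logarithm is defined.
#' @inheritParams tendon_force
#' @return normalized tendon length.
#' @export
tendon_length <- function(ft, k = .hill_const$k_generic, s = tendon_shift(k)) {
  cc <- .hill_const
  log((ft + cc$tendon_c3 - s) / cc$tendon_c1) / k + cc$tendon_c2
}

## d(ltilde)/d(ftilde): needed for tendon velocity in the implicit
## contraction dynamics.
tendon_length_deriv <- function(ft, k = .hill_const$k_generic,
                                s = tendon_shift(k)) {
  cc <- .hill_const
  1 / (k * (ft + cc$tendon_c3 - s))
}

#' Active force-length curve
#'
#' Smooth sum-of-Gaussians active force-length multiplier; peaks at a
#' normalized fiber length of ~1 and tails off toward 0.4 and 1.6.
#'
#' @param lm normalized fiber length (fiber length / optimal fiber length).
#' @return dimensionless multiplier in (0, ~1].
#' @export
active_fl <- function(lm) {
  cc <- .hill_const
  out <- 0
  for (i in seq_along(cc$fl_b1)) {
    den <- cc$fl_b3[i] + cc$fl_b4[i] * lm
    out <- out + cc$fl_b1[i] * exp(-0.5 * (lm - cc$fl_b2[i])^2 / (den * den))
  }
  out
}

#' Force-velocity curve
#'
#' Smooth logarithmic force-velocity multiplier; exactly 1 at zero velocity,
#' ~0 at the maximal shortening velocity (`vm = -1`), > 1 when lengthening.
#'
#' @param vm normalized fiber velocity (fiber velocity / maximal shortening
#'   velocity); negative when shortening.
#' @return dimensionless multiplier.
#' @export
force_velocity <- function(vm) {
  cc <- .hill_const
  x <- cc$fv_d2 * vm + cc$fv_d3
  cc$fv_d1 * log(x + sqrt(x * x + 1)) + cc$fv_d4
}

#' Passive force-length curve
#'
#' Exponential passive fiber elasticity: ~0 at and below the optimal fiber
#' length, increasing beyond it.
#'
#' @inheritParams active_fl
#' @return dimensionless multiplier.
#' @export
passive_fl <- function(lm) {
  cc <- .hill_const
  (exp(cc$pfl_kpe * (lm - 1) / cc$pfl_e0) - 1) / (exp(cc$pfl_kpe) - 1)
}

#' Muscle activation dynamics
#'
#' First-order bilinear excitation-activation coupling with distinct
#' activation and deactivation time constants, smoothed with a tanh blend so
#' the rate is differentiable in `(e, a)`.  Fixed point at `a = e`.
#'
#' @param e muscle excitation in `[0, 1]`.
#' @param a muscle activation in `[0, 1]`.
#' @param tau_act activation time constant (s), default 0.015.
#' @param tau_deact deactivation time constant (s), default 0.06.
#' @param b blend sharpness (dimensionless), default 40.
#' @return `da/dt` (1/s).
#' @export
activation_dynamics <- function(e, a, tau_act = 0.015, tau_deact = 0.06,
                                b = 40) {
  sig <- smooth_step(e - a, b)
  (e - a) * (sig / tau_act + (1 - sig) / tau_deact)
}

## Partial derivatives of the activation rate (analytic; used by the
## transcription Jacobian).
activation_dynamics_jac <- function(e, a, tau_act = 0.015, tau_deact = 0.06,
                                    b = 40) {
  d <- e - a
  th <- tanh(b * d)
  sig <- 0.5 * th + 0.5
  rate_coef <- sig / tau_act + (1 - sig) / tau_deact
  dsig <- 0.5 * b * (1 - th * th)
  dcoef <- dsig * (1 / tau_act - 1 / tau_deact)
  list(de = rate_coef + d * dcoef,
       da = -(rate_coef + d * dcoef))
}
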