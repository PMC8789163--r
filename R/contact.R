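## Smooth Hunt-Crossley sphere-plane foot-ground contact.
##
## The ground is the horizontal plane y = 0.  The normal force is a
## Hertz-type term proportional to penetration^(3/2) times a dissipation
## factor (1 + 1.5 c \delta_dot); both the contact switch and the 3/2 power
## are regularized so the force is differentiable everywhere and ~0 out of
## contact.  Tangential force is smoothed Coulomb friction plus a viscous
## term, opposing the slip velocity of the contact point.

#' Define a contact sphere
#'
#' @param name sphere label.
#' @param segment parent segment name.
#' @param center 2-vector: sphere center in the segment frame (m).
#' @param radius sphere radius (m), > 0.
#' @param stiffness Hertz stiffness scale (N m^-3/2), > 0.
#' @param dissipation Hunt-Crossley dissipation (s/m), >= 0.
#' @param mu_d dynamic (= static) Coulomb friction coefficient.
#' @param mu_v viscous friction coefficient (s/m).
#' @param v_trans friction transition velocity (m/s).
#' @param eps smoothing length scale (m).
#' @return a contact sphere list.
#' @export
contact_sphere <- function(name, segment, center, radius, stiffness = 4.5e5,
                           dissipation = 2, mu_d = 0.8, mu_v = 0.5,
                           v_trans = 0.1, eps = 1e-5) {
  stopifnot(radius > 0, stiffness > 0, dissipation >= 0)
  list(name = name, segment = segment, center = center, radius = radius,
       stiffness = stiffness, dissipation = dissipation, mu_d = mu_d,
       mu_v = mu_v, v_trans = v_trans, eps = eps)
}

#' Smooth Hunt-Crossley sphere-plane force
#'
#' @param delta penetration depth (m); negative above ground. Vectorized.
#' @param delta_dot penetration rate (m/s).
#' @param v_slip tangential (forward) slip velocity of the contact point
#'   (m/s).
#' @param sphere a sphere from [contact_sphere()].
#' @return list with `fx` (tangential, N), `fy` (normal, N) and `fn`
#'   (normal magnitude before friction, N).
#' @export
sphere_force <- function(delta, delta_dot, v_slip, sphere) {
  s <- sphere
  ds <- smooth_pos(delta, s$eps)
  sw <- smooth_step(delta, 1 / s$eps)
  damp <- smooth_pos(1 + 1.5 * s$dissipation * delta_dot, 1e-2)
  fn <- s$stiffness * ds * sqrt(ds) * damp * sw
  fx <- -fn * (s$mu_d * tanh(v_slip / s$v_trans) + s$mu_v * v_slip)
  list(fx = fx, fy = fn, fn = fn)
}

#' Ground reaction forces, centers of pressure and per-sphere forces
#'
#' Places every contact sphere by forward kinematics, evaluates the smooth
#' sphere-plane law and sums per foot (spheres grouped by the `_r` / `_l`
#' suffix of their parent segment).  The center of pressure is the
#' vertical-force-weighted mean of the contact point positions.
#'
#' @param m a `predgait_model`.
#' @param Q,QD coordinate positions and velocities (`nq x P`).
#' @return list with `feet` (per side: `Fx`, `Fy`, `cop` P-vectors),
#'   `spheres` (per-sphere forces and world positions) and `ext` (external
#'   force list consumable by [inverse_dynamics()]).
#' @export
model_grf <- function(m, Q, QD) {
  fk <- forward_kinematics(m, Q, QD)
  P <- ncol(Q)
  spheres <- list()
  ext <- list()
  sides <- list()
  for (cs in m$contact_spheres) {
    pt <- fk_point(fk, cs$segment, cs$center)
    delta <- cs$radius - pt$y
    delta_dot <- -pt$vy
    v_slip <- pt$vx + pt$w * cs$radius  # lowest-point velocity
    f <- sphere_force(delta, delta_dot, v_slip, cs)
    cpx <- pt$x                          # contact point (below center)
    cpy <- pt$y - cs$radius
    spheres[[cs$name]] <- list(fx = f$fx, fy = f$fy, x = cpx, y = cpy)
    ext[[length(ext) + 1L]] <- list(segment = cs$segment, px = cpx, py = cpy,
                                    fx = f$fx, fy = f$fy)
    side <- if (grepl("_r$", cs$segment)) "r"
            else if (grepl("_l$", cs$segment)) "l" else "c"
    if (is.null(sides[[side]]))
      sides[[side]] <- list(Fx = rep(0, P), Fy = rep(0, P),
                            mom = rep(0, P))
    sides[[side]]$Fx <- sides[[side]]$Fx + f$fx
    sides[[side]]$Fy <- sides[[side]]$Fy + f$fy
    sides[[side]]$mom <- sides[[side]]$mom + f$fy * cpx
  }
  feet <- lapply(sides, function(sd) {
    sd$cop <- sd$mom / (sd$Fy + 1e-9)
    sd$mom <- NULL
    sd
  })
  list(feet = feet, spheres = spheres, ext = ext)
}

#' First vertical ground-reaction-force peak
#'
#' Value of the first local maximum of the vertical GRF over stance whose
#' prominence exceeds a threshold; falls back to the maximum over the first
#' half of the series when no such local maximum exists.
#'
#' @param v vertical GRF series over a stance phase (N).
#' @param prominence minimum peak prominence (N), default 10.
#' @return peak force (N).
#' @export
first_vertical_peak <- function(v, prominence = 10) {
  n <- length(v)
  if (n == 0) stop("empty vertical GRF series")
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
        ## prominence: drop to the higher of the two flanking valleys
        left <- i; while (left > 1 && v[left - 1] <= v[i]) left <- left - 1
        right <- i; while (right < n && v[right + 1] <= v[i]) right <- right + 1
        valley_l <- min(v[left:i]); valley_r <- min(v[i:right])
        if (v[i] - max(valley_l, valley_r) >= prominence)
          return(v[i])
      }
    }
  }
  max(v[seq_len(max(1L, floor(n / 2)))])
}
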