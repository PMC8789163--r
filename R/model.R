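## Declarative musculoskeletal model (planar).
##
## A model is a plain list with class "predgait_model": segments, joints,
## muscles, contact spheres, per-coordinate passive torque parameters and
## collision pairs.  Coordinates are derived from the joint list in
## definition order.  Model variants (locked toes, mass redistribution,
## contact-sphere height, tendon stiffness) are parameterized against an
## immutable `base` snapshot so applying a variant and its inverse restores
## the original fields bit-for-bit.

#' Construct a musculoskeletal model
#'
#' @param name model name (string).
#' @param segments data.frame with columns `name`, `mass` (kg), `inertia`
#'   (kg m^2 about the COM), `length` (m), `com_x`, `com_y` (m, COM offset in
#'   the segment frame).
#' @param joints list of joints. Each joint is a list with `name`, `type`
#'   (one of "planar", "hinge", "weld"), `parent`, `child` (segment names;
#'   parent "ground" allowed), `loc_parent` (2-vector, m: joint position in
#'   the parent frame), `coords` (character: coordinate names; 3 for planar
#'   \[tx, ty, rz\], 1 for hinge, none for weld), `range` (list of 2-vectors,
#'   rad or m), optional `is_toe` flag and `locked_angle` (rad, for welds).
#' @param muscles list of muscle definitions (see [muscle_params()]).
#' @param contact_spheres list of contact spheres (see [contact_sphere()]).
#' @param passive named list (by coordinate) of passive torque parameter
#'   lists (see [passive_params()]).
#' @param torque_actuators list of `{coordinate, max_torque, tau}`.
#' @param collision_pairs list of `{a = list(segment, point), b = ...,
#'   min_dist}`.
#' @param gravity gravitational acceleration (m/s^2, downward positive).
#' @return an object of class `predgait_model`.
#' @export
model_spec <- function(name, segments, joints, muscles = list(),
                       contact_spheres = list(), passive = list(),
                       torque_actuators = list(), collision_pairs = list(),
                       gravity = 9.81) {
  m <- structure(list(
    name = name, version = "1",
    segments = segments, joints = joints, muscles = muscles,
    contact_spheres = contact_spheres, passive = passive,
    torque_actuators = torque_actuators, collision_pairs = collision_pairs,
    gravity = gravity,
    variant_state = list(torso_mass_delta = 0, contact_vertical_offset = 0,
                         toes_locked = FALSE, tendon_stiffness_fraction = 1)
  ), class = "predgait_model")
  m$base <- list(segments = segments, joints = joints,
                 contact_spheres = contact_spheres, muscles = muscles)
  validate_model(rebuild_model(m))
}

## Recompute derived fields (coordinate table) and revalidate caches.
rebuild_model <- function(m) {
  coords <- list()
  for (j in m$joints) {
    if (j$type == "weld") next
    kinds <- switch(j$type, planar = c("px", "py", "rz"), hinge = "rz",
                    config_error("unknown joint type '%s'", j$type))
    for (i in seq_along(kinds)) {
      coords[[length(coords) + 1L]] <- list(
        name = j$coords[i], joint = j$name, kind = kinds[i],
        range = j$range[[i]], is_toe = isTRUE(j$is_toe))
    }
  }
  m$coordinates <- coords
  m$coord_names <- vapply(coords, `[[`, "", "name")
  attr(m, "engine") <- NULL
  m
}

#' Validate a model's structural invariants
#'
#' Checks that the total mass is positive, coordinate names are unique, all
#' muscle paths and contact spheres reference existing segments, and toe
#' coordinates carry no active actuation.
#'
#' @param m a `predgait_model`.
#' @return the model, invisibly usable in pipelines.
#' @export
validate_model <- function(m) {
  if (sum(m$segments$mass) <= 0) config_error("total mass must be positive")
  if (anyDuplicated(m$coord_names))
    config_error("coordinate names must be unique")
  segs <- c("ground", m$segments$name)
  for (j in m$joints)
    if (!(j$parent %in% segs) || !(j$child %in% m$segments$name))
      config_error("joint '%s' references unknown segment", j$name)
  for (mus in m$muscles)
    for (pp in mus$path)
      if (!(pp$segment %in% m$segments$name))
        config_error("muscle '%s' path references unknown segment '%s'",
                     mus$name, pp$segment)
  for (cs in m$contact_spheres)
    if (!(cs$segment %in% m$segments$name))
      config_error("contact sphere '%s' references unknown segment", cs$name)
  toe_coords <- m$coord_names[vapply(m$coordinates, `[[`, TRUE, "is_toe")]
  for (ta in m$torque_actuators)
    if (ta$coordinate %in% toe_coords)
      config_error("toe coordinate '%s' must not be actuated", ta$coordinate)
  m
}

#' Passive joint torque parameters
#'
#' Exponential end-range stiffness plus an optional linear spring and linear
#' damping.  The torque law is
#' `T = k1 * exp(k2 * (q_lo - q)) - k1 * exp(k2 * (q - q_hi))
#'    - k_lin * (q - q0) - damping * qdot`.
#'
#' @param k1 exponential limit-torque magnitude (Nm), >= 0.
#' @param k2 exponential rate (1/rad), >= 0.
#' @param q_lo,q_hi soft range-of-motion limits (rad).
#' @param damping linear damping (Nm s/rad), >= 0.
#' @param k_lin linear spring stiffness (Nm/rad), >= 0.
#' @param q0 linear spring neutral angle (rad).
#' @return a parameter list.
#' @export
passive_params <- function(k1 = 2, k2 = 10, q_lo = -1, q_hi = 1,
                           damping = 0.1, k_lin = 0, q0 = 0) {
  stopifnot(damping >= 0, k_lin >= 0, k1 >= 0, k2 >= 0, q_hi >= q_lo)
  list(k1 = k1, k2 = k2, q_lo = q_lo, q_hi = q_hi, damping = damping,
       k_lin = k_lin, q0 = q0)
}

#' Passive joint torque
#'
#' Sum of exponential end-range limit torques, a linear spring and linear
#' damping; smooth in both arguments.
#'
#' @param q joint angle (rad); vectorized.
#' @param qdot joint velocity (rad/s); vectorized.
#' @param params parameters from [passive_params()].
#' @return torque (Nm).
#' @export
#' @examples
#' p <- passive_params(k_lin = 25, damping = 2)
#' passive_torque(0.1, 0, p)   # spring contributes -2.5 Nm
passive_torque <- function(q, qdot, params) {
  p <- params
  p$k1 * exp(p$k2 * (p$q_lo - q)) - p$k1 * exp(p$k2 * (q - p$q_hi)) -
    p$k_lin * (q - p$q0) - p$damping * qdot
}

#' Describe a model variant
#'
#' @param toes_locked `NA` to leave the toe joints as they are, `TRUE` to
#'   replace the toe hinges by welds at the neutral angle, `FALSE` to unlock.
#' @param torso_mass_delta signed change of the torso mass (kg); the opposite
#'   amount is distributed over the leg segments proportionally to their
#'   masses (total mass conserved; inertia rescales linearly with mass).
#' @param contact_vertical_offset vertical shift of every contact-sphere
#'   center in its segment frame (m); radii unchanged.
#' @param tendon_stiffness_fraction tendon stiffness fraction in (0, 1\]
#'   applied to the triceps-surae muscles (`NA` to leave unchanged);
#'   `k = 35 * fraction` with the curve shift recomputed.
#' @return a `predgait_variant` list.
#' @export
model_variant <- function(toes_locked = NA, torso_mass_delta = 0,
                          contact_vertical_offset = 0,
                          tendon_stiffness_fraction = NA) {
  if (!is.na(tendon_stiffness_fraction))
    stopifnot(tendon_stiffness_fraction > 0, tendon_stiffness_fraction <= 1)
  structure(list(toes_locked = toes_locked,
                 torso_mass_delta = torso_mass_delta,
                 contact_vertical_offset = contact_vertical_offset,
                 tendon_stiffness_fraction = tendon_stiffness_fraction),
            class = "predgait_variant")
}

#' Invert a model variant
#'
#' @param v a `predgait_variant`.
#' @return the inverse variant: applying `v` then `invert_variant(v)`
#'   restores the original model bit-for-bit.
#' @export
invert_variant <- function(v) {
  model_variant(
    toes_locked = if (is.na(v$toes_locked)) NA else !v$toes_locked,
    torso_mass_delta = -v$torso_mass_delta,
    contact_vertical_offset = -v$contact_vertical_offset,
    tendon_stiffness_fraction = if (is.na(v$tendon_stiffness_fraction)) NA
                                else 1)
}

## Which segments count as "torso" / "legs" for mass redistribution.
torso_segments <- function(m) m$segments$name[m$segments$name %in%
                                                c("torso", "trunk", "hat")]
leg_segments <- function(m) setdiff(m$segments$name, torso_segments(m))

#' Apply a variant to a model
#'
#' All variant effects are recomputed from the model's immutable base
#' snapshot plus the cumulative variant state, so variants compose and
#' invert exactly.
#'
#' @param m a `predgait_model`.
#' @param v a `predgait_variant` from [model_variant()].
#' @return the transformed model.
#' @export
apply_variant <- function(m, v) {
  st <- m$variant_state
  if (!is.na(v$toes_locked)) st$toes_locked <- v$toes_locked
  st$torso_mass_delta <- st$torso_mass_delta + v$torso_mass_delta
  st$contact_vertical_offset <-
    st$contact_vertical_offset + v$contact_vertical_offset
  if (!is.na(v$tendon_stiffness_fraction))
    st$tendon_stiffness_fraction <- v$tendon_stiffness_fraction
  m$variant_state <- st

  ## masses: delta removed from torso, spread over legs by mass fraction
  seg <- m$base$segments
  if (st$torso_mass_delta != 0) {
    it <- seg$name %in% torso_segments(m)
    il <- !it
    if (!any(it)) config_error("model has no torso segment")
    ratio_t <- (sum(seg$mass[it]) + st$torso_mass_delta) / sum(seg$mass[it])
    ratio_l <- (sum(seg$mass[il]) - st$torso_mass_delta) / sum(seg$mass[il])
    seg$mass[it] <- seg$mass[it] * ratio_t
    seg$mass[il] <- seg$mass[il] * ratio_l
    seg$inertia[it] <- seg$inertia[it] * ratio_t
    seg$inertia[il] <- seg$inertia[il] * ratio_l
  }
  m$segments <- seg

  ## contact sphere height
  m$contact_spheres <- lapply(m$base$contact_spheres, function(cs) {
    cs$center[2] <- cs$center[2] + st$contact_vertical_offset
    cs
  })

  ## toe lock / unlock
  m$joints <- lapply(m$base$joints, function(j) {
    if (isTRUE(j$is_toe) && st$toes_locked) {
      j$type <- "weld"
      j$locked_angle <- 0
    }
    j
  })

  ## tendon stiffness on the triceps surae
  m$muscles <- lapply(m$base$muscles, function(mus) {
    if (identical(mus$group, "triceps_surae")) {
      mus$stiff_frac <- st$tendon_stiffness_fraction
      mus$k <- .hill_const$k_generic * mus$stiff_frac
      mus$shift <- tendon_shift(mus$k)
    }
    mus
  })

  validate_model(rebuild_model(m))
}

#' Distances between declared collision point pairs
#'
#' @param q coordinate vector (one configuration).
#' @param m a `predgait_model`.
#' @return numeric vector of Euclidean distances (m), one per declared pair;
#'   `numeric(0)` when the model declares none.
#' @export
collision_distance <- function(q, m) {
  if (length(m$collision_pairs) == 0) return(numeric(0))
  Q <- matrix(q, ncol = 1)
  fk <- forward_kinematics(m, Q)
  vapply(m$collision_pairs, function(cp) {
    pa <- fk_point(fk, cp$a$segment, cp$a$point)
    pb <- fk_point(fk, cp$b$segment, cp$b$point)
    sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  }, 0)
}

#' @export
print.predgait_model <- function(x, ...) {
  cat(sprintf("<predgait model '%s'>\n", x$name))
  cat(sprintf("  segments: %d (total mass %.3f kg)\n", nrow(x$segments),
              sum(x$segments$mass)))
  cat(sprintf("  coordinates: %d (%s)\n", length(x$coord_names),
              paste(x$coord_names, collapse = ", ")))
  cat(sprintf("  muscles: %d, contact spheres: %d, torque actuators: %d\n",
              length(x$muscles), length(x$contact_spheres),
              length(x$torque_actuators)))
  st <- x$variant_state
  cat(sprintf(
    "  variant: toes_locked=%s mass_delta=%.3g contact_dy=%.3g tendon=%.2g\n",
    st$toes_locked, st$torso_mass_delta, st$contact_vertical_offset,
    st$tendon_stiffness_fraction))
  invisible(x)
}

## Left-right mirror map for half-gait-cycle symmetry: coordinates ending in
## `_r` exchange with `_l`; everything else maps to itself.
symmetry_map <- function(m) {
  nm <- m$coord_names
  out <- vapply(nm, function(s) {
    if (grepl("_r$", s)) sub("_r$", "_l", s)
    else if (grepl("_l$", s)) sub("_l$", "_r", s)
    else s
  }, "")
  idx <- match(out, nm)
  if (anyNA(idx)) config_error("coordinate mirror map is inconsistent")
  idx
}

## Same for muscles (by name suffix).
muscle_symmetry_map <- function(m) {
  nm <- vapply(m$muscles, `[[`, "", "name")
  out <- vapply(nm, function(s) {
    if (grepl("_r$", s)) sub("_r$", "_l", s)
    else if (grepl("_l$", s)) sub("_l$", "_r", s)
    else s
  }, "")
  idx <- match(out, nm)
  if (anyNA(idx)) config_error("muscle mirror map is inconsistent")
  idx
}
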