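## Planar rigid-body skeletal dynamics.
##
## The kinematic tree is compiled from the declarative joint list into a
## flat "engine" (parent indices, joint types, frame offsets).  Inverse
## dynamics is a planar recursive Newton-Euler pass, written so every
## per-body quantity is a vector over an arbitrary number of evaluation
## points P: one call evaluates the whole collocation grid.  Gravity enters
## through the standard accelerated-base trick.  The residual formulation
## (accelerations as inputs, `M(q) u_a + bias - tau_applied` as output) is
## what the collocation transcription uses as an equality path constraint.

model_engine <- function(m) {
  eng <- attr(m, "engine")
  if (!is.null(eng)) return(eng)
  seg <- m$segments
  nb <- nrow(seg)
  idx <- seq_len(nb); names(idx) <- seg$name
  parent <- integer(nb); jtype <- character(nb)
  locp <- matrix(0, nb, 2); locked <- numeric(nb)
  coord_idx <- vector("list", nb)
  placed <- logical(nb)
  order <- integer(0)
  cmap <- match(m$coord_names, m$coord_names) # identity; names used below
  names(cmap) <- m$coord_names
  for (j in m$joints) {
    b <- idx[[j$child]]
    parent[b] <- if (j$parent == "ground") 0L else idx[[j$parent]]
    if (parent[b] > 0 && !placed[parent[b]])
      config_error("joints must be listed parent-first ('%s')", j$name)
    if (j$type == "planar" && j$parent != "ground")
      config_error("planar base joint must attach to ground")
    jtype[b] <- j$type
    locp[b, ] <- j$loc_parent
    locked[b] <- if (is.null(j$locked_angle)) 0 else j$locked_angle
    coord_idx[[b]] <- if (j$type == "weld") integer(0) else
      match(j$coords, m$coord_names)
    placed[b] <- TRUE
    order <- c(order, b)
  }
  if (!all(placed)) config_error("segment(s) without a joint: %s",
                                 paste(seg$name[!placed], collapse = ", "))
  eng <- list(nb = nb, order = order, parent = parent, jtype = jtype,
              locp = locp, locked = locked, coord_idx = coord_idx,
              mass = seg$mass, inertia = seg$inertia,
              com = cbind(seg$com_x, seg$com_y), seg_idx = idx,
              nq = length(m$coord_names))
  eng
}

## Forward kinematics over P configurations.
## Q, QD, QDD: nq x P matrices (QD/QDD optional).  base_acc_y adds a common
## upward base acceleration (set to +gravity inside RNEA).
## Returns per-body lists of P-vectors: th, px, py [, w, vx, vy][, al, ax, ay].
forward_kinematics <- function(m, Q, QD = NULL, QDD = NULL, base_acc_y = 0) {
  eng <- model_engine(m)
  P <- ncol(Q)
  z <- rep(0, P)
  nb <- eng$nb
  th <- px <- py <- w <- vx <- vy <- al <- ax <- ay <- vector("list", nb)
  vel <- !is.null(QD); acc <- !is.null(QDD)
  for (b in eng$order) {
    p <- eng$parent[b]
    if (p == 0L) {
      thp <- z; pxp <- z; pyp <- z; wp <- z; vxp <- z; vyp <- z
      alp <- z; axp <- z; ayp <- z + base_acc_y
    } else {
      thp <- th[[p]]; pxp <- px[[p]]; pyp <- py[[p]]
      if (vel) { wp <- w[[p]]; vxp <- vx[[p]]; vyp <- vy[[p]] }
      if (acc) { alp <- al[[p]]; axp <- ax[[p]]; ayp <- ay[[p]] }
    }
    cp <- cos(thp); sp <- sin(thp)
    rx <- cp * eng$locp[b, 1] - sp * eng$locp[b, 2]
    ry <- sp * eng$locp[b, 1] + cp * eng$locp[b, 2]
    ci <- eng$coord_idx[[b]]
    if (eng$jtype[b] == "planar") {
      th[[b]] <- Q[ci[3], ]
      px[[b]] <- rx + Q[ci[1], ]; py[[b]] <- ry + Q[ci[2], ]
      if (vel) { w[[b]] <- QD[ci[3], ]; vx[[b]] <- QD[ci[1], ]
                 vy[[b]] <- QD[ci[2], ] }
      if (acc) { al[[b]] <- QDD[ci[3], ]; ax[[b]] <- QDD[ci[1], ]
                 ay[[b]] <- QDD[ci[2], ] + base_acc_y }
    } else {
      dth <- if (eng$jtype[b] == "hinge") Q[ci[1], ] else eng$locked[b]
      th[[b]] <- thp + dth
      px[[b]] <- pxp + rx; py[[b]] <- pyp + ry
      if (vel) {
        w[[b]] <- wp + if (eng$jtype[b] == "hinge") QD[ci[1], ] else 0
        vx[[b]] <- vxp - wp * ry; vy[[b]] <- vyp + wp * rx
      }
      if (acc) {
        al[[b]] <- alp + if (eng$jtype[b] == "hinge") QDD[ci[1], ] else 0
        ax[[b]] <- axp - alp * ry - wp * wp * rx
        ay[[b]] <- ayp + alp * rx - wp * wp * ry
      }
    }
  }
  structure(list(model = m, eng = eng, P = P, th = th, px = px, py = py,
                 w = w, vx = vx, vy = vy, al = al, ax = ax, ay = ay,
                 has_vel = vel, has_acc = acc),
            class = "predgait_fk")
}

## World position (and velocity, if available) of a point fixed in a segment
## frame; `fk` from forward_kinematics, `point` a 2-vector.
fk_point <- function(fk, segment, point) {
  b <- fk$eng$seg_idx[[segment]]
  c0 <- cos(fk$th[[b]]); s0 <- sin(fk$th[[b]])
  rx <- c0 * point[1] - s0 * point[2]
  ry <- s0 * point[1] + c0 * point[2]
  out <- list(x = fk$px[[b]] + rx, y = fk$py[[b]] + ry)
  if (fk$has_vel) {
    out$vx <- fk$vx[[b]] - fk$w[[b]] * ry
    out$vy <- fk$vy[[b]] + fk$w[[b]] * rx
    out$w <- fk$w[[b]]
  }
  out
}

#' Inverse dynamics (recursive Newton-Euler, planar)
#'
#' Computes the generalized forces `tau = M(q) qdd + bias(q, qd) - tau_ext`
#' required to realize the given accelerations, with external point forces
#' (e.g. foot-ground contact) taken into account.
#'
#' @param m a `predgait_model`.
#' @param Q,QD,QDD coordinate positions, velocities, accelerations
#'   (`nq x P` matrices).
#' @param ext optional list of external point forces, each a list with
#'   `segment`, `px`, `py` (world application point, P-vectors) and
#'   `fx`, `fy` (world force components, P-vectors).
#' @param gravity include gravity (default TRUE).
#' @return `nq x P` matrix of generalized forces.
#' @export
inverse_dynamics <- function(m, Q, QD, QDD, ext = list(), gravity = TRUE) {
  eng <- model_engine(m)
  P <- ncol(Q)
  fk <- forward_kinematics(m, Q, QD, QDD,
                           base_acc_y = if (gravity) m$gravity else 0)
  nb <- eng$nb
  fx <- fy <- nn <- vector("list", nb)
  ## external forces grouped by body
  extb <- vector("list", nb)
  for (e in ext) {
    b <- eng$seg_idx[[e$segment]]
    extb[[b]] <- c(extb[[b]], list(e))
  }
  for (b in eng$order) {
    cth <- cos(fk$th[[b]]); sth <- sin(fk$th[[b]])
    cx <- cth * eng$com[b, 1] - sth * eng$com[b, 2]
    cy <- sth * eng$com[b, 1] + cth * eng$com[b, 2]
    acx <- fk$ax[[b]] - fk$al[[b]] * cy - fk$w[[b]]^2 * cx
    acy <- fk$ay[[b]] + fk$al[[b]] * cx - fk$w[[b]]^2 * cy
    Fx <- eng$mass[b] * acx; Fy <- eng$mass[b] * acy
    fx[[b]] <- Fx; fy[[b]] <- Fy
    nn[[b]] <- eng$inertia[b] * fk$al[[b]] + cx * Fy - cy * Fx
    for (e in extb[[b]]) {
      fx[[b]] <- fx[[b]] - e$fx
      fy[[b]] <- fy[[b]] - e$fy
      nn[[b]] <- nn[[b]] - ((e$px - fk$px[[b]]) * e$fy -
                            (e$py - fk$py[[b]]) * e$fx)
    }
  }
  tau <- matrix(0, eng$nq, P)
  for (b in rev(eng$order)) {
    ci <- eng$coord_idx[[b]]
    if (eng$jtype[b] == "planar") {
      tau[ci[1], ] <- fx[[b]]
      tau[ci[2], ] <- fy[[b]]
      tau[ci[3], ] <- nn[[b]]
    } else if (eng$jtype[b] == "hinge") {
      tau[ci[1], ] <- nn[[b]]
    }
    p <- eng$parent[b]
    if (p > 0L) {
      fx[[p]] <- fx[[p]] + fx[[b]]
      fy[[p]] <- fy[[p]] + fy[[b]]
      nn[[p]] <- nn[[p]] + nn[[b]] +
        (fk$px[[b]] - fk$px[[p]]) * fy[[b]] -
        (fk$py[[b]] - fk$py[[p]]) * fx[[b]]
    }
  }
  tau
}

#' Skeletal dynamics residual
#'
#' Implicit equation of motion: `residual = M(q) u_a + bias(q, qd)
#' - tau_applied`, where the applied generalized forces are the muscle joint
#' torques, passive torques and ideal-actuator torques, and contact wrenches
#' enter as external forces.  Zero residual identifies `u_a` with the true
#' accelerations.
#'
#' @inheritParams inverse_dynamics
#' @param UA candidate coordinate accelerations (`nq x P`).
#' @param applied list with optional elements `muscle` (nq x P joint
#'   torques), `passive` (nq x P), `actuator` (nq x P) and `contact`
#'   (external force list as in [inverse_dynamics()]).
#' @return `nq x P` residual of generalized forces (Nm or N).
#' @export
dynamics_residual <- function(m, Q, QD, UA, applied = list()) {
  tau <- inverse_dynamics(m, Q, QD, UA,
                          ext = applied$contact %||% list(), gravity = TRUE)
  for (f in c("muscle", "passive", "actuator"))
    if (!is.null(applied[[f]])) tau <- tau - applied[[f]]
  tau
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mass matrix at a configuration
#'
#' Assembled column-by-column from inverse dynamics with unit accelerations
#' and gravity off; symmetric positive definite for a well-formed model.
#'
#' @param m a `predgait_model`.
#' @param q coordinate vector.
#' @return `nq x nq` matrix.
#' @export
mass_matrix <- function(m, q) {
  nq <- length(q)
  Q <- matrix(q, nq, nq)
  QD <- matrix(0, nq, nq)
  QDD <- diag(nq)
  inverse_dynamics(m, Q, QD, QDD, gravity = FALSE)
}

#' Muscle joint torques from tendon forces and fitted geometry
#'
#' `tau_j = sum_muscles r_j(q) * F_T`; coordinates not spanned by any
#' muscle path (e.g. the toes) receive zero.
#'
#' @param Q coordinate matrix (`nq x P`).
#' @param FT tendon forces (`n_muscle x P`, N).
#' @param geom fitted muscle geometry from [fit_all_muscles()].
#' @return `nq x P` torque matrix (Nm).
#' @export
muscle_joint_torques <- function(Q, FT, geom) {
  nq <- geom$nq
  P <- ncol(Q)
  tau <- matrix(0, nq, P)
  for (i in seq_along(geom$muscles)) {
    g <- geom$muscles[[i]]
    R <- mtu_moment_arms(g, Q)
    for (jj in seq_along(g$coord_idx))
      tau[g$coord_idx[jj], ] <- tau[g$coord_idx[jj], ] + R[jj, ] * FT[i, ]
  }
  tau
}

#' Ideal torque-actuator dynamics
#'
#' First-order lag of the actuator torque toward `e_a * max_torque`,
#' approximating a pure time delay.
#'
#' @param e_a actuator excitation in `[-1, 1]`.
#' @param torque current internal torque state (Nm).
#' @param max_torque actuator strength (Nm).
#' @param tau time constant (s), default 0.035.
#' @return torque rate (Nm/s).
#' @export
torque_actuator_dynamics <- function(e_a, torque, max_torque, tau = 0.035) {
  (e_a * max_torque - torque) / tau
}
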