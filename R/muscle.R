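## Hill-type muscle-tendon mechanics.
##
## Contraction dynamics are posed implicitly: the normalized tendon force is
## a state, its scaled time derivative a control, and the force equilibrium
## between fiber and tendon a path constraint.  `hill_equilibrium()`
## evaluates that constraint residual (and the fiber kinematics needed by
## the metabolic model) from activation, musculotendon length/velocity and
## the tendon-force state.

#' Muscle-tendon parameter set
#'
#' @param name muscle name (conventionally suffixed `_r` / `_l`).
#' @param F_max maximal isometric force (N).
#' @param l_opt optimal fiber length (m).
#' @param l_slack tendon slack length (m).
#' @param alpha_opt pennation angle at optimal fiber length (rad).
#' @param v_max maximal shortening velocity (optimal fiber lengths / s).
#' @param stiff_frac tendon stiffness fraction in (0, 1]; `k = 35 *
#'   stiff_frac` and the tendon curve shift is recomputed so the force at
#'   slack length is unchanged.
#' @param fast_twitch fast-twitch fiber fraction in `[0, 1]`.
#' @param mass muscle mass (kg); default from F_max, specific tension
#'   0.25 MPa and density 1059.7 kg/m^3.
#' @param path list of via points `{segment, point = c(x, y)}` from origin
#'   to insertion.
#' @param group functional group label (e.g. "triceps_surae",
#'   "quadriceps"); the tendon-stiffness variant targets "triceps_surae".
#' @return a muscle parameter list.
#' @export
muscle_params <- function(name, F_max, l_opt, l_slack, alpha_opt = 0,
                          v_max = 10, stiff_frac = 1, fast_twitch = 0.5,
                          mass = NULL, path = list(), group = "") {
  stopifnot(F_max > 0, l_opt > 0, l_slack > 0)
  k <- .hill_const$k_generic * stiff_frac
  list(name = name, F_max = F_max, l_opt = l_opt, l_slack = l_slack,
       alpha_opt = alpha_opt, v_max = v_max, k = k, stiff_frac = stiff_frac,
       shift = tendon_shift(k), fast_twitch = fast_twitch,
       mass = if (is.null(mass)) F_max / 0.25e6 * 1059.7 * l_opt else mass,
       path = path, group = group)
}

## Per-muscle parameter vectors for matrix evaluation (length n_muscle,
## recycled down the columns of n_muscle x P matrices).
muscle_param_vectors <- function(m) {
  g <- function(f) vapply(m$muscles, `[[`, 0, f)
  list(F_max = g("F_max"), l_opt = g("l_opt"), l_slack = g("l_slack"),
       alpha_opt = g("alpha_opt"), v_max = g("v_max"), k = g("k"),
       shift = g("shift"), fast_twitch = g("fast_twitch"), mass = g("mass"),
       names = vapply(m$muscles, `[[`, "", "name"))
}

## Matrix Hill evaluation: all inputs n_muscle x P (or per-muscle vectors
## recycled).  Returns residual and fiber kinematics.  `beta` is a small
## normalized fiber damping for well-posedness.
hill_eval <- function(A, FT, LMT, VMT, FTDOT, pv, beta = 0.01) {
  lt <- tendon_length(FT, pv$k, pv$shift)
  lT <- pv$l_slack * lt
  w <- pv$l_opt * sin(pv$alpha_opt)
  proj <- LMT - lT
  ## smooth guard keeping the fiber projection positive (> 0.05 l_opt)
  proj <- smooth_pos(proj - 0.05 * pv$l_opt, 1e-4) + 0.05 * pv$l_opt
  lM <- sqrt(proj * proj + w * w)
  lm_tilde <- lM / pv$l_opt
  cos_a <- proj / lM
  vT <- pv$l_slack * tendon_length_deriv(FT, pv$k, pv$shift) * FTDOT
  vm_tilde <- (VMT - vT) * cos_a / (pv$v_max * pv$l_opt)
  fl <- active_fl(lm_tilde)
  fv <- force_velocity(vm_tilde)
  fp <- passive_fl(lm_tilde)
  res <- FT - (A * fl * fv + fp + beta * vm_tilde) * cos_a
  list(residual = res, lm_tilde = lm_tilde, vm_tilde = vm_tilde,
       cos_alpha = cos_a, fl_active = fl, fv = fv, fl_passive = fp,
       F_tendon = FT * pv$F_max,
       F_fiber_active = A * fl * fv * pv$F_max,
       F_fiber_iso = A * fl * pv$F_max,
       F_fiber_total = (A * fl * fv + fp + beta * vm_tilde) * pv$F_max)
}

#' Hill muscle-tendon equilibrium residual
#'
#' Implicit force balance between the tendon (normalized force `ft`, the
#' state) and the fiber (activation, force-length, force-velocity, passive
#' elasticity and a small damping `beta`), acting through the pennation
#' angle under the constant-thickness rule `l_M sin(alpha) = l_opt
#' sin(alpha_opt)`.  A zero residual defines the admissible manifold used as
#' a path constraint by the optimal-control transcription.
#'
#' @param a activation in `[0, 1]`.
#' @param l_mt musculotendon length (m).
#' @param v_mt musculotendon lengthening velocity (m/s).
#' @param ft normalized tendon force (state).
#' @param params a muscle parameter list from [muscle_params()].
#' @param ft_dot time derivative of the normalized tendon force (1/s);
#'   needed for the fiber-velocity term of the implicit dynamics.
#' @param beta normalized fiber damping, default 0.01.
#' @return list with `residual` (dimensionless), `lm_tilde`, `vm_tilde`,
#'   `cos_alpha`, and tendon/fiber forces in newtons.
#' @export
hill_equilibrium <- function(a, l_mt, v_mt, ft, params, ft_dot = 0,
                             beta = 0.01) {
  pv <- list(F_max = params$F_max, l_opt = params$l_opt,
             l_slack = params$l_slack, alpha_opt = params$alpha_opt,
             v_max = params$v_max, k = params$k, shift = params$shift)
  lt <- tendon_length(ft, pv$k, pv$shift)
  if (any(l_mt - pv$l_slack * lt <= 0.05 * pv$l_opt))
    stop(errorCondition(
      sprintf("muscle '%s': non-physical geometry (fiber too short)",
              params$name %||% "?"),
      class = c("predgait_domain_error", "error")))
  hill_eval(a, ft, l_mt, v_mt, ft_dot, pv, beta)
}

#' Solve the Hill equilibrium for the tendon-force state
#'
#' Static (zero tendon-force rate) root solve of the equilibrium residual in
#' `ft` by bisection; used for initial guesses and rigid-tendon checks.
#'
#' @inheritParams hill_equilibrium
#' @param interval search interval for the normalized tendon force.
#' @return normalized tendon force at equilibrium.
#' @export
hill_solve_ft <- function(a, l_mt, v_mt, params, beta = 0.01,
                          interval = c(-0.2, 3)) {
  f <- function(ft) hill_eval(a, ft, l_mt, v_mt, 0,
                              list(F_max = params$F_max, l_opt = params$l_opt,
                                   l_slack = params$l_slack,
                                   alpha_opt = params$alpha_opt,
                                   v_max = params$v_max, k = params$k,
                                   shift = params$shift), beta)$residual
  stats::uniroot(f, interval, tol = 1e-12)$root
}
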