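## Phenomenological muscle metabolic energetics (Bhargava-style) with every
## conditional replaced by a tanh blend of configurable sharpness, so the
## rate is differentiable and usable inside a gradient-based optimal-control
## problem.  The unsmoothed piecewise model is implemented alongside as the
## independent oracle (`mode = "piecewise"`).

.metab_const <- list(
  act_slow = 40, act_fast = 133,       # W/kg activation heat constants
  maint_slow = 74, maint_fast = 111,   # W/kg maintenance heat constants
  alpha_short_iso = 0.16,              # shortening heat, isometric-force part
  alpha_short_tot = 0.18,              # shortening heat, total-force part
  alpha_lengthen = 0.157,              # lengthening heat coefficient
  heat_floor = 1.0,                    # W/kg: minimum total heat rate
  basal_per_kg = 1.2                   # W/kg body mass, added once
)

## Piecewise-linear maintenance-rate dependence on normalized fiber length:
## knots (0, .5), (.5, .5), (1, 1), (1.5, 1), (2, 0).
.maint_knots <- cbind(x = c(0, 0.5, 1.0, 1.5, 2.0),
                      y = c(0.5, 0.5, 1.0, 1.0, 0.0))

maintenance_fl <- function(lm, smooth = TRUE, b = 100) {
  xk <- unname(.maint_knots[, "x"]); yk <- unname(.maint_knots[, "y"])
  nseg <- length(xk) - 1L
  segval <- function(i, x) {
    sl <- (yk[i + 1] - yk[i]) / (xk[i + 1] - xk[i])
    yk[i] + sl * (x - xk[i])
  }
  if (!smooth) {
    x <- pmin(pmax(lm, 0), xk[length(xk)])
    i <- pmin(pmax(findInterval(x, xk), 1L), nseg)
    out <- segval(i, x)
    out[lm >= xk[length(xk)]] <- 0
    return(out)
  }
  ## smooth: start on segment 1, blend in the slope changes at inner knots,
  ## and switch off entirely beyond the last knot
  out <- segval(1L, lm)
  for (i in 2:nseg) {
    w <- smooth_step(lm - xk[i], b)
    out <- out + w * (segval(i, lm) - segval(i - 1L, lm))
  }
  out * (1 - smooth_step(lm - xk[length(xk)], b))
}

#' Muscle metabolic energy rate (Bhargava-style, smoothed)
#'
#' Sum of activation heat, fiber-length-dependent maintenance heat,
#' velocity-sign-dependent shortening/lengthening heat and mechanical work
#' rate, each per muscle.  In the default smooth mode every conditional
#' (excitation-vs-activation blend, shortening vs lengthening, the
#' piecewise maintenance fiber-length factor and the total heat floor) is a
#' hyperbolic-tangent blend of sharpness `b`; `mode = "piecewise"` evaluates
#' the underlying unsmoothed model and serves as the verification oracle.
#'
#' @param e muscle excitation in `[0, 1]` (vector or `n x P` matrix).
#' @param a muscle activation in `[0, 1]`.
#' @param lm_tilde normalized fiber length.
#' @param vm_tilde normalized fiber velocity (negative shortening).
#' @param F_iso active isometric fiber force at the current length,
#'   `a * fl(lm) * F_max` (N).
#' @param F_total total fiber force (N).
#' @param params list of per-muscle parameter vectors: `mass` (kg),
#'   `fast_twitch`, `v_max`, `l_opt` (from [muscle_param_vectors()] or a
#'   single [muscle_params()] list).
#' @param mode "smooth" (default) or "piecewise".
#' @param b blend sharpness for the smooth mode, default 100.
#' @param work "signed" (default: eccentric work subtracts) or "positive"
#'   (clamped at zero).
#' @return list of rates in watts, same shape as the inputs: `activation`,
#'   `maintenance`, `shortening`, `work`, `total`.
#' @export
bhargava_rate <- function(e, a, lm_tilde, vm_tilde, F_iso, F_total, params,
                          mode = c("smooth", "piecewise"), b = 100,
                          work = c("signed", "positive")) {
  mode <- match.arg(mode)
  work <- match.arg(work)
  cc <- .metab_const
  mm <- params$mass; ff <- params$fast_twitch
  smooth <- mode == "smooth"

  ## excitation/activation dependence: A = e if e > a else (e + a) / 2
  if (smooth) {
    sw <- smooth_step(e - a, b)
    A <- sw * e + (1 - sw) * (e + a) / 2
  } else A <- ifelse(e > a, e, (e + a) / 2)

  decay_slow <- sin(pi / 2 * A)
  decay_fast <- 1 - cos(pi / 2 * A)
  h_act <- mm * ((1 - ff) * cc$act_slow * decay_slow +
                 ff * cc$act_fast * decay_fast)
  h_maint <- mm * maintenance_fl(lm_tilde, smooth = smooth, b = b) *
    ((1 - ff) * cc$maint_slow * decay_slow + ff * cc$maint_fast * decay_fast)

  ## fiber velocity in m/s (negative = shortening)
  v_m <- vm_tilde * params$v_max * params$l_opt
  alpha_s <- cc$alpha_short_iso * F_iso + cc$alpha_short_tot * F_total
  alpha_l <- cc$alpha_lengthen * F_total
  if (smooth) {
    swv <- smooth_step(-vm_tilde, b)   # 1 when shortening
    alpha <- swv * alpha_s + (1 - swv) * alpha_l
  } else alpha <- ifelse(v_m <= 0, alpha_s, alpha_l)
  h_sl <- -alpha * v_m

  w_rate <- -F_total * v_m
  if (work == "positive") {
    w_rate <- if (smooth) smooth_pos(w_rate, 1e-3) else pmax(w_rate, 0)
  }

  heat <- h_act + h_maint + h_sl
  floor_w <- cc$heat_floor * mm
  heat_tot <- if (smooth) floor_w + smooth_pos(heat - floor_w, 1e-3)
              else pmax(heat, floor_w)
  list(activation = h_act, maintenance = h_maint, shortening = h_sl,
       work = w_rate, heat = heat_tot, total = heat_tot + w_rate)
}

#' Basal metabolic rate
#'
#' @param body_mass body mass (kg).
#' @return basal whole-body rate (W), `1.2 W/kg * body_mass`.
#' @export
basal_rate <- function(body_mass) .metab_const$basal_per_kg * body_mass

#' Gross metabolic cost of transport
#'
#' `COT = integral of the whole-body metabolic rate over one gait cycle /
#' (body mass x forward distance)` in J kg^-1 m^-1.
#'
#' @param traj either a `gait_solution` (uses its collocation-consistent
#'   quadrature) or a list with `time` (s), `Edot` (whole-body rate, W,
#'   including basal) and `distance` (m).
#' @param body_mass body mass (kg).
#' @return cost of transport (J kg^-1 m^-1).
#' @export
cost_of_transport <- function(traj, body_mass) {
  if (inherits(traj, "gait_solution")) {
    E <- traj$energy_total
    dist <- traj$distance
  } else {
    if (is.null(traj$distance) || traj$distance <= 0)
      stop("trajectory has zero forward distance")
    dt <- diff(traj$time)
    E <- sum(dt * (traj$Edot[-1] + traj$Edot[-length(traj$Edot)]) / 2)
    dist <- traj$distance
  }
  if (dist <= 0) stop("trajectory has zero forward distance")
  E / (body_mass * dist)
}

#' Per-group share of a cost-of-transport difference
#'
#' Splits the difference in total metabolic energy between two solutions
#' over named muscle groups; shares sum to 100%.
#'
#' @param sol_a,sol_b two `gait_solution` objects over the same muscle set.
#' @param groups named list of character vectors of muscle names; muscles
#'   not listed are collected into an "other" group.
#' @return named numeric vector of percentage shares.
#' @export
per_group_breakdown <- function(sol_a, sol_b, groups) {
  if (!identical(sol_a$muscle_names, sol_b$muscle_names))
    stop("solutions have different muscle sets")
  dE <- sol_b$energy_per_muscle - sol_a$energy_per_muscle
  names(dE) <- sol_a$muscle_names
  used <- character(0)
  shares <- vapply(groups, function(g) {
    used <<- c(used, g)
    sum(dE[intersect(g, names(dE))])
  }, 0)
  rest <- setdiff(names(dE), used)
  if (length(rest)) shares <- c(shares, other = sum(dE[rest]))
  tot <- sum(shares)
  if (tot == 0) return(shares * 0)
  100 * shares / tot
}
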