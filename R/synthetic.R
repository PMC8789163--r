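## Synthetic data generators: a planar musculoskeletal fixture model and a
## synthetic periodic reference gait emulating averaged overground walking
## data (joint angles, torques, GRFs, EMG envelopes, mean +/- SD).  All
## outputs are deterministic functions of (seed, params).

## ---------------------------------------------------------------- fixture

#' Planar walking fixture model
#'
#' A sagittal-plane model anchored to a 62 kg / 1.70 m adult: a single
#' head-arms-torso segment on a 3-DoF planar base, and per leg a hip, knee,
#' ankle and (optionally) metatarsophalangeal hinge, nine muscles and three
#' contact spheres (heel and metatarsal heads on the hindfoot, one on the
#' toe segment).  Segment masses follow standard anthropometric fractions
#' and sum to the body mass; tendon slack lengths are computed from the path
#' geometry so each fiber operates near its optimal length in a mid-gait
#' posture.  The toe joints have no muscles: a linear rotational spring
#' (25 Nm/rad) and damper (2 Nm s/rad) on top of the exponential limit
#' torques.
#'
#' @param body_mass body mass (kg), default 62.
#' @param height stature (m), default 1.70; segment lengths scale linearly.
#' @param toes include toe segments and MTP joints (default TRUE); when
#'   FALSE the toe joints are welded (equivalent to the locked-toes
#'   variant).
#' @param toe_damping MTP damping coefficient (Nm s/rad), default 2.
#' @return a `predgait_model`.
#' @export
make_planar_fixture <- function(body_mass = 62, height = 1.70, toes = TRUE,
                                toe_damping = 2) {
  s <- height / 1.70
  l_th <- 0.4165 * s; l_sh <- 0.4182 * s
  ## mass fractions: HAT 0.678, thigh 0.100, shank 0.0465, foot 0.0145
  m_hat <- 0.678 * body_mass
  m_th <- 0.100 * body_mass; m_sh <- 0.0465 * body_mass
  m_hf <- 0.0125 * body_mass; m_toe <- 0.0020 * body_mass
  segments <- data.frame(
    name = c("torso", "thigh_r", "shank_r", "hindfoot_r", "toes_r",
             "thigh_l", "shank_l", "hindfoot_l", "toes_l"),
    mass = c(m_hat, m_th, m_sh, m_hf, m_toe, m_th, m_sh, m_hf, m_toe),
    inertia = c(m_hat * (0.35 * s)^2,
                rep(c(m_th * (0.323 * l_th)^2, m_sh * (0.302 * l_sh)^2,
                      m_hf * (0.085 * s)^2, m_toe * (0.03 * s)^2), 2)),
    length = c(0.60 * s, rep(c(l_th, l_sh, 0.18 * s, 0.08 * s), 2)),
    com_x = c(0, rep(c(0, 0, 0.05 * s, 0.03 * s), 2)),
    com_y = c(0.32 * s, rep(c(-0.433 * l_th, -0.433 * l_sh, -0.04 * s,
                              -0.01 * s), 2))
  )
  leg_joints <- function(side) {
    list(
      list(name = paste0("hip_", side), type = "hinge", parent = "torso",
           child = paste0("thigh_", side), loc_parent = c(0, 0),
           coords = paste0("hip_", side), range = list(c(-0.9, 1.2))),
      list(name = paste0("knee_", side), type = "hinge",
           parent = paste0("thigh_", side), child = paste0("shank_", side),
           loc_parent = c(0, -l_th), coords = paste0("knee_", side),
           range = list(c(-2.1, 0.1))),
      list(name = paste0("ankle_", side), type = "hinge",
           parent = paste0("shank_", side),
           child = paste0("hindfoot_", side), loc_parent = c(0, -l_sh),
           coords = paste0("ankle_", side), range = list(c(-0.9, 0.7))),
      list(name = paste0("mtp_", side),
           type = if (toes) "hinge" else "weld",
           parent = paste0("hindfoot_", side),
           child = paste0("toes_", side),
           loc_parent = c(0.13 * s, -0.05 * s),
           coords = paste0("mtp_", side), range = list(c(-0.5, 1.2)),
           is_toe = TRUE, locked_angle = 0)
    )
  }
  joints <- c(list(list(
    name = "base", type = "planar", parent = "ground", child = "torso",
    loc_parent = c(0, 0),
    coords = c("pelvis_tx", "pelvis_ty", "pelvis_tilt"),
    range = list(c(-1, 5), c(0.70, 1.10), c(-0.6, 0.6)))),
    leg_joints("r"), leg_joints("l"))

  leg_muscles <- function(side) {
    sg <- function(base) paste0(base, "_", side)
    pt <- function(segment, x, y) list(segment = segment,
                                       point = c(x * s, y * s))
    defs <- list(
      list("glut", 3000, 0.160, 0.5, "glutei",
           list(pt("torso", -0.10, 0.07), pt(sg("thigh"), -0.035, -0.13))),
      list("iliopsoas", 2500, 0.130, 0.5, "iliopsoas",
           list(pt("torso", 0.08, 0.09), pt(sg("thigh"), 0.025, -0.12))),
      list("hamstrings", 3500, 0.110, 0.45, "hamstrings",
           list(pt("torso", -0.10, 0.05), pt(sg("shank"), -0.028, -0.04))),
      list("rf", 1500, 0.085, 0.55, "quadriceps",
           list(pt("torso", 0.06, 0.03), pt(sg("thigh"), 0.05, -0.39),
                pt(sg("shank"), 0.04, -0.07))),
      list("vasti", 6000, 0.090, 0.5, "quadriceps",
           list(pt(sg("thigh"), 0.03, -0.15), pt(sg("thigh"), 0.05, -0.39),
                pt(sg("shank"), 0.04, -0.07))),
      list("bfsh", 800, 0.120, 0.5, "hamstrings",
           list(pt(sg("thigh"), -0.03, -0.25), pt(sg("shank"), -0.03, -0.06))),
      list("gastroc", 2800, 0.060, 0.5, "triceps_surae",
           list(pt(sg("thigh"), -0.025, -0.39), pt(sg("shank"), -0.035, -0.07),
                pt(sg("hindfoot"), -0.055, -0.02))),
      list("soleus", 4000, 0.055, 0.25, "triceps_surae",
           list(pt(sg("shank"), -0.025, -0.06), pt(sg("hindfoot"), -0.055, -0.02))),
      list("tibant", 2000, 0.098, 0.3, "dorsiflexors",
           list(pt(sg("shank"), 0.030, -0.25), pt(sg("shank"), 0.037, -0.40),
                pt(sg("hindfoot"), 0.035, -0.01)))
    )
    lapply(defs, function(d)
      muscle_params(name = paste0(d[[1]], "_", side), F_max = d[[2]],
                    l_opt = d[[3]] * s, l_slack = 1,  # set below
                    fast_twitch = d[[4]], group = d[[5]], path = d[[6]]))
  }
  muscles <- c(leg_muscles("r"), leg_muscles("l"))

  spheres <- function(side) list(
    contact_sphere(paste0("heel_", side), paste0("hindfoot_", side),
                   c(-0.06 * s, -0.06 * s), 0.02 * s),
    contact_sphere(paste0("met_", side), paste0("hindfoot_", side),
                   c(0.115 * s, -0.06 * s), 0.02 * s),
    contact_sphere(paste0("toe_", side), paste0("toes_", side),
                   c(0.045 * s, -0.012 * s), 0.018 * s)
  )
  passive <- list(
    hip = passive_params(k1 = 2, k2 = 5, q_lo = -0.5, q_hi = 1.1,
                         damping = 0.1),
    knee = passive_params(k1 = 2, k2 = 8, q_lo = -2.0, q_hi = 0.02,
                          damping = 0.1),
    ankle = passive_params(k1 = 2, k2 = 8, q_lo = -0.6, q_hi = 0.5,
                           damping = 0.1),
    mtp = passive_params(k1 = 2, k2 = 10, q_lo = -0.3, q_hi = 0.9,
                         damping = toe_damping, k_lin = 25, q0 = 0)
  )
  pas <- list()
  for (side in c("r", "l"))
    for (jn in c("hip", "knee", "ankle", "mtp"))
      pas[[paste0(jn, "_", side)]] <- passive[[jn]]

  m <- model_spec(name = if (toes) "planar_fixture" else
                    "planar_fixture_no_toes",
                  segments = segments, joints = joints, muscles = muscles,
                  contact_spheres = c(spheres("r"), spheres("l")),
                  passive = pas)

  ## tendon slack lengths from the path geometry: normalized tendon length 1
  ## and fiber at optimal length in a mid-gait posture
  qref <- stats::setNames(rep(0, length(m$coord_names)), m$coord_names)
  qref[grep("^hip", names(qref))] <- 0.2
  qref[grep("^knee", names(qref))] <- -0.35
  qref["pelvis_ty"] <- 0.91
  Qr <- matrix(qref, ncol = 1)
  m$muscles <- lapply(m$muscles, function(mus) {
    lmt <- mtu_path_length(m, mus, Qr)
    mus$l_slack <- as.numeric(lmt - mus$l_opt * cos(mus$alpha_opt))
    mus
  })
  m$base$muscles <- m$muscles
  validate_model(rebuild_model(m))
}

#' Neutral standing pose
#'
#' All joint angles at neutral; the pelvis height is found by a static root
#' solve so the vertical contact force balances body weight.
#'
#' @param m a `predgait_model`.
#' @return named coordinate vector.
#' @export
standing_pose <- function(m) {
  nq <- length(m$coord_names)
  q <- stats::setNames(rep(0, nq), m$coord_names)
  weight <- sum(m$segments$mass) * m$gravity
  f <- function(py) {
    q["pelvis_ty"] <- py
    grf <- model_grf(m, matrix(q, ncol = 1), matrix(0, nq, 1))
    sum(vapply(grf$feet, function(ft) ft$Fy, 0)) - weight
  }
  q["pelvis_ty"] <- stats::uniroot(f, c(0.80, 1.00), tol = 1e-10)$root
  q
}

## ------------------------------------------------- synthetic reference gait

## Template curves (right side), periodic control points over the gait
## cycle (fractions of a cycle starting at right heel strike).  Angle
## templates in degrees; these are fixture constants emulating the shape of
## averaged overground walking data, not claims about any subject.
.gait_templates <- list(
  hip = list(x = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90) / 100,
             y = c(25, 20, 11, 2, -8, -12, -8, 10, 26, 28)),
  knee = list(x = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 96) / 100,
              y = c(-5, -16, -15, -8, -7, -18, -40, -60, -35, -10, -4)),
  ankle = list(x = c(0, 7, 15, 30, 45, 55, 62, 70, 80, 90, 96) / 100,
               y = c(0, -6, 2, 7, 10, -3, -17, -8, 2, 4, 2)),
  mtp = list(x = c(0, 15, 30, 45, 55, 62, 68, 75, 90) / 100,
             y = c(5, 2, 2, 12, 28, 35, 15, 5, 5)),
  pelvis_tilt = list(x = c(0, 25, 50, 75) / 100, y = c(1.5, 0.5, 1.5, 0.5)),
  pelvis_ty = list(x = c(0, 10, 30, 50, 60, 80) / 100,
                   y = c(0.905, 0.900, 0.920, 0.905, 0.900, 0.920)),
  torque_hip = list(x = c(0, 10, 25, 45, 55, 70, 85) / 100,
                    y = c(-40, -30, 0, 35, 20, -10, -15)),
  torque_knee = list(x = c(0, 8, 15, 30, 45, 55, 65, 80, 92) / 100,
                     y = c(5, 25, 30, 5, -15, -5, 5, 10, 0)),
  torque_ankle = list(x = c(0, 8, 20, 35, 45, 52, 60, 70, 85) / 100,
                      y = c(5, -5, -25, -55, -75, -70, -15, 0, 0)),
  torque_mtp = list(x = c(0, 30, 50, 58, 64, 75) / 100,
                    y = c(0, -1, -6, -12, -4, 0))
)

## EMG envelope bursts: center, width (cycle fraction), peak (normalized).
.emg_templates <- list(
  glut = list(c = 0.05, w = 0.08, p = 0.6),
  iliopsoas = list(c = 0.57, w = 0.08, p = 0.5),
  hamstrings = list(c = 0.95, w = 0.08, p = 0.7),
  rf = list(c = 0.08, w = 0.07, p = 0.3),
  vasti = list(c = 0.08, w = 0.07, p = 0.6),
  bfsh = list(c = 0.68, w = 0.07, p = 0.4),
  gastroc = list(c = 0.42, w = 0.09, p = 0.8),
  soleus = list(c = 0.44, w = 0.09, p = 0.9),
  tibant = list(c = 0.63, w = 0.06, p = 0.6)
)

eval_template <- function(tpl, frac) periodic_resample(tpl$x, tpl$y, frac)

emg_burst <- function(tpl, frac) {
  d <- (frac - tpl$c) %% 1
  d <- pmin(d, 1 - d)
  0.05 + tpl$p * exp(-0.5 * (d / tpl$w)^2)
}

#' Generate a synthetic periodic reference gait
#'
#' Produces mean +/- SD curves on a 101-point gait-cycle grid (0% = right
#' heel strike) for joint angles, joint torques, ground reaction forces and
#' EMG envelopes: angles from low-order periodic templates, the vertical GRF
#' as a two-Gaussian double hump scaled so the per-foot cycle impulse
#' equals half the body weight impulse, EMG as rectified-Gaussian bursts.
#' Mean and SD come from averaging `n_cycles` noisy cycles (smooth random
#' harmonic perturbations), so the dataset emulates data "averaged over 10
#' gait cycles".  Left-side signals are the right-side signals shifted by
#' half a cycle (exact symmetry).  Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param speed walking speed (m/s), default 1.33.
#' @param stance_fraction stance fraction of the gait cycle, default 0.60.
#' @param body_mass body mass (kg), default 62.
#' @param cycle_duration gait cycle duration (s), default 1.05.
#' @param n_cycles number of noisy cycles averaged, default 10.
#' @param sd_scale multiplier on all noise SDs, default 1.
#' @return a `reference_gait` list: `grid` (percent of cycle), `signals`
#'   (per signal: `mean`, `sd`, `unit`), and the generator parameters.
#' @export
make_reference_gait <- function(seed = 1, speed = 1.33,
                                stance_fraction = 0.60, body_mass = 62,
                                cycle_duration = 1.05, n_cycles = 10,
                                sd_scale = 1) {
  stopifnot(speed > 0, stance_fraction > 0, stance_fraction < 1,
            n_cycles >= 2, cycle_duration > 0)
  grid <- seq(0, 1, by = 0.01)
  deg <- pi / 180
  bw <- body_mass * 9.81

  ## right-side deterministic templates
  base <- list()
  for (nm in c("hip", "knee", "ankle", "mtp"))
    base[[paste0(nm, "_r")]] <-
      list(y = eval_template(.gait_templates[[nm]], grid) * deg, unit = "rad",
           sd0 = 1.5 * deg)
  base$pelvis_tilt <- list(y = eval_template(.gait_templates$pelvis_tilt,
                                             grid) * deg,
                           unit = "rad", sd0 = 1.0 * deg)
  base$pelvis_ty <- list(y = eval_template(.gait_templates$pelvis_ty, grid),
                         unit = "m", sd0 = 0.005)
  for (nm in c("hip", "knee", "ankle", "mtp"))
    base[[paste0("torque_", nm, "_r")]] <-
      list(y = eval_template(.gait_templates[[paste0("torque_", nm)]], grid),
           unit = "Nm", sd0 = 4)

  ## vertical GRF: double hump over stance, impulse-balanced
  g1 <- exp(-0.5 * ((grid - 0.13) / 0.055)^2)
  g2 <- exp(-0.5 * ((grid - 0.47) / 0.055)^2)
  win <- smooth_step(grid - 0.005, 300) * smooth_step(stance_fraction - grid,
                                                      300)
  vg <- (1.10 * g1 + 1.05 * g2 + 0.72 * exp(-0.5 * ((grid - 0.3) / 0.1)^2))
  vg <- vg * win
  vg <- vg * (0.5 / mean(vg))            # per-foot cycle average = BW / 2
  base$grf_vy_r <- list(y = vg * bw, unit = "N", sd0 = 0.03 * bw)
  fg <- (-0.16 * exp(-0.5 * ((grid - 0.12) / 0.05)^2) +
         0.17 * exp(-0.5 * ((grid - 0.50) / 0.05)^2)) * win
  base$grf_vx_r <- list(y = fg * bw, unit = "N", sd0 = 0.02 * bw)

  for (nm in names(.emg_templates))
    base[[paste0("emg_", nm, "_r")]] <-
      list(y = emg_burst(.emg_templates[[nm]], grid), unit = "normalized",
           sd0 = 0.05)

  ## noisy cycles -> mean +/- SD
  signals <- with_seed(seed, {
    out <- list()
    for (nm in names(base)) {
      b <- base[[nm]]
      cyc <- matrix(0, n_cycles, length(grid))
      for (i in seq_len(n_cycles)) {
        pert <- rep(0, length(grid))
        for (h in 1:3) {
          amp <- stats::rnorm(1, 0, b$sd0 * sd_scale / h)
          ph <- stats::runif(1, 0, 2 * pi)
          pert <- pert + amp * sin(2 * pi * h * grid + ph)
        }
        cyc[i, ] <- b$y + pert
      }
      out[[nm]] <- list(mean = colMeans(cyc),
                        sd = apply(cyc, 2, stats::sd), unit = b$unit)
    }
    out
  })

  ## enforce exact periodicity of the noisy means (harmonic noise is
  ## already periodic; guard against roundoff) and exact half-cycle
  ## left-right symmetry
  shift_half <- function(v) {
    f <- periodic_resample(grid[-length(grid)], v[-length(v)],
                           (grid + 0.5))
    f
  }
  for (nm in names(signals)) {
    signals[[nm]]$mean[length(grid)] <- signals[[nm]]$mean[1]
    signals[[nm]]$sd[length(grid)] <- signals[[nm]]$sd[1]
    if (grepl("_r$", nm)) {
      lnm <- sub("_r$", "_l", nm)
      signals[[lnm]] <- list(mean = shift_half(signals[[nm]]$mean),
                             sd = shift_half(signals[[nm]]$sd),
                             unit = signals[[nm]]$unit)
    }
  }

  structure(list(grid = grid * 100, signals = signals, speed = speed,
                 stance_fraction = stance_fraction, body_mass = body_mass,
                 cycle_duration = cycle_duration, seed = seed,
                 n_cycles = n_cycles, sd_scale = sd_scale),
            class = "reference_gait")
}

#' Validate a reference gait dataset
#'
#' Schema check shared by generated and externally supplied reference data:
#' 101-point grid, periodic endpoints, nonnegative SDs, exact half-cycle
#' left-right symmetry for sided signals.
#'
#' @param ref a `reference_gait`.
#' @param tol numeric tolerance for periodicity/symmetry.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_reference <- function(ref, tol = 1e-9) {
  stopifnot(length(ref$grid) == 101, ref$speed > 0)
  grid <- ref$grid / 100
  for (nm in names(ref$signals)) {
    sg <- ref$signals[[nm]]
    if (abs(sg$mean[1] - sg$mean[101]) > tol)
      config_error("signal '%s' is not periodic", nm)
    if (any(sg$sd < 0)) config_error("signal '%s' has negative SD", nm)
    if (grepl("_r$", nm)) {
      lnm <- sub("_r$", "_l", nm)
      if (is.null(ref$signals[[lnm]]))
        config_error("signal '%s' lacks a left counterpart", nm)
      lv <- periodic_resample(grid[-101], sg$mean[-101], grid + 0.5)
      if (max(abs(lv - ref$signals[[lnm]]$mean)) > tol)
        config_error("signal '%s' violates half-cycle symmetry", nm)
    }
  }
  invisible(ref)
}

#' Perturbed cold-start population
#'
#' `n` copies of the cold-start guess with small uniform perturbations on
#' the state trajectories; deterministic per seed, bounds respected.
#'
#' @param m a `predgait_model`.
#' @param config an [ocp_config()].
#' @param n number of guesses.
#' @param seed integer seed.
#' @param scale perturbation half-width as a fraction of each variable's
#'   bound range, default 0.01 (0 reproduces the cold start exactly).
#' @return list of `n` guess objects as returned by [cold_start()].
#' @export
make_initial_population <- function(m, config, n, seed = 0, scale = 0.01) {
  base <- cold_start(m, config)
  with_seed(seed, lapply(seq_len(n), function(i) {
    g <- base
    if (i > 1 && scale > 0) {
      rng <- g$ub - g$lb
      pert <- stats::runif(length(g$z), -scale, scale) * rng
      g$z <- pmin(pmax(g$z + pert, g$lb), g$ub)
    }
    g
  }))
}
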