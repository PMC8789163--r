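## Initial guesses, the multi-guess solve driver and gait-solution
## assembly.

## Half-cycle time fractions of all state grid columns.
ocp_grid_frac <- function(ocp) {
  cn <- ocp$coeffs$c
  c(0, (rep(seq_len(ocp$N) - 1L, each = 3) + cn[rep(1:3, ocp$N)]) / ocp$N)
}

## Interpolate the state trajectory at arbitrary half-cycle fractions using
## the collocation polynomial of each mesh interval.
state_at_frac <- function(ocp, X, fracs) {
  out <- matrix(0, nrow(X), length(fracs))
  for (ii in seq_along(fracs)) {
    f <- min(max(fracs[ii], 0), 1)
    i <- min(floor(f * ocp$N) + 1L, ocp$N)
    tau <- f * ocp$N - (i - 1L)
    cols <- c(3L * (i - 1L) + 1L, 3L * (i - 1L) + 1L + 1:3)
    out[, ii] <- colloc_interp(X[, cols, drop = FALSE], tau, ocp$coeffs)
  }
  out
}

## Solver problem adapter (forward differences: cheaper Jacobian stripes,
## guarded by the solver's line searches; direct calls to ocp_derivs keep
## central differences).
ocp_problem <- function(ocp) {
  list(fc = function(z) ocp_fc(ocp, z),
       derivs = function(z, with_obj = TRUE, precise = FALSE)
         ocp_derivs(ocp, z, with_obj = with_obj,
                    fd_mode = if (precise) "central" else "forward"),
       lb = ocp$lb, ub = ocp$ub)
}

## Friction homotopy for the cold start: the translating standing guess is
## wildly infeasible under full Coulomb friction (both feet slide), and
## plain restoration falls into an airborne pseudo-solution.  Solving a
## short sequence of problems with the friction coefficients scaled up
## from zero lets a stepping motion emerge gradually.
scale_friction <- function(m, frac) {
  m$contact_spheres <- lapply(m$base$contact_spheres, function(cs) {
    cs$mu_d <- cs$mu_d * frac
    cs$mu_v <- cs$mu_v * frac
    cs
  })
  attr(m, "engine") <- NULL
  m
}

cold_homotopy_z <- function(m, config, geom, ocp, opts, fracs = c(0, 0.3,
                                                                 0.6),
                            verbose = FALSE) {
  z <- cold_start(m, config, ocp)$z
  stage_opts <- utils::modifyList(opts, list(
    max_iter = 150, polish = FALSE,
    time_limit = max(30, opts$time_limit / (2 * length(fracs))),
    verbose = verbose))
  for (frac in fracs) {
    mf <- scale_friction(m, frac)
    ocp_f <- transcribe(mf, config, geom)
    res <- solve_alm(z, ocp_problem(ocp_f), stage_opts)
    z <- res$z
  }
  z
}

#' Cold-start initial guess
#'
#' A static, bilaterally symmetric standing posture translating forward at
#' the target speed over the guess duration; muscle activations and
#' controls constant, tendon-force states at their static equilibrium.
#'
#' @param m a `predgait_model`.
#' @param config an [ocp_config()].
#' @param ocp optional pre-built transcription (avoids refitting geometry).
#' @return guess list with `z` (scaled decision vector), `lb`, `ub`,
#'   `type`.
#' @export
cold_start <- function(m, config, ocp = NULL) {
  if (is.null(ocp)) ocp <- transcribe(m, config)
  q0 <- standing_pose(m)
  tf0 <- min(max(config$tf_guess, config$tf_bounds[1]), config$tf_bounds[2])
  frac <- ocp_grid_frac(ocp)
  nq <- ocp$nq; nm <- ocp$nm
  X <- matrix(0, ocp$nx, ocp$ngrid)
  X[ocp$qrows, ] <- q0
  X[which(m$coord_names == "pelvis_tx"), ] <-
    q0["pelvis_tx"] + config$speed * tf0 * frac
  X[ocp$qdrows, ] <- 0
  X[ocp$qdrows[which(m$coord_names == "pelvis_tx")], ] <- config$speed
  X[ocp$arows, ] <- 0.1
  Q0 <- matrix(q0, ncol = 1)
  ft0 <- vapply(seq_len(nm), function(i) {
    lmt <- as.numeric(mtu_length(ocp$geom$muscles[[i]], Q0))
    ft <- tryCatch(hill_solve_ft(0.1, lmt, 0, m$muscles[[i]]),
                   error = function(e) 0.05)
    min(max(ft, 0.01), 2)
  }, 0)
  X[ocp$ftrows, ] <- ft0
  z <- ocp_pack(ocp, X, matrix(0, nq, ocp$P), matrix(0, nm, ocp$P),
                matrix(0.1, nm, ocp$N), tf0)
  list(z = pmin(pmax(z, ocp$lb), ocp$ub), lb = ocp$lb, ub = ocp$ub,
       type = "cold")
}

#' Hot-start initial guess from reference gait data
#'
#' Resamples the reference joint-angle curves (first half cycle, 0% = right
#' heel strike) onto the collocation grid; velocities and accelerations
#' from the periodic spline derivatives; the pelvis height is adjusted so
#' the lowest contact sphere tracks the ground with ~2 mm penetration;
#' muscle states and controls constant as in the cold start.
#'
#' @param ref a `reference_gait`.
#' @inheritParams cold_start
#' @return guess list with `z`, `lb`, `ub`, `type`.
#' @export
hot_start <- function(ref, m, config, ocp = NULL) {
  if (is.null(ocp)) ocp <- transcribe(m, config)
  nq <- ocp$nq; nm <- ocp$nm
  needed <- setdiff(m$coord_names, "pelvis_tx")
  missing <- setdiff(needed, names(ref$signals))
  if (length(missing))
    config_error("reference gait lacks coordinate signal(s): %s",
                 paste(missing, collapse = ", "))
  tf0 <- min(max(ref$cycle_duration / 2, config$tf_bounds[1]),
             config$tf_bounds[2])
  Tcyc <- 2 * tf0
  frac_half <- ocp_grid_frac(ocp)          # fraction of the HALF cycle
  frac_cyc <- frac_half * 0.5
  gridf <- ref$grid / 100

  X <- matrix(0, ocp$nx, ocp$ngrid)
  UA <- matrix(0, nq, ocp$P)
  stage_cols <- 2:(ocp$P + 1)
  for (j in seq_len(nq)) {
    nm_j <- m$coord_names[j]
    if (nm_j == "pelvis_tx") {
      X[ocp$qrows[j], ] <- config$speed * tf0 * frac_half
      X[ocp$qdrows[j], ] <- config$speed
      next
    }
    sg <- ref$signals[[nm_j]]
    sf <- stats::splinefun(c(gridf[-length(gridf)], 1),
                           c(sg$mean[-length(sg$mean)], sg$mean[1]),
                           method = "periodic")
    X[ocp$qrows[j], ] <- sf(frac_cyc)
    X[ocp$qdrows[j], ] <- sf(frac_cyc, deriv = 1) / Tcyc
    UA[j, ] <- sf(frac_cyc[stage_cols], deriv = 2) / Tcyc^2
  }

  ## ground-consistent pelvis height: at every grid point solve the pelvis
  ## height so the total vertical contact force supports body weight (the
  ## dominant dynamic requirement); fall back to a 4 mm penetration of the
  ## lowest sphere when the root is not bracketed
  py_row <- which(m$coord_names == "pelvis_ty")
  weight <- sum(m$segments$mass) * m$gravity
  nqz <- matrix(0, nq, 1)
  for (jcol in seq_len(ocp$ngrid)) {
    qj <- X[ocp$qrows, jcol]
    fkj <- function(py) {
      qj[py_row] <- py
      Qj <- matrix(qj, ncol = 1)
      fk1 <- forward_kinematics(m, Qj)
      ymin <- Inf; ftot <- 0
      for (cs in m$contact_spheres) {
        pt <- fk_point(fk1, cs$segment, cs$center)
        ymin <- min(ymin, pt$y - cs$radius)
        ftot <- ftot + sphere_force(cs$radius - pt$y, 0, 0, cs)$fy
      }
      list(ymin = ymin, ftot = ftot)
    }
    py0 <- X[py_row, jcol]
    lo <- py0 - 0.08; hi <- py0 + 0.05
    flo <- fkj(lo)$ftot - weight; fhi <- fkj(hi)$ftot - weight
    if (flo > 0 && fhi < 0) {
      X[py_row, jcol] <- stats::uniroot(function(p) fkj(p)$ftot - weight,
                                        c(lo, hi), tol = 1e-8)$root
    } else {
      X[py_row, jcol] <- py0 - (fkj(py0)$ymin + 0.004)
    }
  }
  ## velocity of the adjusted height by central differences on the grid
  tg <- frac_half * tf0
  n <- ocp$ngrid
  dydt <- rep(0, n)
  dydt[2:(n - 1)] <- (X[py_row, 3:n] - X[py_row, 1:(n - 2)]) /
    (tg[3:n] - tg[1:(n - 2)])
  dydt[1] <- dydt[2]; dydt[n] <- dydt[n - 1]
  X[ocp$qdrows[py_row], ] <- dydt

  X[ocp$arows, ] <- 0.1
  for (i in seq_len(nm)) {
    g <- ocp$geom$muscles[[i]]
    lmt <- mtu_length(g, X[ocp$qrows, , drop = FALSE])
    ft <- vapply(lmt, function(L) {
      tryCatch(min(max(hill_solve_ft(0.1, L, 0, m$muscles[[i]]), 0.01), 2),
               error = function(e) 0.05)
    }, 0)
    X[ocp$ftrows[i], ] <- ft
  }
  z <- ocp_pack(ocp, X, UA, matrix(0, nm, ocp$P),
                matrix(0.1, nm, ocp$N), tf0)
  list(z = pmin(pmax(z, ocp$lb), ocp$ub), lb = ocp$lb, ub = ocp$ub,
       type = "hot")
}

## Interpolate a decision vector from one mesh onto another (same model).
z_remesh <- function(ocp_from, ocp_to, z) {
  u <- ocp_unpack(ocp_from, z)
  frac_to <- ocp_grid_frac(ocp_to)
  X <- state_at_frac(ocp_from, u$X, frac_to)
  stage_frac <- frac_to[2:(ocp_to$P + 1)]
  ## piecewise-constant / linear resampling of the controls
  stage_frac_from <- ocp_grid_frac(ocp_from)[2:(ocp_from$P + 1)]
  interp_rows <- function(Mfrom, fr_from, fr_to) {
    t(vapply(seq_len(nrow(Mfrom)), function(r)
      stats::approx(fr_from, Mfrom[r, ], xout = fr_to, rule = 2)$y,
      numeric(length(fr_to))))
  }
  UA <- interp_rows(u$UA, stage_frac_from, stage_frac)
  DFT <- interp_rows(u$DFT, stage_frac_from, stage_frac)
  mid_to <- (seq_len(ocp_to$N) - 0.5) / ocp_to$N
  iv_from <- pmin(pmax(ceiling(mid_to * ocp_from$N), 1L), ocp_from$N)
  E <- u$E[, iv_from, drop = FALSE]
  ocp_pack(ocp_to, X, UA, DFT, E, u$tf)
}

## Warm start one model's transcription from another model's solution,
## mapping states/controls by coordinate and muscle names (used by the
## locked-toes study: missing coordinates are dropped, new ones start at
## neutral).
z_map_model <- function(ocp_from, ocp_to, z) {
  u <- ocp_unpack(ocp_from, z)
  stopifnot(ocp_from$N == ocp_to$N)
  cf <- ocp_from$model$coord_names; ct <- ocp_to$model$coord_names
  mf <- vapply(ocp_from$model$muscles, `[[`, "", "name")
  mt <- vapply(ocp_to$model$muscles, `[[`, "", "name")
  ci <- match(ct, cf); mi <- match(mt, mf)
  if (anyNA(mi)) config_error("muscle sets do not map")
  pick <- function(M, idx, fill = 0) {
    out <- matrix(fill, length(idx), ncol(M))
    ok <- !is.na(idx)
    out[ok, ] <- M[idx[ok], , drop = FALSE]
    out
  }
  X <- rbind(pick(u$X[ocp_from$qrows, , drop = FALSE], ci),
             pick(u$X[ocp_from$qdrows, , drop = FALSE], ci),
             pick(u$X[ocp_from$arows, , drop = FALSE], mi),
             pick(u$X[ocp_from$ftrows, , drop = FALSE], mi, fill = 0.05))
  ocp_pack(ocp_to, X, pick(u$UA, ci), pick(u$DFT, mi),
           u$E[mi, , drop = FALSE], u$tf)
}

## Rotate a periodic vertical-GRF series so stance is contiguous from the
## first rising edge (heel strike); returns the rotated series and the
## stance index window.  The simulated cycle has a free phase (periodicity
## is phase-invariant), so stance metrics must not assume heel strike at 0%.
stance_window <- function(v, threshold = 20) {
  n <- length(v)
  on <- v > threshold
  if (!any(on)) return(list(v = v, stance = logical(n), start = 1L))
  if (all(on)) return(list(v = v, stance = rep(TRUE, n), start = 1L))
  vp <- c(v[-n])   # drop duplicated periodic endpoint if present
  np <- length(vp)
  onp <- vp > threshold
  rising <- which(!onp[c(np, seq_len(np - 1L))] & onp)
  start <- rising[1]
  idx <- ((start - 1L + seq_len(np) - 1L) %% np) + 1L
  vr <- vp[idx]
  list(v = vr, stance = vr > threshold, start = start)
}

## Count prominent local maxima of a vertical GRF series over stance.
count_grf_humps <- function(v, prominence) {
  n <- length(v)
  if (n < 3) return(0L)
  humps <- 0L
  for (i in 2:(n - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
      left <- i; while (left > 1 && v[left - 1] <= v[i]) left <- left - 1
      right <- i; while (right < n && v[right + 1] <= v[i]) right <- right + 1
      if (v[i] - max(min(v[left:i]), min(v[i:right])) >= prominence)
        humps <- humps + 1L
    }
  }
  humps
}

## Assemble a gait_solution from a converged decision vector.
assemble_solution <- function(ocp, res, guess_type) {
  m <- ocp$model
  fc <- res$fc
  u <- fc$u
  nq <- ocp$nq; nm <- ocp$nm
  tf <- u$tf
  Tcyc <- 2 * tf
  d_half <- u$X[ocp$qrows[ocp$tx_idx], ocp$ngrid] -
    u$X[ocp$qrows[ocp$tx_idx], 1]
  h <- tf / ocp$N

  ## metabolic energy over the half cycle (trapezoid-free: Radau weights)
  wq <- h * ocp$bq
  E_half_muscle <- as.numeric(fc$met %*% wq)
  body_mass <- sum(m$segments$mass)
  mmir <- muscle_symmetry_map(m)
  energy_per_muscle <- E_half_muscle + E_half_muscle[mmir]
  energy_total <- sum(energy_per_muscle) + basal_rate(body_mass) * Tcyc
  distance <- 2 * d_half

  ## full-cycle reconstruction on a 101-point cycle grid
  fracs <- seq(0, 1, by = 0.01)
  Xcyc <- matrix(0, ocp$nx, length(fracs))
  first <- fracs <= 0.5
  Xcyc[, first] <- state_at_frac(ocp, u$X, fracs[first] * 2)
  Xh <- state_at_frac(ocp, u$X, fracs[!first] * 2 - 1)
  Xm <- Xh[ocp$mir_x, , drop = FALSE]
  Xm[ocp$qrows[ocp$tx_idx], ] <- Xh[ocp$qrows[ocp$tx_idx], ] + d_half
  Xcyc[, !first] <- Xm
  Qc <- Xcyc[ocp$qrows, , drop = FALSE]
  QDc <- Xcyc[ocp$qdrows, , drop = FALSE]
  grf <- model_grf(m, Qc, QDc)
  vgrf_r <- grf$feet$r$Fy
  stance_fraction <- mean(vgrf_r > 20)

  sol <- structure(list(
    model_name = m$name, config = ocp$config, guess = guess_type,
    status = res$status, iterations = res$iterations, feas = res$feas,
    objective = res$f, terms = fc$terms,
    tf = tf, cycle_duration = Tcyc, distance = distance,
    stride_length = distance, speed = distance / Tcyc,
    X = u$X, UA = u$UA, DFT = u$DFT, E = u$E,
    coord_names = m$coord_names,
    muscle_names = vapply(m$muscles, `[[`, "", "name"),
    cycle_frac = fracs * 100,
    cycle_states = Xcyc,
    cycle_q = Qc, cycle_qd = QDc,
    cycle_act = Xcyc[ocp$arows, , drop = FALSE],
    cycle_ft = Xcyc[ocp$ftrows, , drop = FALSE],
    grf = list(r = grf$feet$r, l = grf$feet$l),
    stance_fraction = stance_fraction,
    energy_per_muscle = energy_per_muscle,
    energy_total = energy_total,
    body_mass = body_mass,
    n_mesh = ocp$N
  ), class = "gait_solution")
  sol$cot <- cost_of_transport(sol, body_mass)
  sol
}

#' @export
print.gait_solution <- function(x, ...) {
  cat(sprintf("<gait solution: %s, %s guess, status %s>\n", x$model_name,
              x$guess, x$status))
  cat(sprintf("  objective %.6g (iterations %d, feasibility %.2e)\n",
              x$objective, x$iterations, x$feas))
  cat(sprintf("  speed %.3f m/s, stride %.3f m, cycle %.3f s\n", x$speed,
              x$stride_length, x$cycle_duration))
  cat(sprintf("  COT %.3f J/kg/m, stance fraction %.2f\n", x$cot,
              x$stance_fraction))
  invisible(x)
}

#' Solve the predictive gait problem
#'
#' Transcribes and solves the half-gait-cycle optimal-control problem.
#' With `guess = "both"` the problem is solved from both the cold start and
#' the hot start and the lower-cost solution is returned (ties prefer the
#' cold start); the alternative's summary is retained in `$alternatives`.
#' For mesh densities above `n_coarse`, each guess is first solved on a
#' coarse mesh and the solution interpolated to the requested mesh
#' (continuation); the initial guess is still the declared cold/hot start.
#'
#' @param m a `predgait_model`.
#' @param config an [ocp_config()].
#' @param ref reference gait for the hot start; generated synthetically
#'   (seeded by `config$seed`) when NULL and needed.
#' @param guess "both", "cold" or "hot" (default from config).
#' @param geom optional pre-fitted geometry.
#' @param warm optional scaled decision vector used directly as the initial
#'   point (overrides `guess`; used by the studies for warm-started
#'   condition sweeps).
#' @param n_coarse coarse mesh for continuation (default 12; set >= the
#'   target mesh to disable).
#' @param verbose print solver progress.
#' @return a `gait_solution`.
#' @export
solve_gait <- function(m, config, ref = NULL, guess = config$guess,
                       geom = NULL, warm = NULL, n_coarse = 12,
                       verbose = FALSE) {
  if (is.null(geom)) geom <- fit_all_muscles(m)
  ocp <- transcribe(m, config, geom)
  prob <- ocp_problem(ocp)
  opts <- list(max_iter = config$max_iter, opt_tol = config$tol,
               feas_tol = config$feas_tol, verbose = verbose,
               time_limit = config$time_limit)

  run_one <- function(gtype, z0) {
    res <- solve_alm(z0, prob, opts)
    assemble_solution(ocp, res, gtype)
  }
  guess_z <- function(gtype) {
    if (config$n_mesh > n_coarse) {
      ## mesh continuation: solve coarse from the declared guess first
      cfg_c <- config; cfg_c$n_mesh <- as.integer(n_coarse)
      sol_c <- solve_gait(m, cfg_c, ref = ref, guess = gtype, geom = geom,
                          n_coarse = n_coarse, verbose = verbose)
      ocp_c <- transcribe(m, cfg_c, geom)
      zc <- ocp_pack(ocp_c, sol_c$X, sol_c$UA, sol_c$DFT, sol_c$E, sol_c$tf)
      return(z_remesh(ocp_c, ocp, zc))
    }
    if (gtype == "cold") cold_homotopy_z(m, config, geom, ocp, opts,
                                         verbose = verbose)
    else {
      if (is.null(ref)) ref <<- make_reference_gait(seed = config$seed)
      hot_start(ref, m, config, ocp)$z
    }
  }

  if (!is.null(warm)) return(run_one("warm", warm))
  types <- switch(guess, both = c("cold", "hot"), cold = "cold", hot = "hot")
  sols <- lapply(types, function(gt) run_one(gt, guess_z(gt)))
  names(sols) <- types
  if (length(sols) == 1) return(sols[[1]])
  ## lower cost wins; ties prefer the cold start (deterministic)
  jc <- sols$cold$objective; jh <- sols$hot$objective
  best <- if (jh < jc - 1e-12) sols$hot else sols$cold
  other <- if (identical(best, sols$hot)) sols$cold else sols$hot
  best$alternatives <- list(guess = other$guess, objective = other$objective,
                            status = other$status,
                            iterations = other$iterations,
                            cot = other$cot)
  best
}

#' Mesh / tolerance / initial-guess convergence study
#'
#' Solves the fixture problem over a grid of mesh densities and initial
#' guesses, and over a set of convergence tolerances at the first mesh, and
#' tabulates iterations, objective and RMS trajectory differences against
#' the densest-mesh solution (states resampled to a common 101-point cycle
#' grid).
#'
#' @param m a `predgait_model`.
#' @param config base [ocp_config()].
#' @param meshes integer vector of mesh densities.
#' @param tols numeric vector of NLP tolerances.
#' @param guesses character vector among "cold", "hot".
#' @param ref optional reference gait (synthesized when NULL).
#' @return data.frame, one row per (mesh x guess) and per extra tolerance;
#'   column `rms_delta` is the mean RMS state difference to the
#'   densest-mesh solution of the same guess.
#' @export
convergence_study <- function(m, config, meshes = c(8, 12, 16),
                              tols = config$tol, guesses = c("cold", "hot"),
                              ref = NULL) {
  geom <- fit_all_muscles(m)
  if (is.null(ref)) ref <- make_reference_gait(seed = config$seed)
  rows <- list()
  sols <- list()
  for (gt in guesses) for (Nm in meshes) {
    cfg <- config; cfg$n_mesh <- as.integer(Nm)
    sol <- tryCatch(
      solve_gait(m, cfg, ref = ref, guess = gt, geom = geom),
      error = function(e) NULL)
    key <- paste(gt, Nm, sep = "_")
    sols[[key]] <- sol
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "mesh", guess = gt, n_mesh = Nm, tol = config$tol,
      status = if (is.null(sol)) "error" else sol$status,
      iterations = if (is.null(sol)) NA else sol$iterations,
      objective = if (is.null(sol)) NA else sol$objective,
      cot = if (is.null(sol)) NA else sol$cot)
  }
  for (tol in setdiff(tols, config$tol)) {
    cfg <- config; cfg$tol <- tol; cfg$n_mesh <- as.integer(meshes[1])
    sol <- tryCatch(
      solve_gait(m, cfg, ref = ref, guess = guesses[1], geom = geom),
      error = function(e) NULL)
    key <- paste("tol", tol, sep = "_")
    sols[[key]] <- sol
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "tol", guess = guesses[1], n_mesh = meshes[1], tol = tol,
      status = if (is.null(sol)) "error" else sol$status,
      iterations = if (is.null(sol)) NA else sol$iterations,
      objective = if (is.null(sol)) NA else sol$objective,
      cot = if (is.null(sol)) NA else sol$cot)
  }
  tab <- do.call(rbind, rows)
  ## RMS deltas against the densest mesh per guess
  tab$rms_delta <- NA_real_
  for (gt in guesses) {
    dense <- sols[[paste(gt, max(meshes), sep = "_")]]
    if (is.null(dense)) next
    for (Nm in meshes) {
      sol <- sols[[paste(gt, Nm, sep = "_")]]
      if (is.null(sol)) next
      dd <- sol$cycle_states - dense$cycle_states
      rms <- sqrt(rowMeans(dd^2))
      tab$rms_delta[tab$kind == "mesh" & tab$guess == gt &
                      tab$n_mesh == Nm] <- mean(rms)
    }
  }
  attr(tab, "solutions") <- sols
  tab
}
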