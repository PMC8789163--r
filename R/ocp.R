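## Direct-collocation transcription of the predictive gait problem.
##
## Decision variables: states x = [q; qdot; a; ftilde] at every mesh and
## collocation point of a half gait cycle, "slack" controls (coordinate
## accelerations u_a and tendon-force derivatives dft) at collocation
## points, muscle excitations e per mesh interval (piecewise constant), and
## the half-cycle duration t_f.  Constraints: 3-stage Radau IIA collocation
## defects, Hill muscle-tendon equilibrium and skeletal dynamics residuals
## at every collocation point, half-cycle periodicity through the
## left-right mirror map, and the prescribed-speed equality
## `tx(t_f) - tx(0) = v t_f`.  The objective is the squared-term effort/
## energy cost (metabolic rate, activations, accelerations, passive
## torques, arm-actuator excitations, all squared and normalized by
## distance) plus a small penalty on the remaining controls to avoid
## singular arcs.  All variables are affinely scaled to O(1).

#' Configuration of the gait optimal-control problem
#'
#' @param speed target gait speed (m/s), default 1.33.
#' @param n_mesh mesh intervals per half gait cycle (>= 4; full-scale studies use
#'   50-125, the desk-scale fixture default is 25).
#' @param tol convergence tolerance of the NLP solve (stationarity),
#'   default 1e-4.
#' @param feas_tol feasibility tolerance (max scaled constraint violation),
#'   default 1e-6.
#' @param weights named numeric vector of cost weights: `E` (metabolic
#'   rate squared, per W^2), `act` (muscle activations squared), `acc`
#'   (joint accelerations squared), `passive` (passive torques squared),
#'   `arm` (arm-actuator excitations squared) and `penalty` (singular-arc
#'   penalty on the remaining controls).  Each term is normalized by its
#'   count so the defaults put every term at O(1) on a typical gait.
#' @param tf_bounds bounds on the half-cycle duration (s).
#' @param tf_guess initial half-cycle duration for the cold start (s).
#' @param guess initial-guess policy for [solve_gait()]: "both", "cold" or
#'   "hot".
#' @param seed integer seed for any stochastic guess perturbation.
#' @param max_iter inner-iteration budget of the solver.
#' @param metab_b tanh sharpness of the smoothed metabolic model.
#' @param time_limit wall-clock limit for one NLP solve (s).
#' @param work_mode mechanical-work term of the metabolic model inside the
#'   cost: "signed" (eccentric work subtracts) or "positive" (clamped at
#'   zero).
#' @return an `ocp_config` list.
#' @export
ocp_config <- function(speed = 1.33, n_mesh = 25, tol = 1e-4,
                       feas_tol = 1e-6,
                       weights = c(E = 1e-3, act = 10, acc = 1e-3,
                                   passive = 1e-2, arm = 1, penalty = 1e-3),
                       tf_bounds = c(0.25, 0.8), tf_guess = 0.45,
                       guess = c("both", "cold", "hot"), seed = 0,
                       max_iter = 600, metab_b = 100, time_limit = 600,
                       work_mode = c("signed", "positive")) {
  stopifnot(n_mesh >= 4, tol > 0, all(weights >= 0), speed > 0)
  structure(list(speed = speed, n_mesh = as.integer(n_mesh), tol = tol,
                 feas_tol = feas_tol, weights = weights,
                 tf_bounds = tf_bounds, tf_guess = tf_guess,
                 guess = match.arg(guess), seed = seed,
                 max_iter = max_iter, metab_b = metab_b,
                 time_limit = time_limit, work_mode = match.arg(work_mode)),
            class = "ocp_config")
}

#' Closed-form size census of the transcription
#'
#' @param nq,nm numbers of coordinates and muscles.
#' @param N mesh intervals per half cycle.
#' @return list with `n_var`, `n_con` and a per-family breakdown.
#' @export
transcription_census <- function(nq, nm, N) {
  nx <- 2 * nq + 2 * nm
  P <- 3 * N
  list(n_var = nx * (P + 1) + nq * P + nm * P + nm * N + 1,
       n_con = nx * P + nm * P + nq * P + (nx - 1) + 1,
       breakdown = list(states = nx * (P + 1), accelerations = nq * P,
                        ft_derivatives = nm * P, excitations = nm * N,
                        duration = 1, defects = nx * P, hill = nm * P,
                        dynamics = nq * P, periodicity = nx - 1, speed = 1))
}

#' Transcribe the predictive gait problem
#'
#' Builds index maps, scaling, bounds and evaluation closures for the
#' nonlinear program; muscle geometry is fitted on the fly when not
#' supplied.
#'
#' @param m a `predgait_model`.
#' @param config an [ocp_config()].
#' @param geom optional pre-fitted [fit_all_muscles()] geometry.
#' @return a `gait_ocp` object.
#' @export
transcribe <- function(m, config, geom = NULL) {
  if (is.null(geom)) geom <- fit_all_muscles(m)
  nq <- length(m$coord_names)
  nm <- length(m$muscles)
  nx <- 2 * nq + 2 * nm
  N <- config$n_mesh
  P <- 3L * N
  ngrid <- P + 1L
  coeffs <- radau_coefficients(3)
  pv <- muscle_param_vectors(m)

  ## ---- variable indexing (z is in scaled units) ----
  iX <- matrix(seq_len(nx * ngrid), nx, ngrid)
  offUA <- nx * ngrid
  iUA <- matrix(offUA + seq_len(nq * P), nq, P)
  offDFT <- offUA + nq * P
  iDFT <- matrix(offDFT + seq_len(nm * P), nm, P)
  offE <- offDFT + nm * P
  iE <- matrix(offE + seq_len(nm * N), nm, N)
  itf <- offE + nm * N + 1L
  n_var <- itf

  qrows <- seq_len(nq); qdrows <- nq + seq_len(nq)
  arows <- 2 * nq + seq_len(nm); ftrows <- 2 * nq + nm + seq_len(nm)

  kind <- vapply(m$coordinates, `[[`, "", "kind")
  sx <- c(rep(1, nq), rep(10, nq), rep(1, nm), rep(1, nm))
  sua <- ifelse(kind == "rz", 300, 100)
  sdft <- 60
  stf <- 1

  ## ---- bounds (physical, then scaled) ----
  qlb <- vapply(m$coordinates, function(cc) cc$range[1], 0)
  qub <- vapply(m$coordinates, function(cc) cc$range[2], 0)
  qdlim <- ifelse(kind == "rz", 30, 6)
  xlb <- c(qlb, -qdlim, rep(0, nm), rep(0, nm))
  xub <- c(qub, qdlim, rep(1, nm), rep(2.5, nm))
  lb <- rep(0, n_var); ub <- rep(0, n_var)
  lb[as.vector(iX)] <- rep(xlb / sx, ngrid)
  ub[as.vector(iX)] <- rep(xub / sx, ngrid)
  lb[as.vector(iUA)] <- rep(-sua * 2 / sua, P)   # |u_a| <= 2 * scale
  ub[as.vector(iUA)] <- rep(sua * 2 / sua, P)
  lb[as.vector(iDFT)] <- -2; ub[as.vector(iDFT)] <- 2
  lb[as.vector(iE)] <- 0; ub[as.vector(iE)] <- 1
  lb[itf] <- config$tf_bounds[1] / stf; ub[itf] <- config$tf_bounds[2] / stf

  ## ---- stage bookkeeping ----
  p_int <- rep(seq_len(N), each = 3)       # interval of each stage
  p_stage <- rep(1:3, N)                   # stage within interval
  s0col <- 3L * (p_int - 1L) + 1L          # grid column of interval start
  bq <- coeffs$b[p_stage]                  # quadrature weight per stage

  ## ---- constraint indexing & row scales ----
  n_def <- nx * P
  offH <- n_def
  offD <- offH + nm * P
  offPer <- offD + nq * P
  per_rows <- setdiff(seq_len(nx), which(m$coord_names == "pelvis_tx"))
  offS <- offPer + length(per_rows)
  n_con <- offS + 1L
  sdyn <- 1 / 100

  mir <- symmetry_map(m)
  mmir <- muscle_symmetry_map(m)
  mir_x <- c(mir, nq + mir, 2 * nq + mmir, 2 * nq + nm + mmir)
  tx_idx <- which(m$coord_names == "pelvis_tx")

  pas_idx <- match(names(m$passive), m$coord_names)
  pas_keep <- !is.na(pas_idx)
  pas_idx <- pas_idx[pas_keep]
  pas_par <- m$passive[pas_keep]
  base_coords <- which(vapply(m$coordinates, function(cc)
    cc$kind != "rz" || grepl("tilt", cc$name), TRUE))
  acc_coords <- setdiff(seq_len(nq), base_coords)  # penalized accelerations

  ocp <- list(model = m, geom = geom, config = config, pv = pv,
              nq = nq, nm = nm, nx = nx, N = N, P = P, ngrid = ngrid,
              coeffs = coeffs, iX = iX, iUA = iUA, iDFT = iDFT, iE = iE,
              itf = itf, n_var = n_var, n_con = n_con,
              qrows = qrows, qdrows = qdrows, arows = arows,
              ftrows = ftrows, sx = sx, sua = sua, sdft = sdft, stf = stf,
              lb = lb, ub = ub, p_int = p_int, p_stage = p_stage,
              s0col = s0col, bq = bq, offH = offH, offD = offD,
              offPer = offPer, offS = offS, per_rows = per_rows,
              sdyn = sdyn, mir_x = mir_x, tx_idx = tx_idx,
              pas_idx = pas_idx, pas_par = pas_par,
              acc_coords = acc_coords,
              census = transcription_census(nq, nm, N))
  class(ocp) <- "gait_ocp"
  ocp
}

#' @export
print.gait_ocp <- function(x, ...) {
  cat(sprintf(
    "<gait OCP: %d mesh intervals, %d variables, %d constraints>\n",
    x$N, x$n_var, x$n_con))
  invisible(x)
}

## ---- unpacking -----------------------------------------------------------

ocp_unpack <- function(ocp, z) {
  X <- matrix(z[as.vector(ocp$iX)], ocp$nx, ocp$ngrid) * ocp$sx
  UA <- matrix(z[as.vector(ocp$iUA)], ocp$nq, ocp$P) * ocp$sua
  DFT <- matrix(z[as.vector(ocp$iDFT)], ocp$nm, ocp$P) * ocp$sdft
  E <- matrix(z[as.vector(ocp$iE)], ocp$nm, ocp$N)
  tf <- z[ocp$itf] * ocp$stf
  list(X = X, UA = UA, DFT = DFT, E = E, tf = tf,
       Q = X[ocp$qrows, , drop = FALSE], QD = X[ocp$qdrows, , drop = FALSE],
       A = X[ocp$arows, , drop = FALSE], FT = X[ocp$ftrows, , drop = FALSE])
}

ocp_pack <- function(ocp, X, UA, DFT, E, tf) {
  z <- numeric(ocp$n_var)
  z[as.vector(ocp$iX)] <- as.vector(X / ocp$sx)
  z[as.vector(ocp$iUA)] <- as.vector(UA / ocp$sua)
  z[as.vector(ocp$iDFT)] <- as.vector(DFT / ocp$sdft)
  z[as.vector(ocp$iE)] <- as.vector(E)
  z[ocp$itf] <- tf / ocp$stf
  z
}

## ---- pointwise physics helpers ------------------------------------------

## Muscle geometry over stage columns: lengths, velocities, moment arms.
ocp_mtu <- function(ocp, Q, QD) {
  nm <- ocp$nm; P <- ncol(Q)
  LMT <- matrix(0, nm, P); VMT <- matrix(0, nm, P)
  R <- vector("list", nm)
  for (i in seq_len(nm)) {
    g <- ocp$geom$muscles[[i]]
    ev <- mtu_eval(g, Q, arms = TRUE)
    LMT[i, ] <- ev$len
    R[[i]] <- ev$R
    VMT[i, ] <- -colSums(ev$R * QD[g$coord_idx, , drop = FALSE])
  }
  list(LMT = LMT, VMT = VMT, R = R)
}

## cheap velocity-only update of a cached geometry evaluation (moment arms
## and lengths depend on Q alone)
ocp_mtu_vel <- function(ocp, mtu, QD) {
  for (i in seq_len(ocp$nm)) {
    ci <- ocp$geom$muscles[[i]]$coord_idx
    mtu$VMT[i, ] <- -colSums(mtu$R[[i]] * QD[ci, , drop = FALSE])
  }
  mtu
}

ocp_muscle_torques <- function(ocp, R, FTN) {
  tau <- matrix(0, ocp$nq, ncol(FTN))
  for (i in seq_len(ocp$nm)) {
    ci <- ocp$geom$muscles[[i]]$coord_idx
    for (jj in seq_along(ci))
      tau[ci[jj], ] <- tau[ci[jj], ] + R[[i]][jj, ] * FTN[i, ]
  }
  tau
}

ocp_passive <- function(ocp, Q, QD) {
  Tp <- matrix(0, ocp$nq, ncol(Q))
  for (jj in seq_along(ocp$pas_idx)) {
    j <- ocp$pas_idx[jj]
    Tp[j, ] <- passive_torque(Q[j, ], QD[j, ], ocp$pas_par[[jj]])
  }
  Tp
}

## d(passive torque)/dq and /dqdot (analytic)
ocp_passive_jac <- function(ocp, Q, QD) {
  dq <- matrix(0, ocp$nq, ncol(Q)); dqd <- matrix(0, ocp$nq, ncol(Q))
  for (jj in seq_along(ocp$pas_idx)) {
    j <- ocp$pas_idx[jj]; p <- ocp$pas_par[[jj]]
    dq[j, ] <- -p$k1 * p$k2 * exp(p$k2 * (p$q_lo - Q[j, ])) -
      p$k1 * p$k2 * exp(p$k2 * (Q[j, ] - p$q_hi)) - p$k_lin
    dqd[j, ] <- -p$damping
  }
  list(dq = dq, dqd = dqd)
}

## Scaled skeletal dynamics residual at the stage points.
ocp_dyn <- function(ocp, Q, QD, UA, FTN) {
  grf <- model_grf(ocp$model, Q, QD)
  mtu <- ocp_mtu(ocp, Q, QD)
  tau_m <- ocp_muscle_torques(ocp, mtu$R, FTN)
  Tp <- ocp_passive(ocp, Q, QD)
  res <- inverse_dynamics(ocp$model, Q, QD, UA, ext = grf$ext) -
    tau_m - Tp
  res * ocp$sdyn
}

## Hill residual at the stage points.
ocp_hill <- function(ocp, A, FT, Q, QD, DFT) {
  mtu <- ocp_mtu(ocp, Q, QD)
  hill_eval(A, FT, mtu$LMT, mtu$VMT, DFT, ocp$pv)$residual
}

## Per-muscle metabolic rate (W) at the stage points.
ocp_metab <- function(ocp, Estage, A, FT, Q, QD, DFT) {
  mtu <- ocp_mtu(ocp, Q, QD)
  hh <- hill_eval(A, FT, mtu$LMT, mtu$VMT, DFT, ocp$pv)
  bhargava_rate(Estage, A, hh$lm_tilde, hh$vm_tilde, hh$F_fiber_iso,
                hh$F_fiber_total, ocp$pv, mode = "smooth", work = ocp$config$work_mode,
                b = ocp$config$metab_b)$total
}

## State time-derivative at the stage points (for the defects).
ocp_fstate <- function(ocp, u, Estage) {
  rbind(u$X[ocp$qdrows, 2:(ocp$P + 1), drop = FALSE],
        u$UA,
        activation_dynamics(Estage, u$X[ocp$arows, 2:(ocp$P + 1),
                                        drop = FALSE]),
        u$DFT)
}

## ---- full evaluation -----------------------------------------------------

## Objective + constraints (cheap path, used by line searches).
ocp_fc <- function(ocp, z) {
  u <- ocp_unpack(ocp, z)
  P <- ocp$P
  Xc <- u$X[, 2:(P + 1), drop = FALSE]
  Qc <- Xc[ocp$qrows, , drop = FALSE]; QDc <- Xc[ocp$qdrows, , drop = FALSE]
  Ac <- Xc[ocp$arows, , drop = FALSE]; FTc <- Xc[ocp$ftrows, , drop = FALSE]
  Estage <- u$E[, ocp$p_int, drop = FALSE]
  h <- u$tf / ocp$N

  ## defects
  FF <- ocp_fstate(ocp, u, Estage)
  D <- Xc - u$X[, ocp$s0col, drop = FALSE]
  Amat <- ocp$coeffs$A
  for (k in 1:3) {
    pk <- which(ocp$p_stage == k)
    acc <- 0
    for (j in 1:3) acc <- acc + Amat[k, j] * FF[, pk - k + j, drop = FALSE]
    D[, pk] <- D[, pk] - h * acc
  }
  D <- D / ocp$sx

  ## path constraints
  mtu <- ocp_mtu(ocp, Qc, QDc)
  hh <- hill_eval(Ac, FTc, mtu$LMT, mtu$VMT, u$DFT, ocp$pv)
  FTN <- FTc * ocp$pv$F_max
  grf <- model_grf(ocp$model, Qc, QDc)
  tau_m <- ocp_muscle_torques(ocp, mtu$R, FTN)
  Tp <- ocp_passive(ocp, Qc, QDc)
  dyn <- (inverse_dynamics(ocp$model, Qc, QDc, u$UA, ext = grf$ext) -
            tau_m - Tp) * ocp$sdyn

  ## periodicity & speed
  per <- (u$X[ocp$per_rows, ocp$ngrid] -
            u$X[ocp$mir_x[ocp$per_rows], 1]) / ocp$sx[ocp$per_rows]
  spd <- u$X[ocp$tx_idx, ocp$ngrid] - u$X[ocp$tx_idx, 1] -
    ocp$config$speed * u$tf

  cvec <- c(as.vector(D), as.vector(hh$residual), as.vector(dyn), per, spd)

  ## objective
  met <- bhargava_rate(Estage, Ac, hh$lm_tilde, hh$vm_tilde, hh$F_fiber_iso,
                       hh$F_fiber_total, ocp$pv, mode = "smooth", work = ocp$config$work_mode,
                       b = ocp$config$metab_b)$total
  w <- ocp$config$weights
  cw <- ocp$bq / (ocp$N * ocp$config$speed)
  nj <- max(1L, length(ocp$acc_coords)); np <- max(1L, length(ocp$pas_idx))
  terms <- c(
    E = w[["E"]] * sum(cw * colSums(met^2)) / ocp$nm,
    act = w[["act"]] * sum(cw * colSums(Ac^2)) / ocp$nm,
    acc = w[["acc"]] *
      sum(cw * colSums(u$UA[ocp$acc_coords, , drop = FALSE]^2)) / nj,
    passive = w[["passive"]] *
      sum(cw * colSums(Tp[ocp$pas_idx, , drop = FALSE]^2)) / np,
    penalty = w[["penalty"]] *
      sum(cw * (colSums(Estage^2) + colSums((u$DFT / ocp$sdft)^2))) / ocp$nm)
  J <- sum(terms)

  list(f = J, c = cvec, u = u, met = met, hill = hh, grf = grf, Tp = Tp,
       mtu = mtu, terms = terms)
}

## Triplet accumulator.
trip_new <- function() new.env(parent = emptyenv())
trip_add <- function(tr, i, j, v) {
  n <- (tr$n %||% 0L) + 1L
  tr$i[[n]] <- i; tr$j[[n]] <- j; tr$v[[n]] <- v; tr$n <- n
}
trip_mat <- function(tr, nrow, ncol) {
  Matrix::sparseMatrix(i = unlist(tr$i), j = unlist(tr$j),
                       x = unlist(tr$v), dims = c(nrow, ncol))
}

## Add FD-derived entries for a block function: rows `off + (p-1)*nrb + r`,
## columns `colmat[s, p]`; dval is nrb x P derivative for slot s.
block_fd_entries <- function(tr, dval, off, nrb, cols, drop_tol = 0) {
  nz <- which(dval != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(invisible())
  p <- nz[, 2]
  trip_add(tr, off + (p - 1L) * nrb + nz[, 1], cols[p], dval[nz])
}

## Full evaluation with constraint Jacobian, gradient and Gauss-Newton
## Hessian (all in scaled variable space).
ocp_derivs <- function(ocp, z, fd_step = 1e-5, with_obj = TRUE,
                       fd_mode = c("central", "forward")) {
  fd_mode <- match.arg(fd_mode)
  base <- ocp_fc(ocp, z)
  u <- base$u
  P <- ocp$P; nx <- ocp$nx; nq <- ocp$nq; nm <- ocp$nm
  Xc <- u$X[, 2:(P + 1), drop = FALSE]
  Qc <- Xc[ocp$qrows, , drop = FALSE]; QDc <- Xc[ocp$qdrows, , drop = FALSE]
  Ac <- Xc[ocp$arows, , drop = FALSE]; FTc <- Xc[ocp$ftrows, , drop = FALSE]
  Estage <- u$E[, ocp$p_int, drop = FALSE]
  h <- u$tf / ocp$N
  Amat <- ocp$coeffs$A
  iXc <- ocp$iX[, 2:(P + 1), drop = FALSE]
  iX0 <- ocp$iX[, ocp$s0col, drop = FALSE]
  iEst <- ocp$iE[, ocp$p_int, drop = FALSE]

  tr <- trip_new()

  ## ---------------- defects (analytic) ----------------
  ## self and start entries
  for (r in seq_len(nx)) {
    rows <- (seq_len(P) - 1L) * nx + r
    trip_add(tr, rows, iXc[r, ], rep(1, P))
    trip_add(tr, rows, iX0[r, ], rep(-1, P))
  }
  ## state-derivative coupling: defect_k -= h * A[k, j] * F_j
  FF <- ocp_fstate(ocp, u, Estage)
  aj <- activation_dynamics_jac(Estage, Ac)
  for (k in 1:3) {
    pk <- which(ocp$p_stage == k)
    for (j in 1:3) {
      pj <- pk - k + j
      coef <- -h * Amat[k, j]
      ## q-rows <- qd state
      rows <- (pk - 1L) * nx
      trip_add(tr, rep(rows, each = nq) + ocp$qrows,
               as.vector(iXc[ocp$qdrows, pj, drop = FALSE]),
               rep(coef * ocp$sx[ocp$qdrows] / ocp$sx[ocp$qrows], times = length(pk)))
      ## qd-rows <- u_a
      trip_add(tr, rep(rows, each = nq) + ocp$qdrows,
               as.vector(ocp$iUA[, pj, drop = FALSE]),
               rep(coef * ocp$sua / ocp$sx[ocp$qdrows], times = length(pk)))
      ## a-rows <- a state and e
      trip_add(tr, rep(rows, each = nm) + ocp$arows,
               as.vector(iXc[ocp$arows, pj, drop = FALSE]),
               coef * as.vector(aj$da[, pj, drop = FALSE]))
      trip_add(tr, rep(rows, each = nm) + ocp$arows,
               as.vector(iEst[, pj, drop = FALSE]),
               coef * as.vector(aj$de[, pj, drop = FALSE]))
      ## ft-rows <- dft
      trip_add(tr, rep(rows, each = nm) + ocp$ftrows,
               as.vector(ocp$iDFT[, pj, drop = FALSE]),
               rep(coef * ocp$sdft / ocp$sx[ocp$ftrows], times = length(pk)))
    }
  }
  ## d(defect)/d(tf)
  dtf <- matrix(0, nx, P)
  for (k in 1:3) {
    pk <- which(ocp$p_stage == k)
    acc <- 0
    for (j in 1:3) acc <- acc + Amat[k, j] * FF[, pk - k + j, drop = FALSE]
    dtf[, pk] <- -acc / ocp$N
  }
  dtf <- (dtf / ocp$sx) * ocp$stf
  nzn <- which(dtf != 0, arr.ind = TRUE)
  if (nrow(nzn))
    trip_add(tr, (nzn[, 2] - 1L) * nx + nzn[, 1], rep(ocp$itf, nrow(nzn)),
             dtf[nzn])

  ## ---------------- hill & dynamics blocks (central FD) ----------------
  ## Each path constraint at a collocation point depends only on variables
  ## at that point, so one vectorized evaluation with a whole variable
  ## "slot" (e.g. q_3 at every point) displaced yields a full Jacobian
  ## stripe.  Muscle geometry and contact only depend on (q, qd): they are
  ## cached for the slots that cannot change them.
  mtu0 <- base$mtu
  grf0 <- base$grf
  forward <- fd_mode == "forward"
  hill0 <- matrix(base$c[(ocp$offH + 1):ocp$offD], nm, P)
  dyn0 <- matrix(base$c[(ocp$offD + 1):ocp$offPer], nq, P)
  dyn_fun <- function(Q, QD, UA, FT, grf = NULL, mtu = NULL) {
    if (is.null(grf)) grf <- model_grf(ocp$model, Q, QD)
    if (is.null(mtu)) mtu <- ocp_mtu(ocp, Q, QD)
    tau_m <- ocp_muscle_torques(ocp, mtu$R, FT * ocp$pv$F_max)
    Tp <- ocp_passive(ocp, Q, QD)
    (inverse_dynamics(ocp$model, Q, QD, UA, ext = grf$ext) - tau_m - Tp) *
      ocp$sdyn
  }
  hill_fun <- function(A, FT, Q, QD, DFT, mtu = NULL) {
    if (is.null(mtu)) mtu <- ocp_mtu(ocp, Q, QD)
    hill_eval(A, FT, mtu$LMT, mtu$VMT, DFT, ocp$pv)$residual
  }
  met_fun <- function(E, A, FT, Q, QD, DFT, mtu = NULL) {
    if (is.null(mtu)) mtu <- ocp_mtu(ocp, Q, QD)
    hh <- hill_eval(A, FT, mtu$LMT, mtu$VMT, DFT, ocp$pv)
    bhargava_rate(E, A, hh$lm_tilde, hh$vm_tilde, hh$F_fiber_iso,
                  hh$F_fiber_total, ocp$pv, mode = "smooth", work = ocp$config$work_mode,
                  b = ocp$config$metab_b)$total
  }
  hillmet_fun <- function(E, A, FT, Q, QD, DFT, mtu, want_met) {
    hh <- hill_eval(A, FT, mtu$LMT, mtu$VMT, DFT, ocp$pv)
    met <- if (want_met)
      bhargava_rate(E, A, hh$lm_tilde, hh$vm_tilde, hh$F_fiber_iso,
                    hh$F_fiber_total, ocp$pv, mode = "smooth", work = ocp$config$work_mode,
                    b = ocp$config$metab_b)$total else NULL
    list(hill = hh$residual, met = met)
  }
  met0 <- base$met

  ## metabolic-rate FD entries accumulate into the objective residual
  ## Jacobian (built below); metabolic rows come first in that stack
  trR <- trip_new()
  offR_E <- 0L

  dstep <- fd_step
  slot_defs <- list(
    list(kind = "q", n = nq), list(kind = "qd", n = nq),
    list(kind = "ua", n = nq), list(kind = "a", n = nm),
    list(kind = "ft", n = nm), list(kind = "dft", n = nm),
    list(kind = "e", n = nm))
  for (sd in slot_defs) {
    geom_fixed <- !(sd$kind %in% c("q", "qd"))
    mtu_c <- if (geom_fixed) mtu0 else NULL
    grf_c <- if (geom_fixed) grf0 else NULL
    for (s in seq_len(sd$n)) {
      sc <- switch(sd$kind,
                   q = ocp$sx[ocp$qrows[s]], qd = ocp$sx[ocp$qdrows[s]],
                   ua = ocp$sua[s], a = 1, ft = 1, dft = ocp$sdft, e = 1)
      hphys <- dstep * sc
      cols <- switch(sd$kind,
                     q = iXc[ocp$qrows[s], ], qd = iXc[ocp$qdrows[s], ],
                     ua = ocp$iUA[s, ], a = iXc[ocp$arows[s], ],
                     ft = iXc[ocp$ftrows[s], ], dft = ocp$iDFT[s, ],
                     e = iEst[s, ])
      pert <- function(d) {
        Q <- Qc; QD <- QDc; UA <- u$UA; A <- Ac; FT <- FTc
        DFT <- u$DFT; E <- Estage
        switch(sd$kind,
               q = { Q[s, ] <- Q[s, ] + d },
               qd = { QD[s, ] <- QD[s, ] + d },
               ua = { UA[s, ] <- UA[s, ] + d },
               a = { A[s, ] <- A[s, ] + d },
               ft = { FT[s, ] <- FT[s, ] + d },
               dft = { DFT[s, ] <- DFT[s, ] + d },
               e = { E[s, ] <- E[s, ] + d })
        list(Q = Q, QD = QD, UA = UA, A = A, FT = FT, DFT = DFT, E = E)
      }
      pp <- pert(hphys)
      pm <- if (forward) NULL else pert(-hphys)
      inv2h <- if (forward) 1 / dstep else 1 / (2 * dstep)
      if (geom_fixed) {
        mtu_p <- mtu_c; mtu_m <- mtu_c; grf_p <- grf_c; grf_m <- grf_c
      } else if (sd$kind == "qd") {
        ## moment arms/lengths depend on Q only: update velocities in place
        mtu_p <- ocp_mtu_vel(ocp, mtu0, pp$QD)
        grf_p <- model_grf(ocp$model, pp$Q, pp$QD)
        if (!forward) {
          mtu_m <- ocp_mtu_vel(ocp, mtu0, pm$QD)
          grf_m <- model_grf(ocp$model, pm$Q, pm$QD)
        }
      } else {
        mtu_p <- ocp_mtu(ocp, pp$Q, pp$QD)
        grf_p <- model_grf(ocp$model, pp$Q, pp$QD)
        if (!forward) {
          mtu_m <- ocp_mtu(ocp, pm$Q, pm$QD)
          grf_m <- model_grf(ocp$model, pm$Q, pm$QD)
        }
      }

      if (sd$kind %in% c("q", "qd", "ua", "ft")) {
        lo <- if (forward) dyn0 else
          dyn_fun(pm$Q, pm$QD, pm$UA, pm$FT, grf_m, mtu_m)
        dv <- (dyn_fun(pp$Q, pp$QD, pp$UA, pp$FT, grf_p, mtu_p) - lo) * inv2h
        block_fd_entries(tr, dv, ocp$offD, nq, cols)
      }
      if (sd$kind %in% c("a", "ft", "q", "qd", "dft")) {
        hm_p <- hillmet_fun(pp$E, pp$A, pp$FT, pp$Q, pp$QD, pp$DFT, mtu_p,
                            with_obj)
        hm_m <- if (forward) list(hill = hill0, met = met0) else
          hillmet_fun(pm$E, pm$A, pm$FT, pm$Q, pm$QD, pm$DFT, mtu_m,
                      with_obj)
        block_fd_entries(tr, (hm_p$hill - hm_m$hill) * inv2h, ocp$offH, nm,
                         cols)
        if (with_obj)
          block_fd_entries(trR, (hm_p$met - hm_m$met) * inv2h, offR_E, nm,
                           cols)
      } else if (with_obj && sd$kind == "e") {
        lo <- if (forward) met0 else
          met_fun(pm$E, pm$A, pm$FT, pm$Q, pm$QD, pm$DFT, mtu_m)
        dv <- (met_fun(pp$E, pp$A, pp$FT, pp$Q, pp$QD, pp$DFT, mtu_p) - lo) *
          inv2h
        block_fd_entries(trR, dv, offR_E, nm, cols)
      }
    }
  }

  ## ---------------- periodicity & speed (analytic) ----------------
  npr <- length(ocp$per_rows)
  trip_add(tr, ocp$offPer + seq_len(npr), ocp$iX[ocp$per_rows, ocp$ngrid],
           rep(1, npr))
  trip_add(tr, ocp$offPer + seq_len(npr),
           ocp$iX[ocp$mir_x[ocp$per_rows], 1], rep(-1, npr))
  trip_add(tr, rep(ocp$offS + 1L, 3),
           c(ocp$iX[ocp$tx_idx, ocp$ngrid], ocp$iX[ocp$tx_idx, 1], ocp$itf),
           c(ocp$sx[ocp$tx_idx], -ocp$sx[ocp$tx_idx],
             -ocp$config$speed * ocp$stf))

  JC <- trip_mat(tr, ocp$n_con, ocp$n_var)

  if (!with_obj)
    return(list(f = base$f, c = base$c, JC = JC, g = NULL, H = NULL,
                base = base))

  ## ---------------- objective residual Jacobian ----------------
  ## residual stack: [Edot (nm*P); a (nm*P); ua (nj*P); Tp (np*P);
  ##                  e (nm*P); dft (nm*P)]
  w <- ocp$config$weights
  cw <- ocp$bq / (ocp$N * ocp$config$speed)
  nj <- length(ocp$acc_coords); np <- length(ocp$pas_idx)
  nR <- nm * P + nm * P + nj * P + np * P + nm * P + nm * P
  offR_a <- nm * P; offR_ua <- offR_a + nm * P
  offR_tp <- offR_ua + nj * P; offR_e <- offR_tp + np * P
  offR_dft <- offR_e + nm * P

  rvec <- c(as.vector(met0), as.vector(Ac),
            as.vector(u$UA[ocp$acc_coords, , drop = FALSE]),
            as.vector(base$Tp[ocp$pas_idx, , drop = FALSE]),
            as.vector(Estage), as.vector(u$DFT / ocp$sdft))
  wvec <- c(rep(cw, each = nm) * w[["E"]] / nm,
            rep(cw, each = nm) * w[["act"]] / nm,
            rep(cw, each = nj) * w[["acc"]] / max(1L, nj),
            rep(cw, each = np) * w[["passive"]] / max(1L, np),
            rep(cw, each = nm) * w[["penalty"]] / nm,
            rep(cw, each = nm) * w[["penalty"]] / nm)

  ## direct (identity-like) entries
  for (s in seq_len(nm)) {
    rows <- offR_a + (seq_len(P) - 1L) * nm + s
    trip_add(trR, rows, iXc[ocp$arows[s], ], rep(1, P))
    rows <- offR_e + (seq_len(P) - 1L) * nm + s
    trip_add(trR, rows, iEst[s, ], rep(1, P))
    rows <- offR_dft + (seq_len(P) - 1L) * nm + s
    trip_add(trR, rows, ocp$iDFT[s, ], rep(1, P))
  }
  for (jj in seq_along(ocp$acc_coords)) {
    s <- ocp$acc_coords[jj]
    rows <- offR_ua + (seq_len(P) - 1L) * nj + jj
    trip_add(trR, rows, ocp$iUA[s, ], rep(ocp$sua[s], P))
  }
  ## passive-torque rows (analytic)
  pj <- ocp_passive_jac(ocp, Qc, QDc)
  for (jj in seq_along(ocp$pas_idx)) {
    s <- ocp$pas_idx[jj]
    rows <- offR_tp + (seq_len(P) - 1L) * np + jj
    trip_add(trR, rows, iXc[ocp$qrows[s], ],
             pj$dq[s, ] * ocp$sx[ocp$qrows[s]])
    trip_add(trR, rows, iXc[ocp$qdrows[s], ],
             pj$dqd[s, ] * ocp$sx[ocp$qdrows[s]])
  }
  JR <- trip_mat(trR, nR, ocp$n_var)

  g <- as.numeric(2 * Matrix::crossprod(JR, wvec * rvec))
  H <- 2 * Matrix::crossprod(sqrt(wvec) * JR)

  list(f = base$f, c = base$c, JC = JC, g = g, H = H, base = base)
}
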