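## Muscle-tendon geometry.
##
## Muscle paths are via-point polylines fixed in segment frames.  The exact
## muscle-tendon length at a posture comes from forward kinematics; for use
## inside the optimal-control problem each muscle's length is approximated
## by a multivariate polynomial in the joint angles it spans, fitted jointly
## to length and moment-arm samples so the identity r_j = -d l_MT / d q_j
## holds exactly by construction.  Muscle-tendon velocity follows by the
## chain rule, l_MT_dot = -sum_j r_j qdot_j.

#' Exact muscle-tendon path length
#'
#' Sum of straight-line distances between consecutive path points placed by
#' forward kinematics.
#'
#' @param m a `predgait_model`.
#' @param muscle a muscle definition from the model (or its name).
#' @param Q `nq x P` coordinate matrix.
#' @return P-vector of path lengths (m).
#' @export
mtu_path_length <- function(m, muscle, Q) {
  if (is.character(muscle)) {
    nm <- vapply(m$muscles, `[[`, "", "name")
    muscle <- m$muscles[[match(muscle, nm)]]
  }
  fk <- forward_kinematics(m, Q)
  pts <- lapply(muscle$path, function(pp) fk_point(fk, pp$segment, pp$point))
  len <- 0
  for (i in seq_len(length(pts) - 1L)) {
    dx <- pts[[i + 1L]]$x - pts[[i]]$x
    dy <- pts[[i + 1L]]$y - pts[[i]]$y
    len <- len + sqrt(dx * dx + dy * dy)
  }
  len
}

## Exact moment arms by central finite difference of the exact path length,
## r_j = -d l / d q_j.  The independent geometric "oracle" used to build the
## polynomial fit samples.
mtu_exact_moment_arms <- function(m, muscle, Q, coord_idx, h = 1e-6) {
  R <- matrix(0, length(coord_idx), ncol(Q))
  for (jj in seq_along(coord_idx)) {
    Qp <- Q; Qp[coord_idx[jj], ] <- Qp[coord_idx[jj], ] + h
    Qm <- Q; Qm[coord_idx[jj], ] <- Qm[coord_idx[jj], ] - h
    R[jj, ] <- -(mtu_path_length(m, muscle, Qp) -
                 mtu_path_length(m, muscle, Qm)) / (2 * h)
  }
  R
}

## Which coordinates a muscle path actually spans: numerically probe the
## sensitivity of the path length to each hinge coordinate.
muscle_spanned_coords <- function(m, muscle, n_probe = 3, tol = 1e-9) {
  nq <- length(m$coord_names)
  ## deterministic probe postures; coordinates the length is insensitive to
  ## (base pose, joints outside the path) are dropped
  Q0 <- matrix(0.3 * sin(outer(seq_len(nq) * 1.7, seq_len(n_probe) * 2.3)),
               nq, n_probe)
  l0 <- mtu_path_length(m, muscle, Q0)
  spanned <- integer(0)
  for (j in seq_len(nq)) {
    Qp <- Q0; Qp[j, ] <- Qp[j, ] + 1e-4
    if (max(abs(mtu_path_length(m, muscle, Qp) - l0)) > tol)
      spanned <- c(spanned, j)
  }
  spanned
}

## Monomial exponent grid for `ncoord` variables with per-coordinate order
## `order` and total degree <= `total`.
poly_exponents <- function(ncoord, order, total = order) {
  grids <- rep(list(0:order), ncoord)
  ex <- as.matrix(expand.grid(grids))
  ex <- ex[rowSums(ex) <= total, , drop = FALSE]
  dimnames(ex) <- NULL
  ex
}

#' Fit a polynomial muscle-tendon length model
#'
#' Least-squares fit of the muscle-tendon length jointly with its gradient:
#' moment-arm samples enter the fit as derivative observations, so the
#' returned geometry satisfies `r_j = -d l_MT / d q_j` exactly by
#' construction (the moment arm IS minus the polynomial gradient).
#'
#' @param samples list with `Q` (`ncoord x S` matrix of coordinate samples),
#'   `lmt` (S-vector of lengths, m) and `R` (`ncoord x S` moment arms, m).
#' @param order maximum polynomial order per coordinate.
#' @param total maximum total degree (default `order`).
#' @param coord_idx global coordinate indices of the fitted coordinates.
#' @param name muscle name carried through for diagnostics.
#' @return an `mtu_geometry` list: exponents, coefficients, fit domain and
#'   residual statistics.
#' @export
fit_polynomials <- function(samples, order = 5, total = order,
                            coord_idx = seq_len(nrow(samples$Q)),
                            name = "muscle") {
  Q <- samples$Q
  ncoord <- nrow(Q); S <- ncol(Q)
  ex <- poly_exponents(ncoord, order, total)
  nterm <- nrow(ex)
  if (S * (ncoord + 1) < 10 * nterm)
    config_error("'%s': need >= 10x more samples than coefficients", name)
  basis <- matrix(1, S, nterm)
  for (j in seq_len(ncoord))
    basis <- basis * t(outer(ex[, j], Q[j, ], function(e, q) q^e))
  rows <- list(basis)
  for (j in seq_len(ncoord)) {
    db <- matrix(0, S, nterm)
    for (t in seq_len(nterm)) {
      e <- ex[t, ]
      if (e[j] == 0) next
      v <- e[j] * Q[j, ]^(e[j] - 1)
      for (j2 in setdiff(seq_len(ncoord), j)) v <- v * Q[j2, ]^(e[j2])
      db[, t] <- v
    }
    rows[[j + 1L]] <- db  # derivative observations: r_j = -d l/d q_j
  }
  X <- do.call(rbind, rows)
  y <- c(samples$lmt, as.vector(t(-samples$R)))
  qrX <- qr(X)
  if (qrX$rank < nterm)
    config_error("'%s': ill-conditioned polynomial design matrix (rank %d < %d)",
                 name, qrX$rank, nterm)
  coef <- qr.coef(qrX, y)
  resid <- X %*% coef - y
  structure(list(
    name = name, coord_idx = coord_idx, expo = ex, coef = as.numeric(coef),
    order = order,
    domain = t(apply(Q, 1, range)),
    max_len_resid = max(abs(resid[seq_len(S)])),
    max_arm_resid = max(abs(resid[-seq_len(S)]))
  ), class = "mtu_geometry")
}

## One-pass evaluation of the length polynomial and (optionally) its
## gradient, with power tables so no `^` is evaluated in the inner loop.
mtu_eval <- function(g, Q, arms = TRUE) {
  Qs <- Q[g$coord_idx, , drop = FALSE]
  nc <- nrow(Qs); P <- ncol(Qs)
  maxe <- apply(g$expo, 2, max)
  pw <- vector("list", nc)
  for (j in seq_len(nc)) {
    pj <- vector("list", maxe[j] + 1L)
    pj[[1]] <- rep(1, P)
    if (maxe[j] >= 1) {
      pj[[2]] <- Qs[j, ]
      for (e in seq_len(maxe[j] - 1L)) pj[[e + 2L]] <- pj[[e + 1L]] * Qs[j, ]
    }
    pw[[j]] <- pj
  }
  len <- rep(0, P)
  R <- if (arms) matrix(0, nc, P) else NULL
  for (t in seq_len(nrow(g$expo))) {
    e <- g$expo[t, ]
    v <- rep(g$coef[t], P)
    for (j in seq_len(nc)) if (e[j] > 0) v <- v * pw[[j]][[e[j] + 1L]]
    len <- len + v
    if (arms) for (j in seq_len(nc)) {
      if (e[j] == 0) next
      vv <- rep(-g$coef[t] * e[j], P)
      for (j2 in seq_len(nc)) {
        ee <- e[j2] - (j2 == j)
        if (ee > 0) vv <- vv * pw[[j2]][[ee + 1L]]
      }
      R[j, ] <- R[j, ] + vv
    }
  }
  list(len = len, R = R)
}

#' Polynomial muscle-tendon length
#'
#' @param g an `mtu_geometry` fit.
#' @param Q full `nq x P` coordinate matrix (the fitted coordinates are
#'   selected by the geometry's `coord_idx`).
#' @return P-vector of lengths (m).
#' @export
mtu_length <- function(g, Q) mtu_eval(g, Q, arms = FALSE)$len

#' Polynomial moment arms
#'
#' `r_j(q) = -d l_MT / d q_j`, evaluated analytically from the fitted
#' coefficients.
#'
#' @inheritParams mtu_length
#' @return `ncoord x P` matrix of moment arms (m) for the spanned
#'   coordinates, in `g$coord_idx` order.
#' @export
mtu_moment_arms <- function(g, Q) mtu_eval(g, Q, arms = TRUE)$R

#' Muscle-tendon lengthening velocity
#'
#' Chain rule on the fitted length polynomial: `v_MT = -sum_j r_j qdot_j`.
#'
#' @inheritParams mtu_length
#' @param QD `nq x P` coordinate velocity matrix.
#' @return P-vector of velocities (m/s).
#' @export
mtu_velocity <- function(g, Q, QD) {
  R <- mtu_moment_arms(g, Q)
  -colSums(R * QD[g$coord_idx, , drop = FALSE])
}

#' Fit polynomial geometry for every muscle of a model
#'
#' Samples each muscle's exact via-point path on a tensor grid over the
#' ranges of the coordinates it spans and fits length + moment-arm
#' polynomials.
#'
#' @param m a `predgait_model`.
#' @param order maximum per-coordinate polynomial order.
#' @param n_grid grid points per spanned coordinate.
#' @return a `predgait_geometry` list with one `mtu_geometry` per muscle.
#' @export
fit_all_muscles <- function(m, order = 5, n_grid = 12) {
  muscles <- lapply(m$muscles, function(mus) {
    ci <- muscle_spanned_coords(m, mus)
    if (length(ci) == 0) config_error("muscle '%s' spans no coordinate",
                                      mus$name)
    ## enough samples for the 10x observations-per-coefficient rule
    nterm <- nrow(poly_exponents(length(ci), order))
    n_grid <- max(n_grid,
                  ceiling((10 * nterm / (length(ci) + 1))^(1 / length(ci))))
    ranges <- lapply(ci, function(j) {
      r <- m$coordinates[[j]]$range
      seq(r[1], r[2], length.out = n_grid)
    })
    grid <- as.matrix(expand.grid(ranges))
    nq <- length(m$coord_names)
    Q <- matrix(0, nq, nrow(grid))
    Q[ci, ] <- t(grid)
    lmt <- mtu_path_length(m, mus, Q)
    R <- mtu_exact_moment_arms(m, mus, Q, ci)
    fit_polynomials(list(Q = Q[ci, , drop = FALSE], lmt = lmt, R = R),
                    order = order, coord_idx = ci, name = mus$name)
  })
  structure(list(nq = length(m$coord_names), muscles = muscles,
                 order = order, n_grid = n_grid),
            class = "predgait_geometry")
}
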