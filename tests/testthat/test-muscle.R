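# Hill equilibrium and the polynomial muscle geometry.

test_that("rigid-tendon limit recovers l_M = l_MT - l_T_slack", {
  p <- muscle_params("test", F_max = 1000, l_opt = 0.1, l_slack = 0.25)
  p$k <- 2000; p$shift <- tendon_shift(2000)
  lmt <- 0.25 + 0.1 * 1.05
  ft <- hill_solve_ft(0.5, lmt, 0, p)
  hh <- hill_equilibrium(0.5, lmt, 0, ft, p)
  expect_equal(hh$lm_tilde * 0.1, lmt - 0.25, tolerance = 0.01)
})

test_that("equilibrium residual substitution identities hold", {
  p <- muscle_params("test", F_max = 1000, l_opt = 0.1, l_slack = 0.25,
                     alpha_opt = 0.1)
  # a = 0, isometric: residual = ft - (passive + beta*vm)*cos(alpha)
  ft <- 0.1
  lt <- tendon_length(ft)
  lmt <- 0.25 * lt + 0.1 * cos(0.1) # fiber at optimum projection
  hh <- hill_equilibrium(0, lmt, 0, ft, p, beta = 0)
  expect_equal(hh$residual,
               ft - passive_fl(hh$lm_tilde) * hh$cos_alpha,
               tolerance = 1e-12)
  expect_equal(hh$F_tendon, ft * 1000)
  # pennation: constant-thickness rule
  expect_equal(hh$lm_tilde * sin(acos(hh$cos_alpha)), sin(0.1),
               tolerance = 1e-9)
})

test_that("bisection root of the residual matches a brute-force solver", {
  p <- muscle_params("m", F_max = 2000, l_opt = 0.09, l_slack = 0.3)
  set.seed(5)
  for (i in 1:8) {
    a <- runif(1, 0.05, 1)
    lmt <- 0.3 + 0.09 * runif(1, 0.7, 1.25)
    ft <- hill_solve_ft(a, lmt, 0, p)
    # brute force: dense scan for the sign change
    grid <- seq(-0.1, 2.5, length.out = 20001)
    r <- hill_eval(a, grid, lmt, 0, 0,
                   list(F_max = p$F_max, l_opt = p$l_opt,
                        l_slack = p$l_slack, alpha_opt = p$alpha_opt,
                        v_max = p$v_max, k = p$k, shift = p$shift))$residual
    i0 <- which(diff(sign(r)) != 0)[1]
    # the root lies inside the bracketing cell of the dense scan
    expect_gte(ft, grid[i0] - 1e-12)
    expect_lte(ft, grid[i0 + 1] + 1e-12)
    expect_equal(hill_equilibrium(a, lmt, 0, ft, p)$residual, 0,
                 tolerance = 1e-9)
  }
})

test_that("domain violation raises a classed error", {
  p <- muscle_params("m", F_max = 1000, l_opt = 0.1, l_slack = 0.25)
  expect_error(hill_equilibrium(0.5, 0.24, 0, 0.5, p),
               class = "predgait_domain_error")
})

test_that("linear path polynomial fit is exact and arms are analytic gradients", {
  # manufactured single-joint muscle with constant moment arm r
  r <- 0.04; l0 <- 0.3
  q <- seq(-1, 1, length.out = 60)
  samples <- list(Q = matrix(q, 1), lmt = l0 - r * q, R = matrix(r, 1, 60))
  g <- fit_polynomials(samples, order = 3, coord_idx = 5L, name = "lin")
  Q <- matrix(0, 11, 7); Q[5, ] <- seq(-0.9, 0.9, length.out = 7)
  expect_equal(mtu_length(g, Q), l0 - r * Q[5, ], tolerance = 1e-10)
  expect_equal(as.numeric(mtu_moment_arms(g, Q)), rep(r, 7),
               tolerance = 1e-10)
})

test_that("fitted gastrocnemius geometry reproduces the exact path", {
  m <- fixture_model()
  geom <- fixture_geom()
  i <- which(vapply(m$muscles, `[[`, "", "name") == "gastroc_r")
  g <- geom$muscles[[i]]
  expect_lt(g$max_len_resid, 1e-3)      # < 1 mm over the fit grid
  # off-grid check against the exact via-point path length
  set.seed(9)
  Q <- matrix(0, 11, 20)
  Q[g$coord_idx, ] <- rbind(runif(20, -1.8, 0.05), runif(20, -0.7, 0.5))
  expect_lt(max(abs(mtu_length(g, Q) - mtu_path_length(m, m$muscles[[i]], Q))),
            1.5e-3)
  # moment arm equals minus the gradient of the fitted length everywhere
  h <- 1e-6
  R <- mtu_moment_arms(g, Q)
  for (jj in seq_along(g$coord_idx)) {
    Qp <- Q; Qp[g$coord_idx[jj], ] <- Qp[g$coord_idx[jj], ] + h
    Qm <- Q; Qm[g$coord_idx[jj], ] <- Qm[g$coord_idx[jj], ] - h
    fd <- -(mtu_length(g, Qp) - mtu_length(g, Qm)) / (2 * h)
    expect_lt(max(abs(fd - R[jj, ])), 1e-8)
  }
})

test_that("polynomial fit refuses under-determined designs", {
  q <- seq(-1, 1, length.out = 8)
  samples <- list(Q = matrix(q, 1), lmt = 0.3 - 0.04 * q,
                  R = matrix(0.04, 1, 8))
  expect_error(fit_polynomials(samples, order = 5),
               class = "predgait_config_error")
})

test_that("mtu velocity follows the chain rule", {
  geom <- fixture_geom()
  g <- geom$muscles[[7]]
  set.seed(13)
  Q <- matrix(0, 11, 5); QD <- matrix(0, 11, 5)
  Q[g$coord_idx, ] <- runif(10, -0.5, 0.2)
  QD[g$coord_idx, ] <- runif(10, -2, 2)
  v <- mtu_velocity(g, Q, QD)
  h <- 1e-7
  fd <- (mtu_length(g, Q + h * QD) - mtu_length(g, Q - h * QD)) / (2 * h)
  expect_equal(v, fd, tolerance = 1e-6)
})
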