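# Rigid-body dynamics against the closed-form double-pendulum oracle, mass
# matrix structure, muscle joint torques and actuator dynamics.

test_that("inverse dynamics matches the closed-form double pendulum", {
  dp <- double_pendulum()
  set.seed(7)
  for (i in 1:10) {
    q <- runif(2, -2, 2); qd <- runif(2, -3, 3); qdd <- runif(2, -5, 5)
    tau <- as.numeric(inverse_dynamics(dp, matrix(q), matrix(qd),
                                       matrix(qdd)))
    expect_equal(tau, double_pendulum_tau(q, qd, qdd), tolerance = 1e-10)
  }
})

test_that("mass matrix is symmetric positive definite and the residual is linear in u_a", {
  m <- fixture_model()
  set.seed(11)
  q <- runif(11, -0.3, 0.3); q[2] <- 0.95
  M <- mass_matrix(m, q)
  expect_lt(max(abs(M - t(M))), 1e-9)
  expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
  # residual linearity: finite difference of the residual in u_a equals M
  qd <- runif(11, -1, 1)
  r0 <- inverse_dynamics(m, matrix(q), matrix(qd), matrix(0, 11, 1))
  for (j in c(1, 4, 7)) {
    e <- rep(0, 11); e[j] <- 1
    r1 <- inverse_dynamics(m, matrix(q), matrix(qd), matrix(e))
    expect_equal(as.numeric(r1 - r0), M[, j], tolerance = 1e-8)
  }
})

test_that("passive unactuated swing conserves mechanical energy", {
  dp <- double_pendulum()
  x0 <- c(0.4, -0.2, 0, 0)
  f <- function(x) c(x[3:4],
                     model_accelerations(dp, x[1:2], x[3:4]))
  E0 <- double_pendulum_energy(x0[1:2], x0[3:4])
  x1 <- rk4(f, x0, 1, 2000)
  E1 <- double_pendulum_energy(x1[1:2], x1[3:4])
  expect_lt(abs(E1 - E0), 1e-6)
})

test_that("muscle joint torques follow the moment arms", {
  m <- fixture_model()
  geom <- fixture_geom()
  nmu <- length(m$muscles)
  Q <- matrix(0, 11, 3)
  Q[4, ] <- c(0.1, 0.3, -0.2); Q[5, ] <- c(-0.3, -0.5, -0.1)
  # zero forces -> zero torques
  expect_equal(muscle_joint_torques(Q, matrix(0, nmu, 3), geom),
               matrix(0, 11, 3))
  # single muscle: torque = r * F on the spanned coordinates only
  FT <- matrix(0, nmu, 3); FT[5, ] <- 1000   # vasti_r (knee only)
  tau <- muscle_joint_torques(Q, FT, geom)
  g5 <- geom$muscles[[5]]
  R <- mtu_moment_arms(g5, Q)
  expect_equal(tau[g5$coord_idx, ], R[1, ] * 1000)
  expect_equal(sum(abs(tau[-g5$coord_idx, ])), 0)
  # toes receive no muscle torque from any muscle
  FTall <- matrix(1000, nmu, 3)
  tau_all <- muscle_joint_torques(Q, FTall, geom)
  mtp <- grep("^mtp", m$coord_names)
  expect_equal(sum(abs(tau_all[mtp, ])), 0)
  # virtual-work oracle: tau_j = -d(sum FT * lmt)/dq_j
  set.seed(3)
  q <- runif(11, -0.2, 0.2)
  ftv <- runif(nmu, 0, 2000)
  tau1 <- muscle_joint_torques(matrix(q), matrix(ftv), geom)
  h <- 1e-6
  for (j in c(4, 5, 6)) {
    qp <- q; qp[j] <- qp[j] + h; qm <- q; qm[j] <- qm[j] - h
    W <- function(qq) sum(ftv * vapply(geom$muscles, function(g)
      mtu_length(g, matrix(qq)), 0))
    expect_equal(tau1[j, 1], -(W(qp) - W(qm)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("torque actuator is a first-order lag", {
  # fixed point at saturation
  expect_equal(torque_actuator_dynamics(1, 100, 100), 0)
  # zero input decays exponentially; step response hits 63.2% at t = tau
  tau_c <- 0.035
  T <- 0; h <- 1e-4
  for (t in seq(h, tau_c, by = h))
    T <- T + h * torque_actuator_dynamics(1, T, 100, tau_c)
  expect_equal(T / 100, 1 - exp(-1), tolerance = 1e-2)
})
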