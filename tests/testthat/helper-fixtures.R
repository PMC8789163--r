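# Shared fixtures and a per-run cache so expensive objects (fixture model,
# fitted geometry, gait solves) are built once per test session.

# Internal helpers exercised directly by the tests.
hill_eval <- predgait:::hill_eval
activation_dynamics_jac <- predgait:::activation_dynamics_jac
maintenance_fl <- predgait:::maintenance_fl
count_grf_humps <- predgait:::count_grf_humps
stance_window <- predgait:::stance_window
solution_metrics <- predgait:::solution_metrics
solve_alm <- predgait:::solve_alm
ocp_fc <- predgait:::ocp_fc
ocp_derivs <- predgait:::ocp_derivs
ocp_unpack <- predgait:::ocp_unpack
ocp_pack <- predgait:::ocp_pack
forward_kinematics <- predgait:::forward_kinematics
fk_point <- predgait:::fk_point
periodic_resample <- predgait:::periodic_resample

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture_model <- function() cached("fixture", make_planar_fixture())
fixture_geom <- function() cached("geom", fit_all_muscles(fixture_model()))
fixture_ref <- function() cached("ref", make_reference_gait(seed = 0))

# Two-link pendulum (hinges about z, frames pointing -y), with hand-derived
# closed-form dynamics used as the independent oracle.
double_pendulum <- function() {
  seg <- data.frame(name = c("link1", "link2"), mass = c(2, 1.5),
                    inertia = c(0.05, 0.03), length = c(0.5, 0.4),
                    com_x = c(0, 0), com_y = c(-0.25, -0.2))
  joints <- list(
    list(name = "j1", type = "hinge", parent = "ground", child = "link1",
         loc_parent = c(0, 0), coords = "q1", range = list(c(-pi, pi))),
    list(name = "j2", type = "hinge", parent = "link1", child = "link2",
         loc_parent = c(0, -0.5), coords = "q2", range = list(c(-pi, pi))))
  model_spec("double_pendulum", seg, joints)
}

# Closed-form M(q) qdd + C(q, qd) + G(q) for the double pendulum above
# (angles measured from straight down; q2 relative to link 1).
double_pendulum_tau <- function(q, qd, qdd) {
  m1 <- 2; m2 <- 1.5; I1 <- 0.05; I2 <- 0.03
  l1 <- 0.5; c1 <- 0.25; c2 <- 0.2; g <- 9.81
  M11 <- I1 + I2 + m1 * c1^2 + m2 * (l1^2 + c2^2 + 2 * l1 * c2 * cos(q[2]))
  M12 <- I2 + m2 * (c2^2 + l1 * c2 * cos(q[2]))
  M22 <- I2 + m2 * c2^2
  C1 <- -m2 * l1 * c2 * sin(q[2]) * (2 * qd[1] * qd[2] + qd[2]^2)
  C2 <- m2 * l1 * c2 * sin(q[2]) * qd[1]^2
  G1 <- (m1 * c1 + m2 * l1) * g * sin(q[1]) + m2 * c2 * g * sin(q[1] + q[2])
  G2 <- m2 * c2 * g * sin(q[1] + q[2])
  c(M11 * qdd[1] + M12 * qdd[2] + C1 + G1,
    M12 * qdd[1] + M22 * qdd[2] + C2 + G2)
}

# Double-pendulum total mechanical energy.
double_pendulum_energy <- function(q, qd) {
  m1 <- 2; m2 <- 1.5; I1 <- 0.05; I2 <- 0.03
  l1 <- 0.5; c1 <- 0.25; c2 <- 0.2; g <- 9.81
  w1 <- qd[1]; w2 <- qd[1] + qd[2]
  th1 <- q[1]; th2 <- q[1] + q[2]
  p1 <- c(c1 * sin(th1), -c1 * cos(th1))
  pj <- c(l1 * sin(th1), -l1 * cos(th1))
  p2 <- pj + c(c2 * sin(th2), -c2 * cos(th2))
  v1 <- w1 * c(-p1[2], p1[1])
  v2 <- w1 * c(-pj[2], pj[1]) + w2 * c(-(p2[2] - pj[2]), p2[1] - pj[1])
  0.5 * m1 * sum(v1^2) + 0.5 * I1 * w1^2 + 0.5 * m2 * sum(v2^2) +
    0.5 * I2 * w2^2 + m1 * g * p1[2] + m2 * g * p2[2]
}

# Forward-dynamics accelerations from the package's implicit residual:
# solve M qdd = tau_applied - bias via the residual's linearity in qdd.
model_accelerations <- function(m, q, qd, tau = 0) {
  nq <- length(q)
  r0 <- inverse_dynamics(m, matrix(q), matrix(qd), matrix(0, nq, 1))
  M <- mass_matrix(m, q)
  solve(M, tau - as.numeric(r0))
}

# Small RK4 integrator used by conservation checks (fixed step).
rk4 <- function(f, x0, t1, n) {
  h <- t1 / n
  x <- x0
  for (i in seq_len(n)) {
    k1 <- f(x); k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2); k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
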