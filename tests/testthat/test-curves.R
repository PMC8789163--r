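# Muscle-tendon characteristic curves and activation dynamics.

test_that("tendon law matches its algebraic inversion and derived values", {
  # direct evaluations derived by inverting the exponential law by hand
  expect_equal(tendon_force(0.995, 35, 0), -0.05, tolerance = 1e-12)
  expect_equal(tendon_force(1, 35, 0), 0.2 * exp(0.175) - 0.25,
               tolerance = 1e-12)
  # round trip over the operating range
  x <- seq(0.98, 1.06, length.out = 101)
  expect_lt(max(abs(tendon_length(tendon_force(x)) - x)), 1e-10)
  # numerically solved shift for k = 14 (independent root-finding oracle)
  s14 <- uniroot(function(s) tendon_force(1, 14, s) - tendon_force(1, 35, 0),
                 c(-0.1, 0.1), tol = 1e-14)$root
  expect_equal(tendon_shift(14), s14, tolerance = 1e-9)
  expect_identical(tendon_shift(35), 0)
})

test_that("force-at-slack invariance holds across stiffness fractions", {
  ks <- 35 * seq(0.3, 1.0, by = 0.1)
  f1 <- tendon_force(1, ks, tendon_shift(ks))
  expect_lt(max(abs(f1 - tendon_force(1, 35, 0))), 1e-12)
})

test_that("tendon curve is monotone with slope increasing in k", {
  lt <- seq(0.98, 1.08, length.out = 200)
  for (k in c(10.5, 21, 35)) {
    f <- tendon_force(lt, k, tendon_shift(k))
    expect_true(all(diff(f) > 0))
  }
  # lower stiffness => longer tendon at equal force
  lt_at_half <- vapply(c(35, 28, 21, 14),
                       function(k) tendon_length(0.5, k, tendon_shift(k)), 0)
  expect_true(all(diff(lt_at_half) > 0))
})

test_that("hill characteristic curves satisfy their anchors", {
  g <- seq(0.4, 1.6, length.out = 5001)
  expect_lt(abs(active_fl(1) - max(active_fl(g))), 5e-3)
  expect_equal(force_velocity(0), 1, tolerance = 1e-12)
  expect_lte(force_velocity(-1), 0.01)
  expect_gt(force_velocity(1), 1.2)     # eccentric force enhancement
  expect_equal(passive_fl(1), 0, tolerance = 1e-12)
  expect_lt(max(abs(passive_fl(g[g <= 1]))), 0.02)
  beyond <- passive_fl(seq(1, 1.6, by = 0.01))
  expect_true(all(diff(beyond) > 0))
})

test_that("activation dynamics has the right fixed point and rates", {
  expect_equal(activation_dynamics(0.5, 0.5), 0)
  # far from the switching surface the smooth rate matches the bilinear one
  expect_equal(activation_dynamics(1, 0), 1 / 0.015, tolerance = 1e-6)
  expect_equal(activation_dynamics(0, 1), -1 / 0.06, tolerance = 1e-6)
  # monotone approach a(t) -> 1 under full excitation
  a <- 0; tr <- numeric(60)
  for (i in 1:60) { a <- a + 0.002 * activation_dynamics(1, a); tr[i] <- a }
  expect_true(all(diff(tr) > 0))
  expect_gt(tr[60], 0.99)
  # analytic jacobian vs finite differences
  ee <- runif(20); aa <- runif(20)
  j <- activation_dynamics_jac(ee, aa)
  h <- 1e-7
  expect_equal(j$de, (activation_dynamics(ee + h, aa) -
                        activation_dynamics(ee - h, aa)) / (2 * h),
               tolerance = 1e-5)
  expect_equal(j$da, (activation_dynamics(ee, aa + h) -
                        activation_dynamics(ee, aa - h)) / (2 * h),
               tolerance = 1e-5)
})
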