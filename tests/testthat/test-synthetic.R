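# Synthetic reference gait and fixture generators.

test_that("reference gait is deterministic, periodic and symmetric", {
  r1 <- make_reference_gait(seed = 4)
  r2 <- make_reference_gait(seed = 4)
  expect_identical(r1, r2)
  r3 <- make_reference_gait(seed = 5)
  expect_false(identical(r1$signals$hip_r$mean, r3$signals$hip_r$mean))
  expect_silent(validate_reference(r1, tol = 1e-8))
  expect_equal(length(r1$grid), 101)
  expect_true(all(vapply(r1$signals, function(s) all(s$sd >= 0), TRUE)))
})

test_that("vertical GRF satisfies the impulse-momentum balance", {
  r <- make_reference_gait(seed = 1)
  bw <- r$body_mass * 9.81
  # per-foot cycle average must be half body weight for periodic gait
  v <- r$signals$grf_vy_r$mean
  avg <- mean(v[-length(v)])
  expect_equal(avg, bw / 2, tolerance = 0.02 * bw / 2)
  # double hump over stance
  expect_gte(count_grf_humps(v, 0.1 * bw), 2)
  # approximate stance duration matches the requested fraction
  expect_equal(mean(v > 20), r$stance_fraction, tolerance = 0.05)
})

test_that("planar fixture has the documented structure", {
  m <- fixture_model()
  expect_equal(sum(m$segments$mass), 62)
  expect_equal(length(m$coord_names), 11)
  expect_equal(length(m$muscles), 18)
  expect_equal(length(m$contact_spheres), 6)
  # locking toes yields the 9-coordinate model
  m9 <- make_planar_fixture(toes = FALSE)
  expect_equal(length(m9$coord_names), 9)
  # toe joint passive parameters: 25 Nm/rad spring, 2 Nm s/rad damper
  expect_equal(m$passive$mtp_r$k_lin, 25)
  expect_equal(m$passive$mtp_r$damping, 2)
  # tendon slack lengths all positive and fibers near optimal at reference
  expect_true(all(vapply(m$muscles, `[[`, 0, "l_slack") > 0))
})

test_that("standing pose balances weight with small penetration", {
  m <- fixture_model()
  q <- standing_pose(m)
  grf <- model_grf(m, matrix(q, ncol = 1), matrix(0, 11, 1))
  expect_equal(sum(vapply(grf$feet, function(f) f$Fy, 0)),
               62 * 9.81, tolerance = 1e-6)
  fk <- forward_kinematics(m, matrix(q, ncol = 1))
  pen <- vapply(m$contact_spheres, function(cs) {
    pt <- fk_point(fk, cs$segment, cs$center)
    cs$radius - pt$y
  }, 0)
  expect_lt(max(pen), 5e-3)
})

test_that("initial population is deterministic and respects bounds", {
  m <- fixture_model()
  cfg <- ocp_config(n_mesh = 4)
  pop1 <- make_initial_population(m, cfg, 3, seed = 2)
  pop2 <- make_initial_population(m, cfg, 3, seed = 2)
  expect_identical(lapply(pop1, `[[`, "z"), lapply(pop2, `[[`, "z"))
  # n = 1 reduces to the cold start; zero perturbation reproduces it
  expect_identical(pop1[[1]]$z, cold_start(m, cfg)$z)
  pop0 <- make_initial_population(m, cfg, 2, seed = 2, scale = 0)
  expect_identical(pop0[[1]]$z, pop0[[2]]$z)
  for (g in pop1) {
    expect_true(all(g$z >= g$lb - 1e-12))
    expect_true(all(g$z <= g$ub + 1e-12))
  }
  expect_false(identical(pop1[[1]]$z, pop1[[2]]$z))
})
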