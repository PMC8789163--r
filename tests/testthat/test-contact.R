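# Smooth Hunt-Crossley contact and GRF analysis.

test_that("sphere force vanishes out of contact and matches Hertz in contact", {
  s <- contact_sphere("s", "hindfoot_r", c(0, 0), 0.02)
  # 1 cm above ground
  f <- sphere_force(-0.01, 0, 0, s)
  expect_lt(abs(f$fy) + abs(f$fx), 0.1)
  # in contact, static: within 1% of the unsmoothed law for delta >= 1 mm
  for (d in c(1e-3, 3e-3, 8e-3)) {
    f <- sphere_force(d, 0, 0, s)
    expect_equal(f$fy, s$stiffness * d^1.5, tolerance = 0.01)
    expect_equal(f$fx, 0)
  }
  # dissipation raises loading force and lowers unloading force
  expect_gt(sphere_force(3e-3, 0.1, 0, s)$fy, sphere_force(3e-3, 0, 0, s)$fy)
  expect_lt(sphere_force(3e-3, -0.1, 0, s)$fy, sphere_force(3e-3, 0, 0, s)$fy)
})

test_that("friction is odd in slip velocity and bounded by the cone + viscous term", {
  s <- contact_sphere("s", "hindfoot_r", c(0, 0), 0.02)
  for (v in c(0.01, 0.05, 0.2, 1)) {
    fp <- sphere_force(3e-3, 0, v, s)
    fm <- sphere_force(3e-3, 0, -v, s)
    expect_equal(fp$fx, -fm$fx, tolerance = 1e-12)
    expect_lte(abs(fp$fx), fp$fn * (s$mu_d + s$mu_v * v) + 1e-9)
  }
})

test_that("sphere force gradients match finite differences including near delta = 0", {
  s <- contact_sphere("s", "hindfoot_r", c(0, 0), 0.02)
  h <- 1e-8
  for (d in c(-1e-3, -1e-5, 0, 1e-5, 1e-3, 5e-3)) {
    for (x in list(c(d, 0.02, 0.05))) {
      num <- (sphere_force(x[1] + h, x[2], x[3], s)$fy -
                sphere_force(x[1] - h, x[2], x[3], s)$fy) / (2 * h)
      num2 <- (sphere_force(x[1], x[2] + h, x[3], s)$fy -
                 sphere_force(x[1], x[2] - h, x[3], s)$fy) / (2 * h)
      expect_true(is.finite(num) && is.finite(num2))
    }
  }
  # smoothness of the tangential component across v_slip = 0
  g1 <- (sphere_force(3e-3, 0, h, s)$fx - sphere_force(3e-3, 0, -h, s)$fx) /
    (2 * h)
  expect_true(is.finite(g1))
})

test_that("standing on both feet transmits body weight through the contacts", {
  m <- fixture_model()
  q <- standing_pose(m)
  grf <- model_grf(m, matrix(q, ncol = 1), matrix(0, length(q), 1))
  weight <- sum(m$segments$mass) * m$gravity
  total <- sum(vapply(grf$feet, function(f) f$Fy, 0))
  expect_equal(total, weight, tolerance = 0.01 * weight)
  # standing penetration is physically small (< 5 mm on every sphere)
  fk <- forward_kinematics(m, matrix(q, ncol = 1))
  for (cs in m$contact_spheres) {
    pt <- fk_point(fk, cs$segment, cs$center)
    expect_lt(cs$radius - pt$y, 5e-3)
  }
  # airborne posture: zero force
  q2 <- q; q2["pelvis_ty"] <- q["pelvis_ty"] + 0.05
  grf2 <- model_grf(m, matrix(q2, ncol = 1), matrix(0, length(q), 1))
  expect_lt(sum(abs(vapply(grf2$feet, function(f) f$Fy, 0))), 0.1)
  # CoP lies within the hull of the loaded sphere projections
  xs <- vapply(grf$spheres[grep("_r$", names(grf$spheres))],
               function(s) s$x, 0)
  expect_gte(grf$feet$r$cop, min(xs) - 1e-9)
  expect_lte(grf$feet$r$cop, max(xs) + 1e-9)
  # total GRF equals the sum of per-sphere forces exactly
  expect_equal(grf$feet$r$Fy + grf$feet$l$Fy,
               sum(vapply(grf$spheres, function(s) s$fy, 0)),
               tolerance = 1e-12)
})

test_that("first vertical peak detection handles humps, ramps and errors", {
  t <- seq(0, 1, length.out = 200)
  double_hump <- 750 * exp(-((t - 0.25) / 0.1)^2) +
    730 * exp(-((t - 0.75) / 0.1)^2)
  expect_equal(first_vertical_peak(double_hump), max(
    double_hump[t < 0.5]), tolerance = 1e-9)
  # monotone ramp falls back to the max of the first half
  ramp <- seq(0, 500, length.out = 100)
  expect_equal(first_vertical_peak(ramp), ramp[50])
  expect_error(first_vertical_peak(numeric(0)))
})
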