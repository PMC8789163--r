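# Model representation, passive torques, variants, collision distances.

test_that("passive torque combines spring, damping and limit terms", {
  toe <- passive_params(k1 = 2, k2 = 10, q_lo = -0.3, q_hi = 0.9,
                        damping = 2, k_lin = 25, q0 = 0)
  base <- passive_torque(0.1, 0, toe) -
    passive_torque(0.1, 0, utils::modifyList(toe, list(k_lin = 0)))
  expect_equal(base, -2.5)              # 25 Nm/rad spring at 0.1 rad
  damp <- passive_torque(0, 1, toe) - passive_torque(0, 0, toe)
  expect_equal(damp, -2)                # 2 Nm s/rad damper at 1 rad/s
  sym <- passive_params(k1 = 2, k2 = 10, q_lo = -1, q_hi = 1)
  expect_equal(passive_torque(0, 0, sym), 0)
  # smoothness: analytic-style central difference is finite & continuous
  q <- seq(-1.2, 1.2, by = 0.01)
  expect_true(all(is.finite(passive_torque(q, 0, sym))))
})

test_that("mass redistribution conserves total mass and inverts exactly", {
  m <- fixture_model()
  total <- sum(m$segments$mass)
  v <- model_variant(torso_mass_delta = -7.4)
  m2 <- apply_variant(m, v)
  expect_equal(sum(m2$segments$mass), total, tolerance = 1e-12)
  it <- m2$segments$name == "torso"
  expect_equal(m2$segments$mass[it], m$segments$mass[it] - 7.4,
               tolerance = 1e-12)
  expect_true(all(m2$segments$mass[!it] > m$segments$mass[!it]))
  # inertia rescales linearly with mass
  expect_equal(m2$segments$inertia / m$segments$inertia,
               m2$segments$mass / m$segments$mass)
  # bit-exact inversion
  m3 <- apply_variant(m2, invert_variant(v))
  expect_identical(m3$segments, m$segments)
})

test_that("torso mass example: 34.2 kg torso loses 7.4 kg to 26.8", {
  m <- fixture_model()
  seg <- m$segments
  seg$mass[seg$name == "torso"] <- 34.2
  m_gen <- m; m_gen$segments <- seg; m_gen$base$segments <- seg
  m2 <- apply_variant(m_gen, model_variant(torso_mass_delta = -7.4))
  expect_equal(m2$segments$mass[m2$segments$name == "torso"], 26.8)
  expect_equal(sum(m2$segments$mass), sum(seg$mass), tolerance = 1e-12)
})

test_that("contact-height variant shifts every sphere and inverts", {
  m <- fixture_model()
  v <- model_variant(contact_vertical_offset = 0.01)
  m2 <- apply_variant(m, v)
  y0 <- vapply(m$contact_spheres, function(cs) cs$center[2], 0)
  y1 <- vapply(m2$contact_spheres, function(cs) cs$center[2], 0)
  r0 <- vapply(m$contact_spheres, function(cs) cs$radius, 0)
  r1 <- vapply(m2$contact_spheres, function(cs) cs$radius, 0)
  expect_equal(y1, y0 + 0.01)
  expect_identical(r1, r0)
  m3 <- apply_variant(m2, invert_variant(v))
  expect_identical(vapply(m3$contact_spheres, function(cs) cs$center[2], 0),
                   y0)
})

test_that("locking the toes removes the MTP coordinates and re-locking inverts", {
  m <- fixture_model()
  m2 <- apply_variant(m, model_variant(toes_locked = TRUE))
  expect_equal(length(m2$coord_names), length(m$coord_names) - 2)
  expect_false(any(grepl("^mtp", m2$coord_names)))
  m3 <- apply_variant(m2, model_variant(toes_locked = FALSE))
  expect_identical(m3$coord_names, m$coord_names)
})

test_that("identity variant is a structural no-op", {
  m <- fixture_model()
  m2 <- apply_variant(m, model_variant())
  expect_identical(m2$segments, m$segments)
  expect_identical(m2$contact_spheres, m$contact_spheres)
  expect_identical(m2$coord_names, m$coord_names)
})

test_that("tendon-stiffness variant touches only the triceps surae", {
  m <- fixture_model()
  m2 <- apply_variant(m, model_variant(tendon_stiffness_fraction = 0.4))
  for (i in seq_along(m$muscles)) {
    if (m$muscles[[i]]$group == "triceps_surae") {
      expect_equal(m2$muscles[[i]]$k, 14)
      expect_equal(m2$muscles[[i]]$shift, tendon_shift(14))
    } else {
      expect_identical(m2$muscles[[i]]$k, m$muscles[[i]]$k)
    }
  }
})

test_that("collision distances match a forward-kinematics oracle", {
  m <- fixture_model()
  expect_identical(collision_distance(rep(0, 11), m), numeric(0))
  # declare a pair and verify against direct point placement
  m$collision_pairs <- list(list(
    a = list(segment = "shank_r", point = c(0, -0.2)),
    b = list(segment = "shank_l", point = c(0, -0.2)), min_dist = 0.05))
  q <- setNames(rep(0, 11), m$coord_names)
  q["hip_r"] <- 0.3; q["hip_l"] <- -0.2; q["knee_r"] <- -0.4
  d <- collision_distance(q, m)
  fk <- forward_kinematics(m, matrix(q, ncol = 1))
  pa <- fk_point(fk, "shank_r", c(0, -0.2))
  pb <- fk_point(fk, "shank_l", c(0, -0.2))
  expect_equal(d, sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2), tolerance = 1e-12)
  # mirrored posture: coincident joints give zero hip separation
  q2 <- setNames(rep(0, 11), m$coord_names)
  expect_equal(collision_distance(q2, m), 0, tolerance = 1e-12)
})

test_that("model validation catches broken references", {
  m <- fixture_model()
  bad <- m
  bad$muscles[[1]]$path[[1]]$segment <- "nonexistent"
  expect_error(validate_model(bad), class = "predgait_config_error")
})
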