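# Smoothed phenomenological metabolic model vs its piecewise oracle, cost
# of transport, per-group breakdown.

metab_pv <- function(n = 1) {
  list(mass = rep(0.5, n), fast_twitch = rep(0.5, n), v_max = rep(10, n),
       l_opt = rep(0.1, n), F_max = rep(1000, n))
}

test_that("quiescent and isometric muscle identities hold", {
  pv <- metab_pv()
  r0 <- bhargava_rate(0, 0, 1, 0, 0, 0, pv)
  expect_equal(r0$work, 0)
  expect_equal(r0$total, 1.0 * pv$mass, tolerance = 1e-6) # heat floor only
  # isometric: no mechanical work; total = heats
  r1 <- bhargava_rate(0.6, 0.5, 1, 0, 400, 450, pv)
  expect_equal(r1$work, 0)
  expect_equal(r1$total, r1$heat)
  expect_gt(r1$activation, 0)
  expect_gt(r1$maintenance, 0)
})

test_that("smooth model matches the piecewise oracle away from switches", {
  set.seed(21)
  n <- 10000
  pv <- metab_pv(n)
  pv$fast_twitch <- runif(n)
  pv$mass <- runif(n, 0.05, 1)
  e <- runif(n); a <- runif(n)
  lm <- runif(n, 0.4, 1.9); vm <- runif(n, -1, 1)
  Fi <- runif(n, 0, 1000); Ft <- runif(n, 0, 1200)
  # keep all inputs >= 0.05 away from every switching surface
  ok <- abs(e - a) > 0.05 & abs(vm) > 0.05 &
    abs(lm - 0.5) > 0.05 & abs(lm - 1) > 0.05 & abs(lm - 1.5) > 0.05 &
    abs(lm - 2) > 0.05
  sm <- bhargava_rate(e, a, lm, vm, Fi, Ft, pv, mode = "smooth")
  pw <- bhargava_rate(e, a, lm, vm, Fi, Ft, pv, mode = "piecewise")
  # compare heats (the clamped total also depends on the floor switch)
  far_floor <- abs((pw$activation + pw$maintenance + pw$shortening) -
                     1.0 * pv$mass) > 0.05
  ok <- ok & far_floor & pw$total != 0
  expect_gt(sum(ok), 3000)
  rel <- abs(sm$total[ok] - pw$total[ok]) /
    pmax(abs(pw$total[ok]), 1e-6)
  expect_lt(max(rel), 0.01)
})

test_that("heat is floored and components behave physiologically", {
  set.seed(22)
  n <- 2000
  pv <- metab_pv(n)
  e <- runif(n); a <- runif(n); lm <- runif(n, 0.5, 1.5)
  vm <- runif(n, -1, 1)
  Fi <- runif(n, 0, 800); Ft <- runif(n, 0, 1000)
  r <- bhargava_rate(e, a, lm, vm, Fi, Ft, pv)
  expect_true(all(r$activation >= -1e-9))
  expect_true(all(r$maintenance >= -1e-3))
  expect_true(all(r$heat >= 1.0 * pv$mass - 1e-2))
  expect_equal(r$total, r$heat + r$work)
})

test_that("cost of transport closed form and scaling laws", {
  traj <- list(time = seq(0, 1, by = 0.01),
               Edot = rep(100, 101), distance = 1.33)
  expect_equal(cost_of_transport(traj, 62), 100 / (62 * 1.33),
               tolerance = 1e-12)
  traj2 <- traj; traj2$distance <- 2 * traj$distance
  expect_equal(cost_of_transport(traj2, 62),
               cost_of_transport(traj, 62) / 2)
  expect_error(cost_of_transport(list(time = 0:1, Edot = c(1, 1),
                                      distance = 0), 62))
})

test_that("per-group breakdown partitions the difference", {
  sol_a <- structure(list(muscle_names = c("m1", "m2", "m3", "m4"),
                          energy_per_muscle = c(10, 20, 30, 40)),
                     class = "gait_solution")
  sol_b <- sol_a
  # identical solutions: all-zero shares
  sh0 <- per_group_breakdown(sol_a, sol_b, list(g1 = c("m1", "m2")))
  expect_true(all(sh0 == 0))
  # single-muscle difference: 100% share in its group
  sol_b$energy_per_muscle <- c(10, 20, 45, 40)
  sh <- per_group_breakdown(sol_a, sol_b,
                            list(g1 = c("m1", "m2"), g2 = c("m3")))
  expect_equal(unname(sh[["g2"]]), 100)
  # shares always sum to 100
  sol_b$energy_per_muscle <- c(13, 18, 44, 47)
  sh2 <- per_group_breakdown(sol_a, sol_b,
                             list(g1 = c("m1", "m2"), g2 = c("m3")))
  expect_equal(sum(sh2), 100, tolerance = 1e-9)
  sol_c <- sol_a; sol_c$muscle_names <- c("x1", "m2", "m3", "m4")
  expect_error(per_group_breakdown(sol_a, sol_c, list()))
})

test_that("maintenance fiber-length factor matches its knots", {
  expect_equal(maintenance_fl(c(0.2, 0.75, 1.2, 1.75, 2.5), smooth = FALSE),
               c(0.5, 0.75, 1, 0.5, 0))
  lm <- seq(0, 2.4, by = 0.001)
  d <- abs(maintenance_fl(lm, smooth = TRUE) -
             maintenance_fl(lm, smooth = FALSE))
  far <- abs(lm - 0.5) > 0.05 & abs(lm - 1) > 0.05 &
    abs(lm - 1.5) > 0.05 & abs(lm - 2) > 0.05
  expect_lt(max(d[far]), 0.01)
})
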