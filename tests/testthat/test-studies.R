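# Evaluation metric operations (stance mask, RMSE, delta-RMSE%).

test_that("stance mask fraction on constructed series", {
  expect_equal(stance_mask(rep(0, 100))$fraction, 0)
  expect_equal(stance_mask(rep(700, 100))$fraction, 1)
  pulse <- c(rep(700, 60), rep(0, 40))
  expect_equal(stance_mask(pulse)$fraction, 0.60)
  expect_equal(stance_mask(pulse, threshold = 800)$fraction, 0)
})

test_that("stance RMSE identities and hand-computed example", {
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(rmse_stance(ref, ref, mask), 0)
  expect_equal(rmse_stance(ref + 2, ref, mask), 2)
  sim <- c(1.5, 1.0, 3.5, 0, 0)
  # hand-computed: sqrt((0.5^2 + 1^2 + 0.5^2) / 3)
  expect_equal(rmse_stance(sim, ref, mask), sqrt(1.5 / 3), tolerance = 1e-12)
  expect_error(rmse_stance(sim, ref, rep(FALSE, 5)))
})

test_that("delta RMSE percent sign convention and errors", {
  mask <- rep(TRUE, 4)
  ref <- c(0, 10, 30, 20)  # range 30
  expect_equal(delta_rmse_percent(10, 8.5, ref, mask), -5.0)
  expect_equal(delta_rmse_percent(7, 7, ref, mask), 0)
  expect_equal(delta_rmse_percent(8.5, 10, ref, mask),
               -delta_rmse_percent(10, 8.5, ref, mask))
  expect_error(delta_rmse_percent(1, 2, rep(5, 4), mask))
})

test_that("tendon sweep default grid is the 8-fraction descending ladder", {
  fr <- eval(formals(tendon_sweep)$fractions)
  expect_equal(fr, seq(1.0, 0.3, by = -0.1))
  expect_length(fr, 8)
  # shift recomputed per fraction keeps the force at slack invariant
  ks <- 35 * fr
  expect_lt(max(abs(tendon_force(1, ks, tendon_shift(ks)) -
                      tendon_force(1, 35, 0))), 1e-12)
})

test_that("metric pipeline is pure: identical reruns on a stored solution", {
  sol <- structure(list(
    cot = 4.1, stride_length = 1.3, cycle_duration = 1.0,
    grf = list(r = list(Fy = c(rep(650, 55), rep(0, 46)))),
    objective = 1, status = "optimal", iterations = 10,
    coord_names = character(0), cycle_q = matrix(0, 0, 101)),
    class = "gait_solution")
  m1 <- solution_metrics(sol)
  m2 <- solution_metrics(sol)
  expect_identical(m1, m2)
  expect_equal(m1$stance_fraction, 55 / 101)
  expect_equal(m1$first_vgrf_peak, 650)
})
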