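# The augmented-Lagrangian solver on small problems with known solutions.

# Generic dense problem adapter: f quadratic-ish, c nonlinear, bounds.
make_prob <- function(fobj, gobj, hobj, cfun, jfun, lb, ub) {
  list(
    fc = function(z) list(f = fobj(z), c = cfun(z)),
    derivs = function(z, with_obj = TRUE) {
      list(f = fobj(z), c = cfun(z),
           JC = Matrix::Matrix(jfun(z), sparse = TRUE),
           g = if (with_obj) gobj(z) else NULL,
           H = if (with_obj) Matrix::Matrix(hobj(z), sparse = TRUE) else
             NULL)
    },
    lb = lb, ub = ub)
}

test_that("solves an equality-constrained quadratic with known optimum", {
  # min (z1-2)^2 + (z2-1)^2  s.t. z1 + z2 = 2  => z* = (1.5, 0.5)
  p <- make_prob(
    fobj = function(z) (z[1] - 2)^2 + (z[2] - 1)^2,
    gobj = function(z) c(2 * (z[1] - 2), 2 * (z[2] - 1)),
    hobj = function(z) diag(c(2, 2)),
    cfun = function(z) z[1] + z[2] - 2,
    jfun = function(z) matrix(c(1, 1), 1),
    lb = c(-10, -10), ub = c(10, 10))
  res <- solve_alm(c(0, 0), p, list(feas_first = 0, polish_tol = 1e-12))
  expect_lt(max(abs(res$z - c(1.5, 0.5))), 1e-5)
  expect_lt(res$feas, 1e-8)
})

test_that("handles a nonlinear constraint and active bounds", {
  # min z1^2 + z2^2  s.t. z1 * z2 = 1, z1 >= 1.4  => z* = (1.4, 1/1.4)
  p <- make_prob(
    fobj = function(z) sum(z^2),
    gobj = function(z) 2 * z,
    hobj = function(z) diag(c(2, 2)),
    cfun = function(z) z[1] * z[2] - 1,
    jfun = function(z) matrix(c(z[2], z[1]), 1),
    lb = c(1.4, -10), ub = c(10, 10))
  res <- solve_alm(c(2, 2), p, list(feas_first = 5, polish_tol = 1e-12))
  expect_lt(res$feas, 1e-8)
  expect_equal(res$z[1], 1.4, tolerance = 1e-4)
  expect_equal(res$z[2], 1 / 1.4, tolerance = 1e-4)
})

test_that("feasibility restoration reaches an exactly feasible point", {
  # pure feasibility: circle intersection from a far start
  p <- make_prob(
    fobj = function(z) 0,
    gobj = function(z) c(0, 0),
    hobj = function(z) diag(c(0, 0)),
    cfun = function(z) c(sum(z^2) - 4, z[1] - 1),
    jfun = function(z) rbind(c(2 * z[1], 2 * z[2]), c(1, 0)),
    lb = c(-10, 0), ub = c(10, 10))
  res <- solve_alm(c(5, 5), p, list(polish_tol = 1e-10, max_iter = 200))
  expect_lt(res$feas, 1e-10)
  expect_equal(res$z, c(1, sqrt(3)), tolerance = 1e-5)
})
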