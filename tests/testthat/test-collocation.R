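# Radau IIA collocation scheme: order conditions, stability function,
# convergence order on a manufactured pendulum solution.

test_that("coefficients satisfy the order conditions and nodes are Radau IIA", {
  cc <- radau_coefficients(3)
  expect_equal(cc$c, c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1),
               tolerance = 1e-14)
  # B(k): sum b c^(k-1) = 1/k for k = 1..5 (order 5 quadrature)
  for (k in 1:5)
    expect_equal(sum(cc$b * cc$c^(k - 1)), 1 / k, tolerance = 1e-12)
  # C(k): A c^(k-1) = c^k / k for k = 1..3
  for (k in 1:3)
    expect_equal(as.numeric(cc$A %*% cc$c^(k - 1)), cc$c^k / k,
                 tolerance = 1e-12)
})

test_that("stability function equals the (2,3) Pade approximant of exp", {
  pade23 <- function(z) (1 + 2 * z / 5 + z^2 / 20) /
    (1 - 3 * z / 5 + 3 * z^2 / 20 - z^3 / 60)
  for (z in c(-5, -1, -0.1, 0.3, 1.7, complex(real = -1, imaginary = 2))) {
    expect_equal(collocation_stability(z), as.complex(pade23(z)),
                 tolerance = 1e-12)
  }
  # L-stability: R(z) -> 0 as z -> -infinity
  expect_lt(Mod(collocation_stability(-1e8)), 1e-6)
})

test_that("integration error decays at >= 3rd order on a forced pendulum", {
  # manufactured solution q*(t) = 0.8 sin(t) of qdd = -sin(q) + u(t)
  u <- function(t) -0.8 * sin(t) + sin(0.8 * sin(t))
  f <- function(t, x) c(x[2], -sin(x[1]) + u(t))
  exact <- function(t) c(0.8 * sin(t), 0.8 * cos(t))
  errs <- vapply(c(4, 8, 16, 32), function(n) {
    out <- radau_integrate(f, exact(0), c(0, 2), n)
    max(abs(out$X[, n + 1] - exact(2)))
  }, 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 3))
  # the scheme is order 5: expect steep decay on the finer pairs
  expect_gt(mean(orders), 4)
})
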