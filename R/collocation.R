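## Radau IIA collocation machinery.
##
## The transcription uses the 3-stage Radau IIA scheme (collocation points
## at (4 - sqrt(6))/10, (4 + sqrt(6))/10 and 1; order 5, stiffly accurate:
## the last stage IS the interval endpoint).  Coefficients are constructed
## from the nodes by exact polynomial integration of the Lagrange basis, so
## the same code yields any Radau-type scheme from its node vector.

#' Radau IIA collocation coefficients
#'
#' @param s number of stages (default 3; nodes are the roots of the Radau
#'   right quadrature polynomial, last node = 1).
#' @return list with `c` (nodes), `A` (Runge-Kutta matrix, `A[i, j] =
#'   integral of the j-th Lagrange polynomial from 0 to c_i`) and `b`
#'   (quadrature weights = last row of `A`).
#' @export
radau_coefficients <- function(s = 3) {
  nodes <- switch(as.character(s),
    "1" = 1,
    "2" = c(1 / 3, 1),
    "3" = c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1),
    stop("radau_coefficients: s must be 1, 2 or 3"))
  ## A from the order conditions: sum_j A[i,j] c_j^(k-1) = c_i^k / k
  V <- outer(nodes, seq_len(s) - 1, `^`)        # Vandermonde
  C <- outer(nodes, seq_len(s), function(ci, k) ci^k / k)
  A <- C %*% solve(V)
  list(c = nodes, A = A, b = A[s, ])
}

#' Stability function of a collocation scheme
#'
#' Amplification factor of one collocation step on `x' = lambda x`:
#' `R(z) = 1 + z b' (I - z A)^{-1} 1`.  For 3-stage Radau IIA this equals
#' the (2,3) Pade approximant of `exp(z)`.
#'
#' @param z complex or numeric argument (`lambda * h`).
#' @param coeffs coefficients from [radau_coefficients()].
#' @return value of `R(z)`.
#' @export
collocation_stability <- function(z, coeffs = radau_coefficients()) {
  s <- length(coeffs$c)
  vapply(z, function(zz) {
    x <- solve(diag(s) - zz * coeffs$A, rep(1, s))
    1 + zz * sum(coeffs$b * x)
  }, complex(1))
}

## Lagrange interpolation on one interval from the start value and the s
## stage values (nodes 0, c_1..c_s).  `tau` in [0, 1]; X is nx x (s+1)
## (start state then stages).  Returns nx x length(tau).
colloc_interp <- function(X, tau, coeffs = radau_coefficients()) {
  nodes <- c(0, coeffs$c)
  L <- vapply(seq_along(nodes), function(j) {
    out <- rep(1, length(tau))
    for (k in seq_along(nodes)) if (k != j)
      out <- out * (tau - nodes[k]) / (nodes[j] - nodes[k])
    out
  }, numeric(length(tau)))
  X %*% t(matrix(L, nrow = length(tau)))
}

#' Integrate an ODE with Radau collocation
#'
#' Fixed-step implicit integration of `x' = f(t, x)` by solving the
#' collocation defect equations per interval with damped Newton iterations
#' (Jacobian by finite differences).  Small helper used by the convergence
#' and energy-conservation checks, not by the optimal-control pipeline.
#'
#' @param f right-hand side `function(t, x) -> dx/dt`.
#' @param x0 initial state.
#' @param tspan `c(t0, t1)`.
#' @param n_steps number of equal steps.
#' @param coeffs collocation coefficients.
#' @param tol Newton tolerance.
#' @return list with `time` (length `n_steps + 1`) and `X` (`nx x (n_steps
#'   + 1)` states at step ends).
#' @export
radau_integrate <- function(f, x0, tspan, n_steps,
                            coeffs = radau_coefficients(), tol = 1e-12) {
  s <- length(coeffs$c)
  nx <- length(x0)
  h <- diff(tspan) / n_steps
  times <- tspan[1] + h * (0:n_steps)
  X <- matrix(0, nx, n_steps + 1)
  X[, 1] <- x0
  for (i in seq_len(n_steps)) {
    t0 <- times[i]; xs <- X[, i]
    K <- matrix(rep(xs, s), nx, s)   # stage states
    res_fun <- function(Kv) {
      K <- matrix(Kv, nx, s)
      FF <- vapply(seq_len(s), function(j) f(t0 + coeffs$c[j] * h, K[, j]),
                   numeric(nx))
      FF <- matrix(FF, nx, s)
      as.vector(K - xs - h * FF %*% t(coeffs$A))
    }
    Kv <- as.vector(K)
    for (it in 1:50) {
      r <- res_fun(Kv)
      if (max(abs(r)) < tol) break
      J <- matrix(0, length(r), length(Kv))
      hh <- 1e-7
      for (j in seq_along(Kv)) {
        Kp <- Kv; Kp[j] <- Kp[j] + hh
        J[, j] <- (res_fun(Kp) - r) / hh
      }
      Kv <- Kv - solve(J, r)
    }
    K <- matrix(Kv, nx, s)
    X[, i + 1] <- K[, s]             # stiffly accurate: last stage = endpoint
  }
  list(time = times, X = X)
}
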