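## Bound-constrained augmented-Lagrangian solver for the transcribed gait
## NLP.
##
## min f(z)  s.t.  c(z) = 0,  lb <= z <= ub
##
## Strategy tailored to collocation problems, where pure feasibility
## restoration (Levenberg-Marquardt on ||c||^2) is reliable and cheap:
##   1. restore feasibility from the initial guess;
##   2. repeat: a few projected damped-Newton steps on the augmented
##      Lagrangian at fixed (lambda, rho), a restoration safeguard if the
##      iterate drifted off the manifold, then a first-order multiplier
##      update;  rho stays moderate (capped) so the neglected constraint
##      curvature in the Gauss-Newton Hessian stays harmless;
##   3. a final restoration polish pushes the constraint violation to
##      ~1e-8 in scaled units.
##
## This replaces the sparse interior-point solver (CasADi + IPOPT) that a
## Python pipeline would use; no equivalent is available in the target
## environment, so the package carries its own solver built on Matrix
## sparse Cholesky factorizations.

solve_alm <- function(z0, prob, opts = list()) {
  o <- utils::modifyList(list(
    max_iter = 600, opt_tol = 1e-4, feas_tol = 1e-6, rho0 = 1e4,
    rho_max = 1e5, mu0 = 1e-3, verbose = FALSE, polish = TRUE,
    polish_tol = 1e-8, max_inner = 25, feas_first = 150, max_outer = 40,
    time_limit = Inf, jac_reuse = 0L), opts)
  lb <- prob$lb; ub <- prob$ub
  z <- pmin(pmax(z0, lb), ub)
  n <- length(z)
  it_total <- 0L
  t_start <- Sys.time()
  elapsed <- function() as.numeric(Sys.time() - t_start, units = "secs")
  out_of_time <- function() elapsed() > o$time_limit
  ## the optimization phase stops early so the closing restoration/polish
  ## always gets a slice of the budget
  out_of_opt_time <- function() elapsed() > 0.8 * o$time_limit

  proj_grad_norm <- function(z, g) {
    pg <- g
    at_lb <- z <= lb + 1e-10; at_ub <- z >= ub - 1e-10
    pg[at_lb] <- pmin(g[at_lb], 0)
    pg[at_ub] <- pmax(g[at_ub], 0)
    max(abs(pg))
  }

  feas_restore <- function(z, max_it, target, tag = "feas",
                           ignore_time = FALSE, precise = FALSE) {
    derivs_args <- if (precise) list(with_obj = FALSE, precise = TRUE)
                   else list(with_obj = FALSE)
    lmu <- 1e-6
    for (fit in seq_len(max_it)) {
      if (!ignore_time && out_of_time()) break
      it_total <<- it_total + 1L
      dv <- do.call(prob$derivs, c(list(z), derivs_args))
      cv2 <- sum(dv$c^2); cv <- max(abs(dv$c))
      if (o$verbose) cat(sprintf("  %s %3d  |c| %.3e\n", tag, fit, cv))
      if (cv < target) break
      gr <- as.numeric(Matrix::crossprod(dv$JC, dv$c))
      try_step <- function(free, lmu) {
        JCf <- if (all(free)) dv$JC else dv$JC[, free, drop = FALSE]
        sol <- suppressWarnings(tryCatch({
          ch <- Matrix::Cholesky(Matrix::forceSymmetric(
            Matrix::crossprod(JCf) + Matrix::Diagonal(sum(free), lmu)),
            LDL = FALSE, perm = TRUE)
          as.numeric(Matrix::solve(ch, -gr[free]))
        }, error = function(e) NULL))
        if (is.null(sol)) return(NULL)
        d <- rep(0, n); d[free] <- sol
        alpha <- 1
        for (ls in 1:10) {
          zn <- pmin(pmax(z + alpha * d, lb), ub)
          cn <- prob$fc(zn)$c
          if (all(is.finite(cn)) && sum(cn^2) < cv2 * (1 - 1e-6 * alpha))
            return(zn)
          alpha <- alpha / 2
        }
        NULL
      }
      improved <- FALSE
      for (try in 1:10) {
        zn <- try_step(rep(TRUE, n), lmu)
        if (is.null(zn)) {
          ## full-space step stalled: retry with bound-pinned variables
          ## whose restoration gradient pushes outward frozen
          free <- !((z <= lb + 1e-10 & gr > 0) | (z >= ub - 1e-10 & gr < 0))
          if (!all(free)) zn <- try_step(free, lmu)
        }
        if (!is.null(zn)) {
          z <- zn; improved <- TRUE; lmu <- max(lmu / 3, 1e-10); break
        }
        lmu <- lmu * 10
        if (lmu > 1e8) break
      }
      if (!improved) break
    }
    z
  }

  restore_target <- max(10 * o$feas_tol, 1e-5)
  if (o$feas_first > 0)
    z <- feas_restore(z, o$feas_first, restore_target)

  lam <- NULL
  rho <- o$rho0
  mu <- o$mu0
  status <- "maxiter"
  f_prev <- Inf
  stalls <- 0L

  for (outer in seq_len(o$max_outer)) {
    if (it_total >= o$max_iter || out_of_opt_time()) break
    ## ---- inner: projected damped Newton on the augmented Lagrangian ----
    reuse_left <- 0L
    for (inner in seq_len(o$max_inner)) {
      if (it_total >= o$max_iter || out_of_opt_time()) break
      it_total <- it_total + 1L
      stale <- reuse_left > 0L
      if (stale) {
        ## quasi-Newton economy: keep the previous Jacobian/Hessian, refresh
        ## only the residuals (the line search guards descent on the exact
        ## merit, so a one-step-stale Jacobian is safe)
        fz <- prob$fc(z)
        dv$f <- fz$f; dv$c <- fz$c
        reuse_left <- reuse_left - 1L
      } else {
        dv <- prob$derivs(z)
        reuse_left <- o$jac_reuse
      }
      if (is.null(lam)) lam <- rep(0, length(dv$c))
      cviol <- max(abs(dv$c))
      gL <- dv$g + as.numeric(Matrix::crossprod(dv$JC, lam + rho * dv$c))
      pg <- proj_grad_norm(z, gL)
      sd <- max(1, max(abs(lam)) / 100)
      if (o$verbose)
        cat(sprintf(
          "  it %3d  f %.6e  |c| %.3e  |pg| %.3e  rho %.1e mu %.1e\n",
          it_total, dv$f, cviol, pg, rho, mu))
      if (pg < o$opt_tol * sd && cviol < o$feas_tol) {
        status <- "optimal"; break
      }
      if (pg < o$opt_tol * sd) break
      JCt <- Matrix::crossprod(dv$JC)
      phi0 <- dv$f + sum(lam * dv$c) + 0.5 * rho * sum(dv$c^2)
      step_ok <- FALSE
      alpha <- 0
      for (try in 1:10) {
        HL <- dv$H + rho * JCt + Matrix::Diagonal(n, mu)
        free <- !((z <= lb + 1e-10 & gL > 0) | (z >= ub - 1e-10 & gL < 0))
        d <- rep(0, n)
        sol <- suppressWarnings(tryCatch({
          ch <- Matrix::Cholesky(Matrix::forceSymmetric(HL[free, free]),
                                 LDL = FALSE, perm = TRUE)
          as.numeric(Matrix::solve(ch, -gL[free]))
        }, error = function(e) NULL))
        if (is.null(sol)) { mu <- mu * 10; next }
        d[free] <- sol
        slope <- sum(gL * d)
        if (slope > 0) { mu <- mu * 10; next }
        alpha <- 1
        for (ls in 1:20) {
          zn <- pmin(pmax(z + alpha * d, lb), ub)
          fcn <- prob$fc(zn)
          phin <- fcn$f + sum(lam * fcn$c) + 0.5 * rho * sum(fcn$c^2)
          if (all(is.finite(fcn$c)) && is.finite(phin) &&
              phin <= phi0 + 1e-4 * alpha * slope) {
            z <- zn; step_ok <- TRUE; break
          }
          alpha <- alpha * 0.5
        }
        if (step_ok) {
          mu <- if (alpha >= 0.5) max(mu / 3, 1e-8) else mu * 2
          break
        }
        mu <- mu * 10
        if (mu > 1e10) break
      }
      if (!step_ok || alpha < 0.25) reuse_left <- 0L
      if (!step_ok) {
        if (stale) next      # retry this point with a fresh Jacobian
        break
      }
    }

    ## ---- safeguard + multiplier update ----
    fcz <- prob$fc(z)
    if (max(abs(fcz$c)) > 10 * restore_target) {
      z <- feas_restore(z, 25, restore_target, tag = "resc")
      fcz <- prob$fc(z)
      rho <- min(rho * 3, o$rho_max)
    }
    if (is.null(lam)) lam <- rep(0, length(fcz$c))
    lam <- pmin(pmax(lam + rho * fcz$c, -1e8), 1e8)
    cviol <- max(abs(fcz$c))
    df <- abs(fcz$f - f_prev)
    if (o$verbose)
      cat(sprintf("  outer %2d  f %.6e  |c| %.3e  df %.2e\n", outer, fcz$f,
                  cviol, df))
    if (status == "optimal") break
    if (cviol < restore_target && df < o$opt_tol * 0.1 * (1 + abs(fcz$f))) {
      stalls <- stalls + 1L
      if (stalls >= 2L) { status <- "acceptable"; break }
    } else stalls <- 0L
    f_prev <- fcz$f
  }

  ## final feasibility polish (always runs: it is cheap and the reported
  ## solution must sit on the constraint manifold)
  if (o$polish) {
    precise <- !is.null(formals(prob$derivs)$precise)
    for (round in 1:2) {
      cv_before <- max(abs(prob$fc(z)$c))
      if (cv_before < o$polish_tol) break
      z <- feas_restore(z, 40, o$polish_tol, tag = "pol",
                        ignore_time = TRUE, precise = precise)
      cv_after <- max(abs(prob$fc(z)$c))
      if (cv_after > 0.5 * cv_before) break   # stalled: stop restarting
    }
  }

  fcz <- prob$fc(z)
  list(z = z, f = fcz$f, c = fcz$c, feas = max(abs(fcz$c)),
       iterations = it_total, status = status, fc = fcz)
}
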