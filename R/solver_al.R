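# Sparse bound-projected augmented-Lagrangian Levenberg-Marquardt solver.
#
# Minimizes 0.5*||r(z)||^2 subject to c(z) = 0 and lower <= z <= upper,
# where r and c are supplied by an evaluation callback returning sparse
# Jacobians.  Inner iterations minimize the augmented Lagrangian
#   phi(z) = 0.5||r||^2 + lambda' c + 0.5*mu*||c||^2
# by damped Gauss-Newton steps on the stacked least-squares system,
# with clipping to the box; outer iterations update the multipliers
# (lambda <- lambda + mu c) or grow mu when feasibility stalls.
# Convergence is declared against first-order (KKT) conditions: the
# constraint residual and the bound-projected gradient of the Lagrangian.
#
# eval_fn(z, want_jac) must return list(r, c, Jr, Jc); Jr/Jc are
# dgCMatrix (may be NULL when want_jac = FALSE, and Jc/c may be length-0
# for unconstrained problems).

al_lm_control <- function(tol_feas = 1e-8, tol_opt = 1e-6, mu0 = 10,
                          mu_growth = 8, mu_max = 1e12, max_outer = 30,
                          max_inner = 60, max_total = 500, nu0 = 1e-4,
                          verbose = FALSE) {
  list(tol_feas = tol_feas, tol_opt = tol_opt, mu0 = mu0,
       mu_growth = mu_growth, mu_max = mu_max, max_outer = max_outer,
       max_inner = max_inner, max_total = max_total, nu0 = nu0,
       verbose = verbose)
}

al_lm <- function(eval_fn, z0, lower, upper, scale,
                  control = al_lm_control(), hess_fn = NULL) {
  N <- length(z0)
  stopifnot(length(lower) == N, length(upper) == N, length(scale) == N,
            all(scale > 0), all(lower <= upper))
  clip <- function(z) pmin(pmax(z, lower), upper)
  z <- clip(z0)
  D <- Matrix::Diagonal(x = scale)
  fixed <- upper - lower <= 0
  # dominate pinned coordinates so curvature coupling through them
  # cannot distort the Newton step of the free ones
  Dfix <- if (any(fixed))
    Matrix::Diagonal(x = ifelse(fixed, 1e10, 0)) else NULL

  ev <- eval_fn(z, TRUE)
  ncon <- length(ev$c)
  lam <- numeric(ncon)
  mu <- if (ncon) control$mu0 else 0
  nu <- control$nu0
  phi_of <- function(e) 0.5 * sum(e$r^2) +
    (if (ncon) sum(lam * e$c) + 0.5 * mu * sum(e$c^2) else 0)
  phi <- phi_of(ev)

  total_it <- 0L
  status <- "max_iter"
  feas_prev <- if (ncon) max(abs(ev$c)) else 0
  kkt_opt <- Inf
  at_lo <- at_hi <- NULL

  proj_grad <- function(g, z) {
    at_lo <- z <= lower + 1e-14 * (1 + abs(lower))
    at_hi <- z >= upper - 1e-14 * (1 + abs(upper))
    g2 <- g
    g2[at_lo] <- pmin(g[at_lo], 0)
    g2[at_hi] <- pmax(g[at_hi], 0)
    g2
  }

  best <- NULL
  merit_of <- function(e) 0.5 * sum(e$r^2) +
    (if (length(e$c)) 1e3 * max(abs(e$c)) else 0)
  for (outer in seq_len(control$max_outer)) {
    inner_done <- FALSE
    n_acc <- 0L
    for (inner in seq_len(control$max_inner)) {
      total_it <- total_it + 1L
      lamhat <- if (ncon) lam + mu * ev$c else numeric(0)
      g <- as.numeric(Matrix::crossprod(ev$Jr, ev$r))
      if (ncon) g <- g + as.numeric(Matrix::crossprod(ev$Jc, lamhat))
      pg <- proj_grad(g, z)
      kkt_opt <- max(abs(pg * scale))
      res_scale <- max(1, sqrt(2 * 0.5 * sum(ev$r^2)))
      if (kkt_opt <= control$tol_opt * res_scale) { inner_done <- TRUE; break }
      if (total_it > control$max_total) break

      JrD <- ev$Jr %*% D
      B <- Matrix::crossprod(JrD)
      if (ncon) B <- B + mu * Matrix::crossprod(ev$Jc %*% D)
      feas_now <- if (ncon) max(abs(ev$c)) else 0
      if (!is.null(hess_fn) && ncon && feas_now < 1) {
        # exact constraint curvature: Newton on the augmented Lagrangian.
        # Far from the manifold the curvature term is dominated by huge
        # multiplier estimates and only destabilizes the step, so the
        # Gauss-Newton model is used there instead.
        Hc <- hess_fn(z, lamhat)
        B <- B + D %*% Hc %*% D
      }
      if (!is.null(Dfix)) B <- B + Dfix
      B <- methods::as(B, "symmetricMatrix")
      gy <- g * scale
      gy[fixed] <- 0
      accepted <- FALSE
      for (fac in 1:18) {
        # an indefinite Newton matrix is expected away from the optimum
        # and is handled by growing the damping, so the CHOLMOD warning
        # carries no information here
        ch <- tryCatch(suppressWarnings(
          Matrix::Cholesky(B, LDL = FALSE, super = TRUE, Imult = nu)),
          error = function(e) NULL)
        if (!is.null(ch)) {
          dy <- -as.numeric(Matrix::solve(ch, gy))
          # damped-Newton direction; backtrack on cheap residual evals
          for (alpha in 2^(0:-6)) {
            z_try <- clip(z + alpha * dy * scale)
            ev_try <- eval_fn(z_try, FALSE)
            phi_try <- phi_of(ev_try)
            if (is.finite(phi_try) && phi_try < phi) {
              step_rel <- max(abs(z_try - z) / scale)
              z <- z_try
              ev <- eval_fn(z, TRUE)
              phi <- phi_of(ev)
              if (alpha == 1) nu <- max(nu / 3, 1e-10)
              else if (alpha < 0.25) nu <- nu * 3
              accepted <- TRUE
              n_acc <- n_acc + 1L
              if (is.null(best) || merit_of(ev) < best$merit)
                best <- list(z = z, ev = ev, merit = merit_of(ev))
              if (step_rel < 1e-11) inner_done <- TRUE
              break
            }
          }
        }
        if (accepted) break
        nu <- max(nu, 1e-8) * 10
        if (nu > 1e14) break
      }
      if (!accepted) { inner_done <- TRUE; break }  # stalled inner
      if (inner_done) break
    }
    feas <- if (ncon) max(abs(ev$c)) else 0
    if (control$verbose)
      message(sprintf("outer %d: cost=%.6e feas=%.2e kkt=%.2e mu=%.1e",
                      outer, 0.5 * sum(ev$r^2), feas, kkt_opt, mu))
    if (!ncon) {
      if (inner_done && kkt_opt <= control$tol_opt *
          max(1, sqrt(sum(ev$r^2)))) { status <- "converged"; break }
      if (inner_done) { status <- "stalled"; break }
    } else {
      res_scale <- max(1, sqrt(sum(ev$r^2)))
      if (feas <= control$tol_feas &&
          kkt_opt <= control$tol_opt * res_scale) {
        status <- "converged"; break
      }
      if (n_acc == 0L && inner_done && kkt_opt > control$tol_opt) {
        # no progress possible at this (lambda, mu); growing mu further
        # only amplifies ill-conditioning
        status <- "stalled"
        break
      }
      if (feas <= max(control$tol_feas, 0.25 * feas_prev)) {
        lam <- lam + mu * ev$c
        feas_prev <- feas
        phi <- phi_of(ev)
      } else {
        if (mu >= control$mu_max) {
          status <- if (inner_done) "infeasible_stall" else "max_iter"
          break
        }
        mu <- mu * control$mu_growth
        phi <- phi_of(ev)
      }
    }
    if (total_it > control$max_total) { status <- "max_iter"; break }
  }

  # return the best-merit iterate if the final point regressed
  if (!is.null(best) && merit_of(ev) > best$merit) {
    z <- best$z
    ev <- best$ev
  }
  list(z = z, cost = 0.5 * sum(ev$r^2), lambda = lam, mu = mu,
       feasibility = if (ncon) max(abs(ev$c)) else 0,
       kkt_optimality = kkt_opt, iterations = total_it, status = status)
}
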