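#' Least-squares assimilation cost
#'
#' \eqn{c = \tfrac12 \sum_i \left[(V_{exp}(t_i) - V_{mod}(t_i))^2 +
#' u^2(t_i)\right]} evaluated at every mesh point.
#'
#' @param V_mod,V_exp model and observed voltage sequences (mV)
#' @param u control sequence (defaults to zero)
#' @return scalar cost
#' @export
assemble_cost <- function(V_mod, u = NULL, V_exp) {
  if (is.null(u)) u <- numeric(length(V_mod))
  if (length(V_mod) != length(V_exp) || length(u) != length(V_mod))
    stop("V_mod, u and V_exp must have equal lengths")
  0.5 * sum((V_exp - V_mod)^2 + u^2)
}

#' Boole collocation residual for one 5-point group
#'
#' \deqn{x(t_{i+4}) - x(t_i) - \frac{2\Delta t}{45}\left[7F_0 + 32F_1 +
#' 12F_2 + 32F_3 + 7F_4\right]}
#' per state column; exact (to machine precision) whenever F(t) is a
#' polynomial of degree <= 5 in time, the O(dt^7) accuracy of Boole's rule.
#'
#' @param x_group 5 x L matrix of states at the group's 5 evenly spaced
#'   points (or length-5 vector for L = 1)
#' @param F_group 5 x L matrix of right-hand-side evaluations
#' @param dt mesh step within the group (ms)
#' @return length-L residual vector
#' @export
boole_residual <- function(x_group, F_group, dt) {
  x_group <- rbind(x_group); F_group <- rbind(F_group)
  if (is.null(dim(x_group)) || nrow(x_group) != 5 || nrow(F_group) != 5)
    stop("a collocation group must contain 5 evenly spaced points")
  w <- c(7, 32, 12, 32, 7)
  drop(x_group[5, ] - x_group[1, ] - (2 * dt / 45) * (w %*% F_group))
}

#' Hermite interpolation residuals for one 5-point group
#'
#' Midpoint conditions at the 2nd and 4th points of the group
#' (symmetric about the group centre):
#' \deqn{x_{i+1} - \tfrac12(x_i + x_{i+2}) - \frac{\Delta t}{4}
#'  (F_i - F_{i+2})}
#' and the analogue at i+3.  With the \eqn{\Delta t/4} factor (the 2-step
#' sub-interval divided by 8) the conditions are exact for trajectories
#' cubic in time, which is the defining property of the Hermite-Simpson
#' interpolant.
#'
#' @inheritParams boole_residual
#' @return 2 x L matrix of residuals (rows: condition at i+1, at i+3)
#' @export
hermite_residuals <- function(x_group, F_group, dt) {
  x_group <- rbind(x_group); F_group <- rbind(F_group)
  if (nrow(x_group) != 5 || nrow(F_group) != 5)
    stop("a collocation group must contain 5 evenly spaced points")
  r1 <- x_group[2, ] - 0.5 * (x_group[1, ] + x_group[3, ]) -
    (dt / 4) * (F_group[1, ] - F_group[3, ])
  r2 <- x_group[4, ] - 0.5 * (x_group[3, ] + x_group[5, ]) -
    (dt / 4) * (F_group[3, ] - F_group[5, ])
  rbind(at_i1 = r1, at_i3 = r2)
}

#' Assemble the collocation estimation problem
#'
#' Transcribes the assimilation task into a sparse constrained nonlinear
#' least-squares problem: decision vector of 8 trajectory variables (7
#' states + control u) per retained mesh point plus the 41 parameters;
#' equality constraints L*G Boole + 2(L+1)*G Hermite rows (G groups);
#' box bounds on every variable (states, 0 <= u <= 1, parameter search
#' intervals).  The control slope limit |du/dt| <= 1 / ms is enforced by
#' one-sided (hinge) penalty residuals on consecutive differences.
#' First derivatives of cost and constraints are analytic and sparse.
#' Internally the Boole/Hermite residuals are step-scaled (divided by the
#' group time span) so feasibility tolerances are uniform rate units.
#'
#' @param dataset a twin dataset (or compatible list with t, V_exp, I_inj)
#' @param mesh a [adaptive_mesh()]/[uniform_mesh()] plan
#' @param model an [rvlm_model()]
#' @param bounds parameter bounds list(lower, upper); default widened table
#' @param options list; recognised: V_range (default c(-150, 100)),
#'   u_max (1), du_dt_max (1), w_du (hinge weight, 10)
#' @return object of class "assimilation_problem"
#' @export
assemble_nlp <- function(dataset, mesh, model = rvlm_model(),
                         bounds = rvlm_bounds("table_widened"),
                         options = list()) {
  o <- modifyList(list(V_range = c(-150, 100), u_max = 1, du_dt_max = 1,
                       w_du = 10), options)
  lo_p <- bounds$lower[.param_names]; hi_p <- bounds$upper[.param_names]
  if (any(lo_p > hi_p)) stop("parameter bounds with lower > upper")
  idx <- mesh$index
  npts <- length(idx)
  G <- length(mesh$grp_start)
  Vexp <- as.numeric(dataset$V_exp[idx])
  Iinj <- as.numeric(dataset$I_inj[idx])
  # left-limit current at each retained point (for group-closing nodes)
  Iend <- as.numeric(dataset$I_inj[pmax(idx - 1L, 1L)])
  N <- 8L * npts + 41L

  z_lower <- numeric(N); z_upper <- numeric(N)
  sel_V <- seq(1, 8 * npts, by = 8)
  sel_u <- seq(8, 8 * npts, by = 8)
  z_lower[] <- 0; z_upper[] <- 1            # gates
  z_lower[sel_V] <- o$V_range[1]; z_upper[sel_V] <- o$V_range[2]
  z_lower[sel_u] <- 0; z_upper[sel_u] <- o$u_max
  z_lower[8 * npts + 1:41] <- lo_p; z_upper[8 * npts + 1:41] <- hi_p

  scale <- numeric(N)
  scale[] <- 0.25
  scale[sel_V] <- 25
  scale[sel_u] <- 0.25
  wp <- (hi_p - lo_p) / 2
  wp[wp <= 0] <- pmax(abs(lo_p[wp <= 0]), 1)
  scale[8 * npts + 1:41] <- wp

  # interval step for each consecutive retained pair (for du/dt hinge)
  dtv <- rep(mesh$grp_dt, each = 4)

  # constant cost Jacobian: rows 1..npts voltage misfit, npts+1..2npts u
  Jcost <- Matrix::sparseMatrix(
    i = c(seq_len(npts), npts + seq_len(npts)),
    j = c(sel_V, sel_u), x = c(rep(-1, npts), rep(1, npts)),
    dims = c(2L * npts, N))

  consts <- unname(model$consts)
  grp_start <- as.integer(mesh$grp_start)
  grp_dt <- as.numeric(mesh$grp_dt)

  cache <- new.env(parent = emptyenv())
  eval_fn <- function(z, want_jac) {
    ce <- colloc_eval_cpp(z, npts, grp_start, grp_dt, Vexp, Iinj, Iend,
                          consts, TRUE, want_jac)
    u <- z[sel_u]
    du <- diff(u)
    viol <- pmax(0, abs(du) - o$du_dt_max * dtv)
    active <- which(viol > 0)
    r_h <- o$w_du * viol[active]
    r <- c(ce$rcost, r_h)
    if (!want_jac) return(list(r = r, c = ce$rcon))
    Jc <- con_jac(cache, ce, 23L * G, N)
    if (length(active)) {
      sg <- o$w_du * sign(du[active])
      Jh <- Matrix::sparseMatrix(
        i = rep(seq_along(active), 2L),
        j = c(sel_u[active + 1L], sel_u[active]),
        x = c(sg, -sg), dims = c(length(active), N))
      Jr <- rbind(Jcost, Jh)
    } else Jr <- Jcost
    list(r = r, c = ce$rcon, Jr = Jr, Jc = Jc)
  }

  # exact Hessian of sum_i omega_i c_i(z) (sparse, symmetric); the
  # sparsity pattern varies with omega, so no pattern cache here
  hess_fn <- function(z, omega) {
    hc <- colloc_hess_cpp(z, npts, grp_start, grp_dt, Vexp, Iinj,
                          consts, TRUE, omega)
    Matrix::sparseMatrix(i = hc$i, j = hc$j, x = hc$v, dims = c(N, N),
                         index1 = FALSE)
  }

  structure(list(
    npts = npts, N = N, G = G, mesh = mesh, dataset = dataset,
    model = model, Vexp = Vexp, Iinj = Iinj,
    n_boole = 7L * G, n_hermite = 16L * G,
    z_lower = z_lower, z_upper = z_upper, scale = scale,
    param_lower = lo_p, param_upper = hi_p,
    sel_V = sel_V, sel_u = sel_u, options = o,
    eval_fn = eval_fn, hess_fn = hess_fn), class = "assimilation_problem")
}

# build/reuse the sparse constraint Jacobian from triplets with a cached
# sparsity pattern (indices are iteration-invariant)
con_jac <- function(cache, ce, nrow, ncol) {
  if (is.null(cache$ord)) {
    ord <- order(ce$j, ce$i)
    ii <- ce$i[ord]; jj <- ce$j[ord]
    first <- c(TRUE, diff(ii) != 0 | diff(jj) != 0)
    gid <- cumsum(first)
    J <- Matrix::sparseMatrix(i = ii[first], j = jj[first],
                              x = rep(1, sum(first)),
                              dims = c(nrow, ncol), index1 = FALSE)
    if (length(J@x) == max(gid)) {
      cache$ord <- ord; cache$gid <- gid; cache$J <- J
    } else {
      return(Matrix::sparseMatrix(i = ce$i, j = ce$j, x = ce$v,
                                  dims = c(nrow, ncol), index1 = FALSE))
    }
  }
  xs <- rowsum(ce$v[cache$ord], cache$gid, reorder = FALSE)
  J <- cache$J
  J@x <- as.numeric(xs)
  J
}

#' @exportS3Method base::print
print.assimilation_problem <- function(x, ...) {
  cat("collocation problem:", x$npts, "mesh points,", x$G, "groups\n")
  cat("decision variables:", x$N, " equality constraints:",
      x$n_boole + x$n_hermite,
      sprintf("(%d Boole + %d Hermite)\n", x$n_boole, x$n_hermite))
  invisible(x)
}

#' Build an initial decision vector
#'
#' Default initialization policy: the voltage trajectory is taken from the
#' observed data; every gate is obtained by filtering its first-order
#' kinetics along the observed voltage with an exact exponential
#' integrator (the gate ODE is linear given V(t), so this recovers the
#' gate trajectories implied by the data under the initial parameter
#' guess's kinetics — far closer to the feasible manifold than pointwise
#' steady states, which lag badly during action potentials); the control
#' starts at zero; parameters at their bound midpoints unless supplied.
#'
#' @param problem an [assemble_nlp()] problem
#' @param params "midpoint", or a named parameter vector (projected into
#'   bounds with a warning if outside)
#' @param u0 initial control value
#' @return numeric decision vector
#' @export
init_decision_vector <- function(problem, params = "midpoint", u0 = 0) {
  lo <- problem$param_lower; hi <- problem$param_upper
  if (identical(params, "midpoint")) {
    p0 <- (lo + hi) / 2
  } else {
    p0 <- as.numeric(params[.param_names])
    if (any(p0 < lo - 1e-12 | p0 > hi + 1e-12)) {
      warning("initial parameters outside bounds; projecting")
      p0 <- pmin(pmax(p0, lo), hi)
    }
  }
  names(p0) <- .param_names
  z <- numeric(problem$N)
  V <- pmin(pmax(problem$Vexp, problem$z_lower[problem$sel_V]),
            problem$z_upper[problem$sel_V])
  z[problem$sel_V] <- V
  z <- refilter_gates(problem, z, p0)
  z[problem$sel_u] <- u0
  z[8 * problem$npts + 1:41] <- p0
  z
}

# exact exponential-integrator filtering of the six linear gate ODEs
# along the voltage trajectory stored in z, under kinetics p0
refilter_gates <- function(problem, z, p0) {
  V <- z[problem$sel_V]
  dtv <- rep(problem$mesh$grp_dt, each = 4)
  gi <- 0L
  for (g in .gate_names) {
    gi <- gi + 1L
    gp <- gate_params(p0, g)
    xinf <- gate_steady_state(V, gp)
    tau <- gate_time_constant(V, gp)
    x <- numeric(length(V))
    x[1] <- xinf[1]
    ef <- exp(-dtv / (0.5 * (tau[-length(tau)] + tau[-1])))
    for (j in seq_along(dtv))
      x[j + 1] <- xinf[j + 1] + (x[j] - xinf[j + 1]) * ef[j]
    z[problem$sel_V + gi] <- pmin(pmax(x, 0), 1)
  }
  z
}

# Synchronization stage of the default initialization: integrate the
# model with a strong nudging term gs*(V_exp - V) (which suppresses the
# positive conditional Lyapunov exponent and smooths the fit landscape),
# and improve the parameters by damped Gauss-Newton on the
# synchronization error with exact forward sensitivities, annealing the
# coupling downward and applying a weak interval-scaled ridge that keeps
# sloppy parameter combinations off the bounds.
sync_parameter_stage <- function(dataset, p0, bounds,
                                 gs_schedule = c(50, 25, 12, 6),
                                 ridge = c(10, 3, 1, 0.3),
                                 iters = 30, substeps = 6,
                                 consts = physical_constants()) {
  pn <- .param_names
  lo <- bounds$lower[pn]; hi <- bounds$upper[pn]
  mid <- (lo + hi) / 2
  wd <- pmax((hi - lo) / 2, 1e-8)
  free <- pn[hi > lo]
  fidx <- match(free, pn) - 1L
  pv <- pmin(pmax(p0[pn], lo), hi)
  Vexp <- as.numeric(dataset$V_exp)
  Iinj <- as.numeric(dataset$I_inj)
  kc <- unname(consts)
  runV <- function(pv, gs, sens) {
    x0 <- c(Vexp[1], gate_steady_states(Vexp[1], setNames(pv, pn)))
    sync_forward_cpp(x0, as.numeric(pv), as.integer(fidx), Vexp, Iinj,
                     dataset$dt_base, gs, as.integer(substeps), kc, sens)
  }
  for (stage in seq_along(gs_schedule)) {
    gs <- gs_schedule[stage]
    lam_r <- ridge[min(stage, length(ridge))]
    obj_of <- function(pv) {
      o <- sum((runV(pv, gs, FALSE)$states[, 1] - Vexp)^2)
      o + lam_r * sum(((pv[free] - mid[free]) / wd[free])^2)
    }
    obj <- obj_of(pv)
    nu <- 1e-2
    for (it in seq_len(iters)) {
      sv <- runV(pv, gs, TRUE)
      r <- sv$states[, 1] - Vexp
      g <- drop(crossprod(sv$SV, r)) +
        2 * lam_r * (pv[free] - mid[free]) / wd[free]^2
      H <- crossprod(sv$SV) + diag(2 * lam_r / wd[free]^2)
      ok <- FALSE
      for (f in 1:20) {
        dp <- tryCatch(-drop(solve(H + diag(nu / wd[free]^2), g)),
                       error = function(e) NULL)
        if (!is.null(dp)) {
          pt <- pv
          pt[free] <- pmin(pmax(pv[free] + dp, lo[free]), hi[free])
          o2 <- obj_of(pt)
          if (is.finite(o2) && o2 < obj * (1 - 1e-12)) {
            pv <- pt; obj <- o2; ok <- TRUE
            nu <- max(nu / 3, 1e-10)
            break
          }
        }
        nu <- nu * 6
        if (nu > 1e15) break
      }
      if (!ok) break
    }
  }
  sync_err <- sum((runV(pv, gs_schedule[length(gs_schedule)],
                        FALSE)$states[, 1] - Vexp)^2)
  list(params = setNames(pv, pn), sync_error = sync_err)
}

#' Solve the collocation problem
#'
#' Runs the sparse augmented-Lagrangian Levenberg-Marquardt solver to
#' first-order (KKT) optimality: equality-constraint residual below the
#' feasibility tolerance and bound-projected Lagrangian gradient below the
#' optimality tolerance (relative to the residual scale).  Deterministic
#' given the initialization and dataset.
#'
#' @param problem an [assemble_nlp()] problem
#' @param init decision vector from [init_decision_vector()], or a named
#'   parameter vector / "midpoint" handed to it
#' @param control named list overriding [al_lm_control()] defaults
#' @return object of class "solution_record": p_est, states, u, cost
#'   (assimilation cost at the solution), feasibility, kkt_optimality,
#'   status, iterations, provenance
#' @export
solve_nlp <- function(problem, init = "staged", control = list()) {
  if (identical(init, "staged")) {
    st <- sync_parameter_stage(problem$dataset,
                               (problem$param_lower +
                                  problem$param_upper) / 2,
                               list(lower = problem$param_lower,
                                    upper = problem$param_upper),
                               consts = problem$model$consts)
    init <- init_decision_vector(problem, st$params)
  } else if (!is.numeric(init) || length(init) != problem$N) {
    init <- init_decision_vector(problem, init)
  }
  ctrl <- do.call(al_lm_control, control)
  sol <- al_lm(problem$eval_fn, init, problem$z_lower, problem$z_upper,
               problem$scale, ctrl, hess_fn = problem$hess_fn)
  z <- sol$z
  npts <- problem$npts
  states <- matrix(z[rep(seq(0, 8 * (npts - 1), by = 8), each = 7) +
                       rep(1:7, npts)], ncol = 7, byrow = TRUE)
  colnames(states) <- c("V", "m", "h", "n", "q", "r", "z")
  u <- z[problem$sel_u]
  p_est <- setNames(z[8 * npts + 1:41], .param_names)
  cost <- assemble_cost(states[, "V"], u, problem$Vexp)
  structure(list(
    p_est = p_est, states = states, u = u, cost = cost,
    feasibility = sol$feasibility, kkt_optimality = sol$kkt_optimality,
    status = sol$status, iterations = sol$iterations,
    z = z, sigma = problem$dataset$sigma, zeta = problem$dataset$zeta),
    class = "solution_record")
}

#' @exportS3Method base::print
print.solution_record <- function(x, ...) {
  cat("solution:", x$status, "after", x$iterations, "iterations\n")
  cat(sprintf("cost = %.6e  feasibility = %.2e  kkt = %.2e  |u| = %.2e\n",
              x$cost, x$feasibility, x$kkt_optimality,
              sqrt(mean(x$u^2))))
  invisible(x)
}

#' Classify an estimate as optimal or suboptimal
#'
#' Interval-scaled maximum deviation: optimal iff
#' \code{max_k |p_est_k - p_ref_k| / w_k <= tol_rel}, where \code{w_k} is
#' the printed search-interval width (degenerate widths fall back to the
#' widened interval).
#'
#' @param p_est,p_ref named parameter vectors
#' @param tol_rel relative tolerance (default 1%)
#' @return list(class, max_dev, dev)
#' @export
classify_solution <- function(p_est, p_ref, tol_rel = 0.01) {
  p_est <- p_est[.param_names]; p_ref <- p_ref[.param_names]
  if (any(is.na(p_est)) || any(is.na(p_ref)))
    stop("parameter name mismatch")
  tab <- rvlm_parameter_table()
  w <- tab$upper - tab$lower
  wb <- rvlm_bounds("table_widened")
  wfall <- (wb$upper - wb$lower)[.param_names]
  w[w <= 0] <- wfall[w <= 0]
  w[w <= 0] <- 1
  dev <- abs(p_est - p_ref) / w
  dev["C"] <- 0
  list(class = if (max(dev) <= tol_rel) "optimal" else "suboptimal",
       max_dev = max(dev), dev = dev)
}

#' Assimilate a twin dataset end to end
#'
#' Convenience wrapper: mesh (uniform unless supplied), problem assembly,
#' initialization, solve.
#'
#' @inheritParams assemble_nlp
#' @param init passed to [solve_nlp()]
#' @param mesh optional mesh plan
#' @param control solver control overrides
#' @export
assimilate <- function(dataset, init = "staged", mesh = NULL,
                       model = rvlm_model(),
                       bounds = rvlm_bounds("table_widened"),
                       options = list(), control = list()) {
  if (is.null(mesh)) mesh <- uniform_mesh(dataset)
  pr <- assemble_nlp(dataset, mesh, model, bounds, options)
  solve_nlp(pr, init, control)
}
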