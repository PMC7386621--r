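# Noise-amplitude ramp regularization: make constructive use of the
# noise-induced offset of cost-surface minima.  Ramping the amplitude of a
# fixed noise realization moves local and global minima relative to one
# another until the local minimum merges with a saddle (a saddle-node
# bifurcation) and the tracked solution drops into the global basin; the
# amplitude is then annealed back to zero.

#' Interval-scaled parameter distance used for jump detection
#' @param p1,p2 named parameter vectors
#' @param widths per-parameter scale (defaults to widened search widths)
#' @export
param_jump_norm <- function(p1, p2, widths = NULL) {
  if (is.null(widths)) {
    b <- rvlm_bounds("table_widened")
    widths <- b$upper - b$lower
    widths[widths <= 0] <- 1
  }
  nm <- intersect(names(p1), names(p2))
  sqrt(sum(((p1[nm] - p2[nm]) / widths[nm])^2))
}

# Core ramp-and-detect logic over a generic per-sigma solver.
# solve_fn(sigma, warm) -> list(par = numeric, cost = scalar, ...);
# warm is the previous return value (NULL-safe).  Flags the first
# consecutive pair whose parameter jump exceeds jump_factor times the
# median inter-step displacement on the leg AND whose cost change is
# similarly discontinuous.
ramp_sigma_core <- function(solve_fn, sigma_grid, start,
                            jump_factor = 10, min_jump = 0.01,
                            dist_fn = function(a, b) sqrt(sum((a - b)^2))) {
  recs <- vector("list", length(sigma_grid))
  dps <- dcs <- numeric(0)
  prev <- start
  sigma_crit <- NA_real_
  jump_at <- NA_integer_
  for (k in seq_along(sigma_grid)) {
    sol <- solve_fn(sigma_grid[k], prev)
    dp <- dist_fn(sol$par, prev$par)
    dc <- abs(sol$cost - prev$cost)
    recs[[k]] <- list(sigma = sigma_grid[k], sol = sol, dp = dp, dc = dc)
    if (length(dps) >= 3) {
      dp_thr <- max(jump_factor * median(dps), min_jump)
      dc_thr <- jump_factor * median(dcs)
      if (dp > dp_thr && dc > dc_thr) {
        sigma_crit <- sigma_grid[k]
        jump_at <- k
        break
      }
    }
    dps <- c(dps, dp); dcs <- c(dcs, dc)
    prev <- sol
  }
  list(records = recs[!vapply(recs, is.null, logical(1))],
       sigma_crit = sigma_crit, jump_at = jump_at)
}

# per-sigma warm-started collocation solve bound to one dataset/realization
make_sigma_solver <- function(dataset_clean, zeta, mesh, model, bounds,
                              options, control) {
  force(dataset_clean)
  function(sigma, warm) {
    ds <- with_noise(dataset_clean, sigma, zeta)
    prob <- assemble_nlp(ds, mesh, model, bounds, options)
    init <- if (!is.null(warm$record)) warm$record$z else warm$par
    sol <- solve_nlp(prob, init = init, control = control)
    list(par = sol$p_est, cost = sol$cost, record = sol, status = sol$status)
  }
}

#' Ramp a fixed noise realization and detect the basin jump
#'
#' Starting from a converged zero-noise solution, re-solves the
#' assimilation problem warm-started at each amplitude of
#' \code{sigma_grid} (two legs from 0, positive and negative; a negative
#' amplitude is the sign-flipped realization) with
#' \code{V_exp = V_use + sigma * eta(zeta)}.  The critical amplitude is
#' flagged at the first consecutive pair whose interval-scaled parameter
#' jump exceeds \code{jump_factor} times the median inter-step
#' displacement on that leg together with a simultaneous cost
#' discontinuity.
#'
#' @param dataset_clean noise-free twin dataset
#' @param zeta noise realization seed
#' @param p_start converged sigma = 0 solution record (from
#'   [solve_nlp()]); its full decision vector seeds the warm starts
#' @param sigma_grid positive amplitudes for each leg (mV); default
#'   10 uV to 500 uV in 10 uV steps
#' @param legs which legs to ramp: c(-1, 1) (default), 1, or -1
#' @param mesh,model,bounds,options,control as in [assemble_nlp()] /
#'   [solve_nlp()]
#' @param jump_factor,min_jump jump-detection thresholds
#' @return object of class "sigma_ramp_trace": per-leg records
#'   (sigma, parameters, cost, jump metrics), detected sigma_crit (mV or
#'   NA), and the post-jump solution record
#' @export
ramp_and_detect <- function(dataset_clean, zeta, p_start,
                            sigma_grid = seq(0.01, 0.5, by = 0.01),
                            legs = c(-1, 1), mesh = NULL,
                            model = rvlm_model(),
                            bounds = rvlm_bounds("table_widened"),
                            options = list(), control = list(),
                            jump_factor = 10, min_jump = 0.01) {
  stopifnot(inherits(p_start, "solution_record"))
  if (is.null(mesh)) mesh <- uniform_mesh(dataset_clean)
  solver <- make_sigma_solver(dataset_clean, zeta, mesh, model, bounds,
                              options, control)
  start <- list(par = p_start$p_est, cost = p_start$cost,
                record = p_start)
  wd <- rvlm_bounds("table_widened")
  widths <- wd$upper - wd$lower; widths[widths <= 0] <- 1
  dist_fn <- function(a, b) param_jump_norm(a, b, widths)
  out <- list()
  for (lg in legs) {
    leg <- ramp_sigma_core(solver, lg * sigma_grid, start,
                           jump_factor = jump_factor, min_jump = min_jump,
                           dist_fn = dist_fn)
    out[[if (lg > 0) "pos" else "neg"]] <- leg
    if (!is.na(leg$sigma_crit)) break  # first jump wins
  }
  sigma_crit <- NA_real_
  post <- NULL
  for (leg in out) {
    if (!is.na(leg$sigma_crit)) {
      sigma_crit <- leg$sigma_crit
      post <- leg$records[[leg$jump_at]]$sol$record
    }
  }
  structure(list(legs = out, sigma_crit = sigma_crit,
                 post_jump = post, zeta = zeta,
                 sigma_grid = sigma_grid), class = "sigma_ramp_trace")
}

#' @exportS3Method base::print
print.sigma_ramp_trace <- function(x, ...) {
  cat("sigma ramp (zeta =", x$zeta, "): ",
      if (is.na(x$sigma_crit)) "no bifurcation detected"
      else paste0("sigma_crit = ", x$sigma_crit, " mV"), "\n")
  invisible(x)
}

#' Anneal the noise amplitude back to zero
#'
#' From the post-jump solution at \code{sigma_from}, steps the amplitude
#' monotonically to zero (reverse of the ramp grid, same realization and
#' sign), warm-starting every solve.  A further jump during annealing
#' indicates a mis-detected basin and raises an error.
#'
#' @inheritParams ramp_and_detect
#' @param sigma_from signed amplitude (mV) of the post-jump solution
#' @param p_from post-jump solution record
#' @return the sigma = 0 solution record (with the annealing path in
#'   attribute "path")
#' @export
anneal_to_zero <- function(dataset_clean, zeta, sigma_from, p_from,
                           sigma_grid = seq(0.01, 0.5, by = 0.01),
                           mesh = NULL, model = rvlm_model(),
                           bounds = rvlm_bounds("table_widened"),
                           options = list(), control = list(),
                           jump_factor = 10, min_jump = 0.05) {
  if (sigma_from == 0) return(p_from)
  if (is.null(mesh)) mesh <- uniform_mesh(dataset_clean)
  solver <- make_sigma_solver(dataset_clean, zeta, mesh, model, bounds,
                              options, control)
  down <- sigma_grid[sigma_grid < abs(sigma_from)]
  grid <- sign(sigma_from) * c(rev(down), 0)
  if (length(grid) == 0 || grid[length(grid)] != 0) grid <- c(grid, 0)
  prev <- list(par = p_from$p_est, cost = p_from$cost, record = p_from)
  wd <- rvlm_bounds("table_widened")
  widths <- wd$upper - wd$lower; widths[widths <= 0] <- 1
  path <- list()
  for (sg in grid) {
    sol <- solver(sg, prev)
    dp <- param_jump_norm(sol$par, prev$par, widths)
    path[[length(path) + 1]] <- list(sigma = sg, par = sol$par,
                                     cost = sol$cost, dp = dp)
    if (dp > min_jump * jump_factor)
      stop("parameter jump during annealing (dp = ", signif(dp, 3),
           " at sigma = ", sg, "): mis-detected basin")
    prev <- sol
  }
  out <- prev$record
  attr(out, "path") <- path
  out
}

#' Full regularized parameter search
#'
#' The three-step algorithm: (i) solve the inverse problem on smooth
#' (noise-free) data; (ii) apply a fixed noise realization and ramp its
#' amplitude until an abrupt step in both the parameters and the cost is
#' observed; (iii) anneal the amplitude back to zero.  The annealed
#' solution replaces the plain one only if it attains a lower zero-noise
#' cost, so the regularized result is never worse than the plain solve.
#'
#' @param dataset noise-free twin dataset
#' @param init initialization for the plain solve (see [solve_nlp()])
#' @param zeta realization seed for the ramp
#' @inheritParams ramp_and_detect
#' @return list: record (final solution), plain (step-i record), ramp
#'   (sigma_ramp_trace), flag ("regularized", "no-bifurcation",
#'   "ramp-not-better")
#' @export
regularized_search <- function(dataset, init = "midpoint", zeta = 101L,
                               sigma_grid = seq(0.01, 0.5, by = 0.01),
                               mesh = NULL, model = rvlm_model(),
                               bounds = rvlm_bounds("table_widened"),
                               options = list(), control = list(),
                               jump_factor = 10, min_jump = 0.01) {
  if (is.null(mesh)) mesh <- uniform_mesh(dataset)
  prob <- assemble_nlp(dataset, mesh, model, bounds, options)
  plain <- solve_nlp(prob, init = init, control = control)
  ramp <- ramp_and_detect(dataset, zeta, plain, sigma_grid = sigma_grid,
                          mesh = mesh, model = model, bounds = bounds,
                          options = options, control = control,
                          jump_factor = jump_factor, min_jump = min_jump)
  if (is.na(ramp$sigma_crit))
    return(list(record = plain, plain = plain, ramp = ramp,
                flag = "no-bifurcation"))
  annealed <- anneal_to_zero(dataset, zeta, ramp$sigma_crit,
                             ramp$post_jump, sigma_grid = sigma_grid,
                             mesh = mesh, model = model, bounds = bounds,
                             options = options, control = control)
  if (annealed$cost < plain$cost)
    list(record = annealed, plain = plain, ramp = ramp,
         flag = "regularized")
  else
    list(record = plain, plain = plain, ramp = ramp,
         flag = "ramp-not-better")
}

#' Success-rate experiment over random initializations
#'
#' Draws \code{n_runs} parameter initializations uniformly within bounds
#' (states initialized from the data as usual), solves each plainly and
#' -- when \code{with_regularization} -- also through the noise ramp with
#' a fresh recorded realization per run, and scores both against
#' \code{p_ref} with [classify_solution()].
#'
#' @param dataset noise-free twin dataset
#' @param p_ref reference (generating) parameters for scoring
#' @param n_runs number of random initializations (>= 1)
#' @param master_seed seed controlling all draws
#' @param with_regularization also run the ramp pipeline per run
#' @param tol_rel classification tolerance (interval-scaled)
#' @inheritParams ramp_and_detect
#' @return list: success_plain, success_regularized (fractions; the
#'   latter NA when disabled), and a per-run data.frame
#' @export
success_rate_experiment <- function(dataset, p_ref, n_runs = 20,
                                    master_seed = 1L,
                                    with_regularization = TRUE,
                                    tol_rel = 0.01,
                                    sigma_grid = seq(0.01, 0.5, by = 0.01),
                                    mesh = NULL, model = rvlm_model(),
                                    bounds = rvlm_bounds("table_widened"),
                                    options = list(), control = list(),
                                    ramp_control = control,
                                    jump_factor = 10, min_jump = 0.01) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (is.null(mesh)) mesh <- uniform_mesh(dataset)
  lo <- bounds$lower[.param_names]; hi <- bounds$upper[.param_names]
  draws <- local_rng(master_seed, {
    list(inits = matrix(runif(n_runs * 41, lo, hi), nrow = n_runs,
                        byrow = TRUE),
         zetas = sample.int(1e6, n_runs))
  })
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    p0 <- setNames(draws$inits[r, ], .param_names)
    p0["C"] <- 1
    res_plain <- tryCatch(
      assimilate(dataset, init = p0, mesh = mesh, model = model,
                 bounds = bounds, options = options, control = control),
      error = function(e) NULL)
    ok_plain <- !is.null(res_plain) &&
      classify_solution(res_plain$p_est, p_ref,
                        tol_rel)$class == "optimal"
    ok_reg <- if (with_regularization) ok_plain else NA
    flag <- NA_character_
    if (with_regularization && !is.null(res_plain)) {
      reg <- tryCatch({
        ramp <- ramp_and_detect(dataset, draws$zetas[r], res_plain,
                                sigma_grid = sigma_grid, mesh = mesh,
                                model = model, bounds = bounds,
                                options = options, control = ramp_control,
                                jump_factor = jump_factor,
                                min_jump = min_jump)
        if (is.na(ramp$sigma_crit)) list(record = res_plain,
                                         flag = "no-bifurcation")
        else {
          ann <- anneal_to_zero(dataset, draws$zetas[r], ramp$sigma_crit,
                                ramp$post_jump, sigma_grid = sigma_grid,
                                mesh = mesh, model = model,
                                bounds = bounds, options = options,
                                control = ramp_control)
          if (ann$cost < res_plain$cost) list(record = ann,
                                              flag = "regularized")
          else list(record = res_plain, flag = "ramp-not-better")
        }
      }, error = function(e) list(record = res_plain, flag = "ramp-error"))
      flag <- reg$flag
      ok_reg <- classify_solution(reg$record$p_est, p_ref,
                                  tol_rel)$class == "optimal"
    }
    runs[[r]] <- data.frame(
      run = r, zeta = draws$zetas[r],
      plain_optimal = ok_plain,
      reg_optimal = ok_reg, reg_flag = flag,
      plain_cost = if (is.null(res_plain)) NA else res_plain$cost)
  }
  runs <- do.call(rbind, runs)
  list(success_plain = mean(runs$plain_optimal),
       success_regularized = if (with_regularization)
         mean(runs$reg_optimal) else NA_real_,
       runs = runs)
}
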