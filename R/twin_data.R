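#' Piecewise-constant current step protocol
#'
#' @param steps data.frame or list of (duration_ms, amplitude_pA) steps, or
#'   a 2-column matrix
#' @return object of class "current_protocol" with a total duration and an
#'   amplitude lookup (left-closed intervals)
#' @export
build_step_protocol <- function(steps) {
  if (is.matrix(steps)) steps <- data.frame(duration_ms = steps[, 1],
                                            amplitude_pA = steps[, 2])
  if (is.list(steps) && !is.data.frame(steps))
    steps <- do.call(rbind, lapply(steps, function(s)
      data.frame(duration_ms = s[[1]], amplitude_pA = s[[2]])))
  stopifnot(nrow(steps) >= 1)
  if (any(steps$duration_ms <= 0)) stop("step durations must be positive")
  ends <- cumsum(steps$duration_ms)
  structure(list(steps = steps, t_end = c(0, ends),
                 T_total = ends[length(ends)]),
            class = "current_protocol")
}

#' Injected current at given times
#' @param protocol a [build_step_protocol()] object
#' @param t times (ms); times at/beyond the protocol end return the last
#'   amplitude
#' @export
protocol_current <- function(protocol, t) {
  idx <- findInterval(t, protocol$t_end, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(protocol$steps))
  protocol$steps$amplitude_pA[idx]
}

#' Shipped stimulation protocol fixtures
#'
#' Versioned mixed-step protocols used by all recovery experiments.  The
#' published experiments used mixed depolarizing/hyperpolarizing steps of
#' 10-100 ms within 200 ms (and 500 ms variants) but did not print the
#' amplitudes; these fixtures reproduce that structure and were calibrated
#' once so the generating parameter set produces several action potentials,
#' a hyperpolarized episode engaging HCN and CaT de-inactivation, and a
#' post-inhibitory rebound.  Amplitudes in pA for a 2.9e4 um^2 soma.
#'
#' @param name "mixed-200ms-v1" (default), "mixed-500ms-v1", or
#'   "holdout-200ms-v1" (held-out prediction protocol)
#' @export
default_protocol <- function(name = "mixed-200ms-v1") {
  steps <- switch(name,
    "mixed-200ms-v1" = rbind(
      c(10, 0), c(30, 1800), c(10, 0), c(50, -900), c(10, 0),
      c(40, 2400), c(15, -400), c(25, 1300), c(10, 0)),
    "mixed-500ms-v1" = rbind(
      c(20, 0), c(60, 1800), c(30, 0), c(160, -900), c(30, 0),
      c(90, 2400), c(40, -400), c(50, 1300), c(20, 0)),
    "holdout-200ms-v1" = rbind(
      c(15, 0), c(20, 2100), c(20, -700), c(35, 1500), c(15, 0),
      c(30, -1100), c(10, 500), c(35, 2000), c(20, 0)),
    stop("unknown protocol fixture: ", name))
  p <- build_step_protocol(steps)
  p$name <- name
  p
}

#' Forward integration of the model under a protocol
#'
#' Integrates the seven-state ODE with the stiff-capable LSODA solver,
#' segment by segment across protocol discontinuities, and returns the
#' solution sampled on \code{t_grid}.  Integrator failures raise errors;
#' silent NaNs are never returned.
#'
#' @param model an [rvlm_model()]
#' @param p named parameter vector
#' @param x0 initial state (V, m, h, n, q, r, z); default: V = -65 and gates
#'   at steady state, relaxed for \code{settle_ms} under the first step's
#'   current
#' @param protocol a current protocol
#' @param t_grid output times (ms), within the protocol duration
#' @param rtol,atol integrator tolerances
#' @param settle_ms pre-equilibration time when x0 is NULL
#' @return matrix with columns time, V, m, h, n, q, r, z
#' @export
integrate_forward <- function(model, p, x0 = NULL, protocol, t_grid,
                              rtol = 1e-8, atol = 1e-8, settle_ms = 200) {
  p <- validate_params(p)
  consts <- unname(model$consts)
  pn <- as.numeric(p[.param_names])
  if (max(t_grid) > protocol$T_total + 1e-9)
    stop("t_grid extends beyond the protocol duration")
  deriv <- function(t, y, parms)
    list(rvlm_rhs_cpp(y, pn, parms, 0, 0, FALSE, consts))
  if (is.null(x0)) {
    x0 <- c(-65, gate_steady_states(-65, p))
    I0 <- protocol$steps$amplitude_pA[1]
    s <- deSolve::lsoda(x0, c(0, settle_ms), deriv, parms = I0,
                        rtol = rtol, atol = atol)
    x0 <- as.numeric(s[nrow(s), -1])
  }
  # integrate each constant-current segment, collecting requested samples
  bounds <- protocol$t_end
  out <- matrix(NA_real_, length(t_grid), 8)
  y <- as.numeric(x0)
  t_cur <- 0
  for (k in seq_len(nrow(protocol$steps))) {
    t1 <- bounds[k + 1]
    sel <- which(t_grid > t_cur - 1e-12 & t_grid <= t1 + 1e-12)
    tt <- sort(unique(c(t_cur, t_grid[sel], t1)))
    s <- deSolve::lsoda(y, tt, deriv,
                        parms = protocol$steps$amplitude_pA[k],
                        rtol = rtol, atol = atol)
    if (attr(s, "istate")[1] < 0 || any(!is.finite(s[, -1])))
      stop("forward integration failed in segment ", k,
           " (istate = ", attr(s, "istate")[1], ")")
    if (length(sel))
      out[sel, ] <- cbind(t_grid[sel],
                          s[match(round(t_grid[sel], 10),
                                  round(s[, 1], 10)), -1, drop = FALSE])
    y <- as.numeric(s[nrow(s), -1])
    t_cur <- t1
  }
  if (any(!is.finite(out)))
    stop("forward integration produced missing samples")
  colnames(out) <- c("time", "V", "m", "h", "n", "q", "r", "z")
  out
}

#' Seed-determined Gaussian noise realization
#'
#' \eqn{\epsilon_i = \sigma \eta_i} with \eqn{\eta_i} i.i.d. unit normals
#' fully determined by the realization seed \code{zeta}.  A negative
#' \code{sigma} flips the sign of the whole realization (same
#' \eqn{|\epsilon|}, mirrored), which is how signed noise amplitudes are
#' defined throughout the regularizer.  The caller's RNG state is left
#' untouched.
#'
#' @param sigma noise amplitude (mV); may be negative or zero
#' @param zeta integer realization seed
#' @param n_samples number of samples (> 0)
#' @export
sample_noise <- function(sigma, zeta, n_samples) {
  stopifnot(n_samples > 0)
  eta <- local_rng(zeta, rnorm(n_samples))
  sigma * eta
}

# evaluate expr under a private RNG stream seeded with `seed`.
# `seed` is forced before the RNG snapshot so that an RNG-dependent
# seed expression advances the caller's stream exactly once.
local_rng <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a twin-experiment dataset
#'
#' Generates the clean "useful" voltage \code{V_use} by stiff forward
#' integration of the model configured with \code{p_true} on a uniform
#' grid, then the "experimental" trace
#' \code{V_exp = V_use + sigma * eta(zeta)}.  Full provenance (seed, sigma,
#' dt, protocol name) is stored.  The published twin experiment used
#' n = 10,000 mesh intervals at dt = 20 us (T = 200 ms); those are the
#' defaults via \code{dt_base} and the 200 ms protocol.
#'
#' @param model an [rvlm_model()]
#' @param p_true generating parameter vector
#' @param protocol current protocol
#' @param sigma noise amplitude (mV)
#' @param zeta realization seed
#' @param dt_base base mesh step (ms); 0.02 ms = 20 us
#' @param T_total window duration (ms); defaults to the protocol duration
#' @param x0,rtol,atol passed to [integrate_forward()]
#' @return object of class "twin_dataset": data.frame-like list with
#'   t, I_inj, V_use, V_exp, the gate trajectories, and provenance
#' @export
make_twin_dataset <- function(model, p_true, protocol, sigma = 0,
                              zeta = 1L, dt_base = 0.02, T_total = NULL,
                              x0 = NULL, rtol = 1e-8, atol = 1e-8) {
  if (is.null(T_total)) T_total <- protocol$T_total
  n <- round(T_total / dt_base)
  t_grid <- seq(0, by = dt_base, length.out = n + 1)
  tr <- integrate_forward(model, p_true, x0, protocol, t_grid,
                          rtol = rtol, atol = atol)
  eps <- sample_noise(sigma, zeta, n + 1)
  structure(list(
    t = tr[, "time"],
    I_inj = protocol_current(protocol, tr[, "time"]),
    V_use = tr[, "V"],
    V_exp = tr[, "V"] + eps,
    states = tr[, -1],
    sigma = sigma, zeta = zeta, dt_base = dt_base,
    protocol = protocol, p_true = p_true,
    consts = model$consts), class = "twin_dataset")
}

#' Replace the noise of a twin dataset
#'
#' Re-applies \code{V_exp = V_use + sigma * eta(zeta)} without
#' re-integrating; used by the noise-amplitude ramp, which varies sigma
#' while holding the realization fixed.
#'
#' @param dataset a twin dataset
#' @param sigma new amplitude (mV)
#' @param zeta realization seed (defaults to the dataset's)
#' @export
with_noise <- function(dataset, sigma, zeta = dataset$zeta) {
  dataset$V_exp <- dataset$V_use + sample_noise(sigma, zeta,
                                                length(dataset$V_use))
  dataset$sigma <- sigma
  dataset$zeta <- zeta
  dataset
}

#' @exportS3Method base::print
print.twin_dataset <- function(x, ...) {
  cat("twin dataset:", length(x$t), "samples, dt =", x$dt_base,
      "ms, T =", max(x$t), "ms, sigma =", x$sigma, "mV, zeta =", x$zeta,
      "\n")
  invisible(x)
}

#' Adaptive collocation mesh
#'
#' Retains every base-grid sample where the trace is depolarized
#' (\code{V_exp > threshold}) and every m-th sample elsewhere, then
#' regroups the retained samples into 5-point collocation groups (4 mesh
#' intervals per group, last point of a group = first point of the next).
#' Within a group the step is uniform: \code{dt} for groups starting
#' supra-threshold, \code{m*dt} otherwise.  Trailing samples that do not
#' complete a group are trimmed.
#'
#' @param dataset a twin dataset on a uniform base grid
#' @param threshold depolarization threshold (mV), default -65
#' @param m sub-threshold step multiplier, one of 1, 2, 4
#' @param n_retained optionally cap the number of retained mesh intervals
#'   (must be a multiple of 4; gives fixed problem size across m)
#' @return object of class "mesh_plan": retained base indices, group start
#'   offsets (0-based into the retained sequence), per-group step (ms)
#' @export
adaptive_mesh <- function(dataset, threshold = -65, m = 1,
                          n_retained = NULL) {
  if (!m %in% c(1, 2, 4)) stop("m must be one of 1, 2, 4")
  V <- dataset$V_exp
  nb <- length(V)
  dt <- dataset$dt_base
  idx <- integer(0)
  grp_start <- integer(0)
  grp_mult <- integer(0)
  i <- 1L
  while (TRUE) {
    step <- if (V[i] > threshold) 1L else as.integer(m)
    need <- i + 4L * step
    if (need > nb) break
    grp_start <- c(grp_start, length(idx))
    grp_mult <- c(grp_mult, step)
    idx <- c(idx, seq(i, by = step, length.out = 4L))
    i <- need
  }
  if (!length(grp_start)) stop("trace shorter than one collocation group")
  idx <- c(idx, i)  # closing point of the last group
  if (!is.null(n_retained)) {
    stopifnot(n_retained %% 4 == 0)
    G <- n_retained / 4
    if (G > length(grp_start))
      stop("trace supports only ", length(grp_start), " groups")
    grp_start <- grp_start[seq_len(G)]
    grp_mult <- grp_mult[seq_len(G)]
    idx <- idx[seq_len(n_retained + 1)]
  }
  structure(list(index = idx, grp_start = grp_start,
                 grp_dt = grp_mult * dt, threshold = threshold, m = m,
                 dt_base = dt, n_retained = length(idx) - 1L),
            class = "mesh_plan")
}

#' @exportS3Method base::print
print.mesh_plan <- function(x, ...) {
  cat("mesh plan:", x$n_retained, "mesh intervals,",
      length(x$grp_start), "groups, m =", x$m,
      ", threshold =", x$threshold, "mV, T =",
      sum(x$grp_dt * 4), "ms\n")
  invisible(x)
}

#' Uniform mesh over a whole twin dataset
#' @param dataset a twin dataset; its sample count minus 1 must be a
#'   multiple of 4
#' @export
uniform_mesh <- function(dataset) {
  n <- length(dataset$t) - 1L
  if (n %% 4 != 0) stop("sample count - 1 must be a multiple of 4")
  structure(list(index = seq_len(n + 1L),
                 grp_start = seq(0L, n - 4L, by = 4L),
                 grp_dt = rep(dataset$dt_base, n / 4),
                 threshold = Inf, m = 1L, dt_base = dataset$dt_base,
                 n_retained = n), class = "mesh_plan")
}
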