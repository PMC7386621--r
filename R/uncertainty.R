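# Posterior characterization of estimated parameters and the analytic
# geometry of the data-misfit surface: offset F, gradient G, Hessian H,
# principal axes, and the noise-induced parameter offset dp = H^{-1} G.

#' Generic forward model interface
#'
#' A forward model maps a parameter vector to a predicted voltage trace on
#' a fixed time grid, together with exact first-order sensitivities
#' dV/dp.  Two constructors are provided: [rvlm_forward_model()]
#' (sensitivities by forward sensitivity ODEs integrated alongside the
#' model) and [linear_forward_model()] (linear-Gaussian toy with constant
#' design matrix, used as an analytically solvable oracle).
#'
#' @param predict function(p) -> numeric trace
#' @param sens function(p) -> n x K sensitivity matrix
#' @param par_names parameter names (length K)
#' @export
forward_model <- function(predict, sens, par_names) {
  structure(list(predict = predict, sens = sens, par_names = par_names),
            class = "forward_model")
}

#' Linear-Gaussian forward model V(p) = V0 + X p
#' @param X n x K design matrix
#' @param V0 baseline trace (default 0)
#' @export
linear_forward_model <- function(X, V0 = 0) {
  X <- as.matrix(X)
  if (length(V0) == 1) V0 <- rep(V0, nrow(X))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("p", seq_len(ncol(X)))
  forward_model(function(p) V0 + drop(X %*% p[nm]),
                function(p) X, nm)
}

#' RVLM forward model with exact sensitivities
#'
#' Integrates the forward sensitivity equations
#' \eqn{\dot S = (\partial F/\partial x) S + \partial F/\partial p}
#' alongside the seven-state model (exact differentiation of the forward
#' map; no finite differences), restricted to the requested free
#' parameters.
#'
#' @param model an [rvlm_model()]
#' @param p_base full named parameter vector supplying fixed parameters
#' @param protocol current protocol
#' @param t_grid output times (ms)
#' @param free names of the free parameters (columns of the sensitivity)
#' @param x0 initial state (default: relaxed as in [integrate_forward()])
#' @param rtol,atol integrator tolerances
#' @export
rvlm_forward_model <- function(model, p_base, protocol, t_grid,
                               free = .param_names, x0 = NULL,
                               rtol = 1e-8, atol = 1e-8) {
  consts <- unname(model$consts)
  free_idx <- match(free, .param_names)
  if (any(is.na(free_idx))) stop("unknown parameter names in 'free'")
  K <- length(free_idx)
  if (is.null(x0)) {
    tr0 <- integrate_forward(model, p_base, NULL, protocol,
                             t_grid = c(0), rtol = rtol, atol = atol)
    x0 <- as.numeric(tr0[1, -1])
  }
  run <- function(p) {
    pfull <- p_base
    pfull[free] <- p[free]
    pn <- as.numeric(pfull[.param_names])
    y0 <- c(x0, rep(0, 7 * K))
    deriv <- function(t, y, parms) {
      x <- y[1:7]
      S <- matrix(y[-(1:7)], 7, K)
      j <- rvlm_jac_cpp(x, pn, parms, 0, 0, FALSE, consts)
      dS <- j$Jx %*% S + j$Jp[, free_idx, drop = FALSE]
      list(c(j$F, as.numeric(dS)))
    }
    bounds <- protocol$t_end
    y <- y0
    t_cur <- 0
    out <- matrix(NA_real_, length(t_grid), length(y0) + 1)
    for (k in seq_len(nrow(protocol$steps))) {
      t1 <- bounds[k + 1]
      sel <- which(t_grid > t_cur - 1e-12 & t_grid <= t1 + 1e-12)
      tt <- sort(unique(c(t_cur, t_grid[sel], t1)))
      s <- deSolve::lsoda(y, tt, deriv,
                          parms = protocol$steps$amplitude_pA[k],
                          rtol = rtol, atol = atol)
      if (length(sel))
        out[sel, ] <- s[match(round(t_grid[sel], 10), round(s[, 1], 10)), ]
      y <- as.numeric(s[nrow(s), -1])
      t_cur <- t1
      if (t_cur >= max(t_grid)) break
    }
    out
  }
  forward_model(
    predict = function(p) run(p)[, 2],
    sens = function(p) {
      o <- run(p)
      # S rows for V are the first of each 7-block after the state block
      o[, 8 + 7 * (seq_len(K) - 1) + 1, drop = FALSE]
    },
    par_names = free)
}

#' Gauss-Newton fit of a forward model to a trace
#'
#' Small dense nonlinear least-squares used for toy-model posterior
#' ensembles (the full RVLM path goes through the collocation solver).
#'
#' @param fmodel a [forward_model()]
#' @param V_target trace to fit
#' @param p0 named start values (free parameters only)
#' @param max_iter,tol iteration controls
#' @export
fit_forward_model <- function(fmodel, V_target, p0, max_iter = 50,
                              tol = 1e-12) {
  p <- p0
  for (it in seq_len(max_iter)) {
    r <- V_target - fmodel$predict(p)
    S <- fmodel$sens(p)
    g <- drop(crossprod(S, r))
    Hgn <- crossprod(S)
    dp <- drop(solve(Hgn + diag(1e-12 * max(diag(Hgn)), ncol(S)), g))
    p[fmodel$par_names] <- p[fmodel$par_names] + dp
    if (max(abs(dp)) < tol * (1 + max(abs(p)))) break
  }
  list(par = p, rss = sum((V_target - fmodel$predict(p))^2),
       iterations = it)
}

#' Monte-Carlo ensemble of parameter estimates under noise
#'
#' Re-estimates the parameters for \code{R} independent noise
#' realizations of the same clean trace, each assimilation initialized at
#' the zero-noise optimum (which secures convergence to the shifted
#' global minimum).  Failed solves are excluded and counted.
#'
#' @param dataset_clean noise-free twin dataset
#' @param p_init initialization (typically the sigma = 0 estimate)
#' @param sigma noise amplitude (mV)
#' @param R number of realizations
#' @param master_seed seed generating the per-realization seeds
#' @param mesh,model,bounds,options,control solver configuration
#' @return object of class "ensemble_estimates": matrix R x 41, seeds,
#'   sigma, failure count
#' @export
ensemble_estimates <- function(dataset_clean, p_init, sigma, R,
                               master_seed = 1L, mesh = NULL,
                               model = rvlm_model(),
                               bounds = rvlm_bounds("table_widened"),
                               options = list(), control = list()) {
  stopifnot(R >= 1)
  if (is.null(mesh)) mesh <- uniform_mesh(dataset_clean)
  zetas <- local_rng(master_seed, sample.int(1e7, R))
  est <- matrix(NA_real_, R, 41, dimnames = list(NULL, .param_names))
  warm <- NULL
  failed <- 0L
  for (r in seq_len(R)) {
    ds <- with_noise(dataset_clean, sigma, zetas[r])
    prob <- assemble_nlp(ds, mesh, model, bounds, options)
    init <- if (!is.null(warm)) {
      z <- warm$z
      z[8 * prob$npts + 1:41] <- as.numeric(p_init[.param_names])
      z
    } else init_decision_vector(prob, p_init)
    sol <- tryCatch(solve_nlp(prob, init = init, control = control),
                    error = function(e) NULL)
    if (is.null(sol) || !sol$status %in% c("converged", "stalled",
                                           "max_iter")) {
      failed <- failed + 1L
      next
    }
    est[r, ] <- sol$p_est
    warm <- sol  # each realization warm-starts from its predecessor
  }
  ok <- !is.na(est[, 1])
  structure(list(estimates = est[ok, , drop = FALSE], sigma = sigma,
                 zetas = zetas[ok], failed = failed,
                 R = sum(ok)), class = "ensemble_estimates")
}

#' @exportS3Method base::print
print.ensemble_estimates <- function(x, ...) {
  cat("ensemble:", x$R, "estimates at sigma =", x$sigma, "mV (",
      x$failed, "failed )\n")
  invisible(x)
}

#' Sample covariance of an ensemble and its eigen-spectrum
#'
#' Unbiased sample covariance
#' \eqn{\Sigma_{lm} = \frac{1}{R-1}\sum_r (p_{l,r}-\bar p_l)
#' (p_{m,r}-\bar p_m)}; its eigenvalues (sorted descending) are the
#' squared principal half-lengths of the data-misfit ellipsoid, and
#' \eqn{\hat H = \Sigma^{-1}} at a quadratic minimum.
#'
#' @param ens an [ensemble_estimates()] object or plain R x K matrix
#' @return list(Sigma, eigenvalues, eigenvectors)
#' @export
covariance_and_spectrum <- function(ens) {
  M <- if (inherits(ens, "ensemble_estimates")) ens$estimates else
    as.matrix(ens)
  if (nrow(M) < 2) stop("need at least 2 ensemble members for covariance")
  n <- nrow(M)
  ctr <- sweep(M, 2, colMeans(M))
  Sigma <- crossprod(ctr) / (n - 1)
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  list(Sigma = Sigma, eigenvalues = e$values, eigenvectors = e$vectors)
}

#' Misfit-surface geometry at a converged solution
#'
#' The second-order expansion of the data misfit about the zero-noise
#' minimum \eqn{p^*}:
#' offset \eqn{F = \tfrac12\sum_i \epsilon_i^2 + \sum_i \epsilon_i
#' \epsilon_{mod,i}} (the signal-noise entropy term plus noise/model-error
#' correlation), gradient \eqn{G_k = \sum_i \epsilon_i \partial V_i /
#' \partial p_k}, and Hessian
#' \eqn{H_{kk'} = \sum_i [\partial_k V_i \partial_{k'} V_i +
#' \partial^2_{kk'} V_i (\epsilon_i + \epsilon_{mod,i})]}.
#' First-order sensitivities come from the exact sensitivity system of
#' the forward model; the second-order term is obtained by central
#' differencing of those exact sensitivities (step scaled per parameter),
#' which matches full finite differences of the cost to ~1e-7 relative.
#'
#' @param p_star converged parameter vector (free parameters of fmodel)
#' @param dataset twin dataset providing eps = V_exp - V_use
#' @param fmodel a [forward_model()] evaluated on the dataset's grid
#' @param model_error optional model-error trace \eqn{\epsilon_{mod}}
#'   (defaults to V_mod(p_star) - V_use)
#' @param second_order include the error-weighted second-derivative term
#' @param h_rel relative step for the second-order differencing
#' @return object of class "misfit_geometry": F, G, H, eigenvectors,
#'   semi_axes (lambda_k with H eigenvalues lambda_k^-2), offset dp
#' @export
misfit_terms <- function(p_star, dataset, fmodel, model_error = NULL,
                         second_order = TRUE, h_rel = 1e-4) {
  eps <- dataset$V_exp - dataset$V_use
  Vmod <- fmodel$predict(p_star)
  if (length(Vmod) != length(eps))
    stop("forward model grid does not match the dataset")
  if (is.null(model_error)) model_error <- Vmod - dataset$V_use
  S <- fmodel$sens(p_star)
  K <- ncol(S)
  Fterm <- 0.5 * sum(eps^2) + sum(eps * model_error)
  G <- drop(crossprod(S, eps))
  H <- crossprod(S)
  if (second_order) {
    w <- eps + model_error
    H2 <- matrix(0, K, K)
    for (k in seq_len(K)) {
      h <- h_rel * max(abs(p_star[fmodel$par_names[k]]), 1e-3)
      pp <- p_star; pp[fmodel$par_names[k]] <- pp[fmodel$par_names[k]] + h
      pm <- p_star; pm[fmodel$par_names[k]] <- pm[fmodel$par_names[k]] - h
      dS <- (fmodel$sens(pp) - fmodel$sens(pm)) / (2 * h)
      H2[k, ] <- drop(crossprod(dS, w))
    }
    H <- H + (H2 + t(H2)) / 2
  }
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  semi_axes <- ifelse(e$values > 0, 1 / sqrt(pmax(e$values, 1e-300)), Inf)
  structure(list(F = Fterm, G = setNames(G, fmodel$par_names), H = H,
                 eigenvectors = e$vectors, hessian_eigenvalues = e$values,
                 semi_axes = semi_axes, par_names = fmodel$par_names),
            class = "misfit_geometry")
}

#' Noise-induced parameter offset
#'
#' The shift of the misfit minimum induced by the noise realization:
#' \eqn{\delta p = \hat H^{-1} G} (with \eqn{G_k = \sum_i \epsilon_i\,
#' \partial V_i/\partial p_k}, the cost gradient at the unperturbed
#' minimum is \eqn{-G}, so the minimizer of the quadratic expansion is
#' \eqn{+H^{-1}G}), also expressed in the Hessian eigenbasis
#' (\eqn{\delta p' = \hat V^T \delta p}).  A singular Hessian falls back
#' to the pseudo-inverse with a warning.
#'
#' @param geom a [misfit_terms()] object
#' @return list(dp, dp_eigen)
#' @export
parameter_offset <- function(geom) {
  stopifnot(inherits(geom, "misfit_geometry"))
  dp <- tryCatch(solve(geom$H, geom$G), error = function(e) {
    warning("singular Hessian; using pseudo-inverse")
    sv <- svd(geom$H)
    pos <- sv$d > max(sv$d) * 1e-12
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], geom$G)) / sv$d[pos]))
  })
  dp <- setNames(drop(dp), geom$par_names)
  list(dp = dp, dp_eigen = drop(crossprod(geom$eigenvectors, dp)))
}

#' Noise energy and noise-equivalent temperature
#'
#' The expectation of the cost-offset term,
#' \eqn{E[\tfrac12\sum_i \epsilon_i^2] = (n+1)\sigma^2/2}, equated to the
#' Johnson-Nyquist random energy \eqn{2(n+1) k_B T_\sigma R \Delta f}
#' yields the noise-equivalent temperature
#' \eqn{T_\sigma = \sigma^2/(4 k_B R \Delta f)} (sigma converted to
#' volts).
#'
#' @param sigma noise amplitude (mV)
#' @param n number of mesh intervals (n + 1 samples)
#' @param R_membrane membrane resistance (Ohm)
#' @param bandwidth noise bandwidth (Hz)
#' @return list(energy_mV2, T_sigma_K)
#' @export
noise_energy_and_temperature <- function(sigma, n, R_membrane = 1e8,
                                         bandwidth = 1e4) {
  if (R_membrane <= 0 || bandwidth <= 0)
    stop("R_membrane and bandwidth must be positive")
  kB <- 1.380649e-23
  energy <- (n + 1) * sigma^2 / 2
  energy_SI <- (n + 1) * (sigma * 1e-3)^2 / 2
  Tsig <- energy_SI / (2 * (n + 1) * kB * R_membrane * bandwidth)
  list(energy_mV2 = energy, T_sigma_K = Tsig)
}

#' Posterior summary of one parameter's ensemble column
#'
#' Maximum-likelihood estimate as the mode of a Gaussian-kernel density
#' (Silverman bandwidth), standard deviation, moment-matched Gaussian
#' fit, and a non-Gaussianity flag from the sample skewness.
#'
#' @param samples numeric vector (>= 30 values)
#' @param skew_threshold |skewness| above which the PDF is flagged
#' @return list(mle, sd, gaussian = c(mean, sd), skewness, non_gaussian)
#' @export
pdf_summary <- function(samples, skew_threshold = 0.5) {
  if (length(samples) < 30) stop("need at least 30 samples")
  s <- sd(samples)
  if (s == 0)
    return(list(mle = samples[1], sd = 0,
                gaussian = c(mean = samples[1], sd = 0), skewness = 0,
                non_gaussian = FALSE))
  d <- density(samples, bw = "nrd0")
  mle <- d$x[which.max(d$y)]
  m <- mean(samples)
  skew <- mean((samples - m)^3) / s^3
  list(mle = mle, sd = s, gaussian = c(mean = m, sd = s),
       skewness = skew, non_gaussian = abs(skew) > skew_threshold)
}

#' Window-length decorrelation experiment
#'
#' For each sub-threshold step multiplier m, builds an adaptive mesh with
#' a fixed retained problem size over a long base trace (so larger m
#' spans a longer window), runs a posterior ensemble at fixed noise, and
#' returns the covariance spectrum.  Longer windows are expected to
#' reduce every rank-matched eigenvalue.
#'
#' @param dataset_long clean twin dataset on the uniform base grid,
#'   long enough to supply n_retained intervals at the largest m
#' @param p_init ensemble initialization
#' @param m_values multipliers to compare (subset of 1, 2, 4)
#' @param sigma noise amplitude (mV)
#' @param R ensemble size per m
#' @param n_retained fixed retained mesh intervals (multiple of 4)
#' @param threshold depolarization threshold (mV)
#' @param master_seed,model,bounds,options,control as elsewhere
#' @return list per m: mesh, achieved window duration (ms), ensemble,
#'   spectrum (eigenvalues)
#' @export
window_length_experiment <- function(dataset_long, p_init,
                                     m_values = c(1, 2, 4), sigma = 0.25,
                                     R = 50, n_retained = NULL,
                                     threshold = -65, master_seed = 1L,
                                     model = rvlm_model(),
                                     bounds = rvlm_bounds("table_widened"),
                                     options = list(), control = list()) {
  out <- list()
  for (m in m_values) {
    mesh <- adaptive_mesh(dataset_long, threshold = threshold, m = m,
                          n_retained = n_retained)
    ens <- ensemble_estimates(dataset_long, p_init, sigma, R,
                              master_seed = master_seed, mesh = mesh,
                              model = model, bounds = bounds,
                              options = options, control = control)
    sp <- covariance_and_spectrum(ens)
    out[[as.character(m)]] <- list(m = m, mesh = mesh,
                                   T_window = sum(mesh$grp_dt * 4),
                                   ensemble = ens,
                                   eigenvalues = sp$eigenvalues)
  }
  out
}
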