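#' Steady-state gate occupancy
#'
#' Sigmoidal (in)activation curve
#' \eqn{x_\infty(V) = \tfrac12(1 + \tanh((V - V_t)/\delta V))}.  The sign of
#' \code{dV} sets the direction: positive for activation gates, negative for
#' inactivation gates.
#'
#' @param V membrane voltage (mV), vectorized
#' @param g gate parameters as from [gate_params()] (fields V_t, dV,
#'   dV_tau, t0, eps)
#' @return occupancy in \[0, 1\]
#' @export
gate_steady_state <- function(V, g) {
  if (g[["dV"]] == 0) stop("invalid gate parameters: dV must be non-zero")
  0.5 * (1 + tanh((V - g[["V_t"]]) / g[["dV"]]))
}

#' Voltage-dependent gate time constant
#'
#' Bell-shaped recovery time
#' \eqn{\tau(V) = t_0 + \epsilon\,(1 - \tanh^2((V - V_t)/\delta V_\tau))},
#' bounded in \[t0, t0 + eps\]: the recovery time is t0 + eps at the gate
#' threshold and t0 in the fully depolarized/hyperpolarized states.
#'
#' @inheritParams gate_steady_state
#' @return time constant (ms)
#' @export
gate_time_constant <- function(V, g) {
  if (g[["dV_tau"]] <= 0) stop("invalid gate parameters: dV_tau must be > 0")
  th <- tanh((V - g[["V_t"]]) / g[["dV_tau"]])
  g[["t0"]] + g[["eps"]] * (1 - th * th)
}

#' First-order gate relaxation rate
#'
#' \eqn{dx/dt = (x_\infty(V) - x)/\tau(V)}; zero exactly at the
#' voltage-dependent fixed point.
#'
#' @param x gate occupancy in \[0, 1\]
#' @param V membrane voltage (mV)
#' @param g gate parameters
#' @return rate (ms^-1)
#' @export
gate_rhs <- function(x, V, g) {
  (gate_steady_state(V, g) - x) / gate_time_constant(V, g)
}

#' Ohmic ionic current density for one channel
#'
#' \eqn{J = g_\alpha \prod x^{e}\,(E_\alpha - V)} in uA cm^-2, with the
#' channel's gate product: NaT \eqn{m^3 h}, K \eqn{n^4}, HCN \eqn{z}, Leak
#' no gate factor.  The low-threshold calcium current is not ohmic; use
#' [ghk_current_density()].
#'
#' @param channel one of "NaT", "K", "HCN", "Leak"
#' @param V membrane voltage (mV)
#' @param gates named list/vector with the needed gate occupancies
#'   (m, h, n, z)
#' @param p named parameter vector
#' @return current density (uA cm^-2), positive = depolarizing
#' @export
ionic_current_density <- function(channel, V, gates, p) {
  gates <- as.list(gates)
  switch(channel,
    NaT  = p[["g_NaT"]] * gates$m^3 * gates$h * (p[["E_Na"]] - V),
    K    = p[["g_K"]] * gates$n^4 * (p[["E_K"]] - V),
    HCN  = p[["g_H"]] * gates$z * (p[["E_H"]] - V),
    Leak = p[["g_L"]] * (p[["E_L"]] - V),
    stop("unknown channel id: ", channel))
}

#' Goldman-Hodgkin-Katz calcium current density
#'
#' \deqn{J = \bar p\, a^2 i\, \frac{z^2 V F^2}{RT}\,
#'   \frac{[Ca]_i - [Ca]_o e^{-zFV/RT}}{1 - e^{-zFV/RT}}}
#' evaluated continuously through V = 0 (the removable singularity is
#' handled by a series branch).  Returned in uA cm^-2 in the
#' electrophysiological convention (positive = outward); the membrane
#' equation subtracts it, so the calcium current depolarizes at
#' hyperpolarized voltages.
#'
#' @param V membrane voltage (mV), vectorized
#' @param act,inact activation and inactivation gate occupancies
#' @param p_bar maximal permeability in 1e-4 cm s^-1 (table units)
#' @param consts physical constants from [physical_constants()]
#' @return current density (uA cm^-2)
#' @export
ghk_current_density <- function(V, act, inact, p_bar,
                                consts = physical_constants()) {
  if (consts[["Ca_in"]] <= 0 || consts[["Ca_out"]] <= 0)
    stop("calcium concentrations must be positive")
  phi <- vapply(V, ghk_phi_cpp, numeric(1), consts = unname(consts))
  p_bar * 100 * act^2 * inact * phi
}

#' Order-25 Horner polynomial for the GHK voltage factor
#'
#' Builds a degree-25 polynomial approximation of the GHK voltage factor
#' on a declared certification range (default \[-100, 45\] mV) by Chebyshev
#' interpolation, converted to monomial coefficients in the affinely scaled
#' variable and evaluated in Horner form.  A Taylor expansion about V = 0
#' cannot serve here: the factor has complex poles at
#' \eqn{V = \pm 2\pi i RT/(zF) \approx \pm 81i} mV, inside the physiological
#' range, so its Taylor series diverges for |V| > 81 mV.  The Chebyshev
#' construction converges geometrically and meets a 1e-6 relative tolerance
#' with order 25 (in practice ~1e-9).
#'
#' @param range certified voltage range (mV)
#' @param order polynomial order
#' @param consts physical constants
#' @return object of class "ghk_horner": function-like via [ghk_horner_eval()]
#' @export
ghk_horner <- function(range = c(-100, 45), order = 25,
                       consts = physical_constants()) {
  stopifnot(length(range) == 2, range[1] < range[2], order >= 2)
  n <- order + 1
  kk <- seq_len(n) - 1
  # Chebyshev points of the first kind on [-1, 1]
  tch <- cos((2 * kk + 1) * pi / (2 * n))
  a <- range[1]; b <- range[2]
  Vch <- 0.5 * (a + b) + 0.5 * (b - a) * tch
  fch <- vapply(Vch, ghk_phi_cpp, numeric(1), consts = unname(consts))
  # interpolating polynomial in t, monomial basis via Vandermonde solve
  Vand <- outer(tch, 0:order, `^`)
  coef <- solve(Vand, fch)
  structure(list(coef = coef, range = range, order = order,
                 consts = consts),
            class = "ghk_horner")
}

#' Evaluate the GHK Horner polynomial
#'
#' Horner evaluation of the certified polynomial; voltages outside the
#' declared range raise an error because the approximation is not certified
#' there.
#'
#' @param obj object from [ghk_horner()]
#' @param V voltages (mV)
#' @param act,inact,p_bar as in [ghk_current_density()]; if all missing,
#'   the raw voltage factor is returned
#' @export
ghk_horner_eval <- function(obj, V, act = NULL, inact = NULL, p_bar = NULL) {
  stopifnot(inherits(obj, "ghk_horner"))
  if (any(V < obj$range[1] - 1e-9 | V > obj$range[2] + 1e-9))
    stop("voltage outside the certified range [", obj$range[1], ", ",
         obj$range[2], "] mV")
  a <- obj$range[1]; b <- obj$range[2]
  t <- (2 * V - (a + b)) / (b - a)
  acc <- rep(obj$coef[length(obj$coef)], length(t))
  for (i in rev(seq_len(length(obj$coef) - 1))) acc <- acc * t + obj$coef[i]
  if (is.null(act)) return(acc)
  p_bar * 100 * act^2 * inact * acc
}

#' Full membrane right-hand side of the RVLM model
#'
#' Assembles the seven-dimensional rate vector: the voltage equation
#' \eqn{C\,dV/dt = J_{NaT}+J_K+J_{HCN}+J_L - J_{GHK} + I_{inj}/A}
#' (all densities positive-depolarizing; the GHK term carries the
#' electrophysiological sign, hence the subtraction) plus the six
#' first-order gate equations.  In assimilation mode a nudging term
#' \eqn{u\,(V_{exp} - V)} couples the voltage equation to the data;
#' \code{u} and \code{V_exp} must then both be supplied.
#'
#' @param x state vector (V, m, h, n, q, r, z)
#' @param p named parameter vector (41)
#' @param I_inj injected current (pA)
#' @param u control value (nudging gain, ms^-1); NULL in prediction mode
#' @param V_exp observed voltage (mV); NULL in prediction mode
#' @param consts physical constants
#' @return named rate vector of length 7
#' @export
membrane_rhs <- function(x, p, I_inj, u = NULL, V_exp = NULL,
                         consts = physical_constants()) {
  if (is.null(u) != is.null(V_exp))
    stop("u and V_exp must be supplied together (assimilation mode) ",
         "or both absent (prediction mode)")
  nudge <- !is.null(u)
  r <- rvlm_rhs_cpp(as.numeric(x[c(1:7)]), as.numeric(p[.param_names]),
                    I_inj, if (nudge) u else 0,
                    if (nudge) V_exp else 0, nudge, unname(consts))
  setNames(r, c("V", "m", "h", "n", "q", "r", "z"))
}

#' Assembled RVLM model specification
#'
#' Bundles the channel table, state dimension, parameter names and physical
#' constants into one object used by the twin-data and assimilation layers.
#'
#' @param consts physical constants
#' @return object of class "rvlm_model"
#' @export
rvlm_model <- function(consts = physical_constants()) {
  channels <- data.frame(
    id = c("NaT", "K", "HCN", "CaT", "Leak"),
    gates = c("m^3 h", "n^4", "z", "q^2 r (GHK)", ""),
    stringsAsFactors = FALSE)
  structure(list(
    n_states = 7L,
    state_names = c("V", "m", "h", "n", "q", "r", "z"),
    n_params = 41L,
    param_names = .param_names,
    channels = channels,
    consts = consts), class = "rvlm_model")
}

#' @exportS3Method base::print
print.rvlm_model <- function(x, ...) {
  cat("RVLM conductance model:", x$n_states, "state variables,",
      x$n_params, "parameters\n")
  cat("channels:", paste(x$channels$id, collapse = ", "), "\n")
  invisible(x)
}

# steady state of all gates at a voltage
gate_steady_states <- function(V, p) {
  vapply(.gate_names,
         function(g) gate_steady_state(V, gate_params(p, g)),
         numeric(length(V)))
}
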