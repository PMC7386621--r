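#' @useDynLib neuroassim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as new
#' @importFrom stats rnorm runif sd density median cov var setNames
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

# Canonical parameter order used by all numeric kernels.  C (membrane
# capacitance) is carried as parameter 1 with a degenerate search interval,
# so the free-parameter count is 41 while C itself is never estimated.
.param_names <- c(
  "C", "E_Na", "E_K", "E_H", "E_L", "A", "g_NaT",
  "V_m", "dV_m", "dVtau_m", "t_m", "eps_m",
  "V_h", "dV_h", "dVtau_h", "t_h", "eps_h",
  "g_K",
  "V_n", "dV_n", "dVtau_n", "t_n", "eps_n",
  "p_T",
  "V_q", "dV_q", "dVtau_q", "t_q", "eps_q",
  "V_r", "dV_r", "dVtau_r", "t_r", "eps_r",
  "g_H",
  "V_z", "dV_z", "dVtau_z", "t_z", "eps_z",
  "g_L")

.gate_names <- c("m", "h", "n", "q", "r", "z")
.gate_offsets <- c(m = 8L, h = 13L, n = 19L, q = 25L, r = 30L, z = 36L)

#' Physical constants for the GHK calcium current
#'
#' Faraday and gas constants, temperature, calcium valence and the intra-
#' and extracellular calcium concentrations (mol cm^-3).  The concentrations
#' default to typical mammalian values, 1e-4 mM inside and 2 mM outside
#' (1 mM = 1e-6 mol cm^-3); they are configuration, not estimated.
#'
#' @param Ca_in,Ca_out calcium concentrations in mol cm^-3
#' @param T_kelvin temperature in K
#' @return named numeric vector (F, Rgas, T, z, Ca_in, Ca_out)
#' @export
physical_constants <- function(Ca_in = 1e-10, Ca_out = 2e-6,
                               T_kelvin = 298.15) {
  stopifnot(Ca_in > 0, Ca_out > 0, T_kelvin > 0)
  c(F = 96485.33212, Rgas = 8.314462618, T = T_kelvin, z = 2,
    Ca_in = Ca_in, Ca_out = Ca_out)
}

#' Reference parameter table of the RVLM neuron model
#'
#' All 41 model parameters with their published search intervals
#' \code{[lower, upper]}, the generating ("true") values, the optimal
#' estimate at zero noise \code{p0_star}, the noise-shifted global estimate
#' \code{p_sigma_zeta}, and the nearest sub-optimal local-minimum estimate
#' \code{p0_local}.  Units follow the model convention: potentials mV,
#' conductances mS cm^-2, permeability 1e-4 cm s^-1, times ms, area
#' 1e4 um^2, capacitance uF cm^-2.
#'
#' Several printed search intervals exclude the true value (e.g. E_Na,
#' E_K, g_NaT) and the g_K interval is degenerate; see
#' \code{\link{rvlm_bounds}} for the widened intervals used in recovery
#' experiments.
#'
#' @return data.frame with columns name, lower, upper, true, p0_star,
#'   p_sigma_zeta, p0_local
#' @export
rvlm_parameter_table <- function() {
  tab <- rbind(
    # name            lower   upper    true      p0*       psz*      p0l
    c("C",             1.0,    1.0,    1.0,      1.0,      1.0,      1.0),
    c("E_Na",         42,     50,     41,       41.007,   41.075,   60.000),
    c("E_K",         -90,    -80,   -100,     -100.005, -100.763,  -90.000),
    c("E_H",         -30,     -5,    -43,      -42.963,  -42.793,  -30.000),
    c("E_L",        -110,    -65,    -65,      -64.999,  -64.964,  -66.541),
    c("A",             0.04,   0.25,   2.90,     2.90,     2.91,     2.90),
    c("g_NaT",       100,    120,     69,       68.912,   69.924,  100.000),
    c("V_m",         -49,    -27,    -39.92,   -39.921,  -39.965,  -30.931),
    c("dV_m",          5,     32,     10,       10.000,    9.949,   15.850),
    c("dVtau_m",       5,     23.39,  23.39,    23.380,   23.254,    0.100),
    c("t_m",           0.02,   0.7,    0.143,    0.143,    0.157,    0.815),
    c("eps_m",         0.012,  7,      1.099,    1.099,    1.094,   19.543),
    c("V_h",         -79,    -39,    -65.37,   -65.365,  -65.558,  -52.863),
    c("dV_h",        -35,     -5,    -17.65,   -17.652,  -17.629,  -13.752),
    c("dVtau_h",       4,     43,     27.22,    27.218,   27.670,   14.107),
    c("t_h",           0.02,  90,      0.701,    0.701,    0.684,    0.502),
    c("eps_h",         1,    470,     12.9,     12.898,   12.942,   10.629),
    c("g_K",           0,      0,      6.9,      6.905,    6.736,    2.232),
    c("V_n",         -69,    -21,    -34.58,   -34.557,  -34.763,  -39.654),
    c("dV_n",          5,     34,     22.17,    22.178,   21.932,   13.118),
    c("dVtau_n",       5,     34,     23.58,    23.588,   23.851,   21.556),
    c("t_n",           0.01,   5.4,    1.291,    1.291,    1.273,    0.434),
    c("eps_n",         0.002, 23,      4.314,    4.311,    4.248,    6.416),
    c("p_T",           0,     80,      1.035,    1.035,    0.210,    0.130),
    c("V_q",         -80,    -35,    -65.5,    -65.491,  -64.483,  -67.767),
    c("dV_q",          5,     39,     12.4,     12.391,   14.003,    9.958),
    c("dVtau_q",      10,     57,     27,       27.123,   28.911,   14.985),
    c("t_q",           0.02,   0.9,    0.719,    0.693,    2.232,    7.556),
    c("eps_q",         0.5,   97,     13.05,    13.059,   11.759,    8.370),
    c("V_r",         -90,    -55,    -86,      -86.011,  -73.916,  -74.356),
    c("dV_r",        -34,     -5,     -8.06,    -8.065,   -4.547,   -3.962),
    c("dVtau_r",       3,     55,     16.71,    16.760,    9.829,    0.100),
    c("t_r",           5,    190,     28.17,    28.120,   27.435,   55.095),
    c("eps_r",         0.5, 7000,    288.68,   287.067,  319.355, 1000.000),
    c("g_H",           0,     10,      0.150,    0.150,    0.149,    0.177),
    c("V_z",         -90,    -40,    -76,      -76.001,  -76.297,  -79.121),
    c("dV_z",        -30,     -5,     -5.5,     -5.517,   -5.430,  -11.876),
    c("dVtau_z",       5,     40,     20.27,    20.273,   21.861,  100.000),
    c("t_z",           0.1,  500,      6.31,     6.348,    0.100,   10.000),
    c("eps_z",         0.1, 5000,     55.05,    55.019,   60.471,   50.323),
    c("g_L",           0.01,   0.6,    0.465,    0.465,    0.463,    0.482))
  out <- data.frame(name = tab[, 1],
                    lower = as.numeric(tab[, 2]),
                    upper = as.numeric(tab[, 3]),
                    true = as.numeric(tab[, 4]),
                    p0_star = as.numeric(tab[, 5]),
                    p_sigma_zeta = as.numeric(tab[, 6]),
                    p0_local = as.numeric(tab[, 7]),
                    stringsAsFactors = FALSE)
  stopifnot(identical(out$name, .param_names))
  out
}

#' Named true parameter vector of the RVLM model
#' @return named numeric vector of length 41
#' @export
rvlm_true_params <- function() {
  tab <- rvlm_parameter_table()
  setNames(tab$true, tab$name)
}

#' Named reference estimates from the parameter table
#' @param which one of "p0_star", "p_sigma_zeta", "p0_local"
#' @export
rvlm_reference_params <- function(which = c("p0_star", "p_sigma_zeta",
                                            "p0_local")) {
  which <- match.arg(which)
  tab <- rvlm_parameter_table()
  setNames(tab[[which]], tab$name)
}

#' Parameter search bounds
#'
#' Two bound sets are shipped.  \code{"table_as_printed"} reproduces the
#' published intervals verbatim, including the degenerate g_K interval and
#' intervals that exclude the generating value.  \code{"table_widened"}
#' symmetrically enlarges every interval just enough to bracket the
#' generating value with a 25% margin of the final width on each side;
#' degenerate non-C intervals get a width of four times the generating
#' value.  All recovery experiments use the widened set.  C stays pinned
#' at 1 in both sets.
#'
#' @param set "table_widened" (default) or "table_as_printed"
#' @return list with named numeric vectors \code{lower} and \code{upper}
#' @export
rvlm_bounds <- function(set = c("table_widened", "table_as_printed")) {
  set <- match.arg(set)
  tab <- rvlm_parameter_table()
  lo <- setNames(tab$lower, tab$name)
  hi <- setNames(tab$upper, tab$name)
  if (set == "table_as_printed") return(list(lower = lo, upper = hi))
  tr <- setNames(tab$true, tab$name)
  for (i in seq_along(lo)) {
    if (tab$name[i] == "C") next
    mid <- 0.5 * (lo[i] + hi[i])
    half <- 0.5 * (hi[i] - lo[i])
    if (half <= 0) half <- 2 * abs(tr[i])  # degenerate printed interval
    # symmetric enlargement about the printed midpoint; half = 2|true-mid|
    # leaves the true value >= 25% of the final width from either edge
    half <- max(half, 2 * abs(tr[i] - mid))
    lo[i] <- mid - half
    hi[i] <- mid + half
    # keep widened intervals physically/numerically admissible
    if (tab$name[i] %in% c("g_NaT", "g_K", "g_H", "g_L", "p_T"))
      lo[i] <- max(lo[i], 0)
    if (tab$name[i] == "A") lo[i] <- max(lo[i], 0.01)
    if (grepl("^(t_|eps_)", tab$name[i])) lo[i] <- max(lo[i], 1e-3)
    if (grepl("^dVtau_", tab$name[i])) lo[i] <- max(lo[i], 0.01)
    if (grepl("^dV_", tab$name[i])) {   # transition width never crosses 0
      if (tab$upper[i] < 0) hi[i] <- min(hi[i], -0.01)
      else lo[i] <- max(lo[i], 0.01)
    }
  }
  list(lower = lo, upper = hi)
}

#' Validate a parameter set against bounds and structural invariants
#'
#' Checks length, names, finite values, non-zero transition widths dV and
#' positive dV_tau, t0 and nonnegative eps for every gate, and (optionally)
#' containment in a bound set.
#'
#' @param p named numeric vector of length 41
#' @param bounds optional list(lower, upper) as from [rvlm_bounds()]
#' @return p invisibly, or an error
#' @export
validate_params <- function(p, bounds = NULL) {
  if (length(p) != 41L || !all(.param_names %in% names(p)))
    stop("parameter set must contain the 41 named model parameters")
  p <- p[.param_names]
  if (any(!is.finite(p))) stop("non-finite parameter value")
  for (g in .gate_names) {
    if (p[paste0("dV_", g)] == 0) stop("gate ", g, ": dV must be non-zero")
    if (p[paste0("dVtau_", g)] <= 0) stop("gate ", g, ": dV_tau must be > 0")
    if (p[paste0("t_", g)] <= 0) stop("gate ", g, ": t0 must be > 0")
    if (p[paste0("eps_", g)] < 0) stop("gate ", g, ": eps must be >= 0")
  }
  if (!is.null(bounds)) {
    lo <- bounds$lower[.param_names]; hi <- bounds$upper[.param_names]
    bad <- which(p < lo - 1e-12 | p > hi + 1e-12)
    if (length(bad))
      stop("parameters outside bounds: ",
           paste(.param_names[bad], collapse = ", "))
  }
  invisible(p)
}

#' Extract one gate's kinetic parameters
#' @param p named parameter vector
#' @param gate one of "m","h","n","q","r","z"
#' @return named vector (V_t, dV, dV_tau, t0, eps)
#' @export
gate_params <- function(p, gate) {
  gate <- match.arg(gate, .gate_names)
  v <- p[paste0(c("V_", "dV_", "dVtau_", "t_", "eps_"), gate)]
  setNames(as.numeric(v), c("V_t", "dV", "dV_tau", "t0", "eps"))
}
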