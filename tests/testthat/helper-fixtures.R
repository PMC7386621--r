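# Shared fixtures: reduced models and small twin datasets, built in code.

# Leak-only parameter set: all voltage-gated conductances and the calcium
# permeability pinned at zero, so the membrane is a linear RC element.
leak_only_params <- function() {
  p <- rvlm_true_params()
  p[c("g_NaT", "g_K", "g_H", "p_T")] <- 0
  p
}

# Bounds that pin every parameter except `free` (names -> c(lower, upper))
pinned_bounds <- function(p, free) {
  lo <- hi <- p[neuroassim:::.param_names]
  for (nm in names(free)) {
    lo[nm] <- free[[nm]][1]
    hi[nm] <- free[[nm]][2]
  }
  list(lower = lo, upper = hi)
}

# Small leak-only twin dataset (linear dynamics, fast to solve)
leak_dataset <- function(T_total = 10, dt = 0.05, sigma = 0, zeta = 1L,
                         I = 500) {
  p <- leak_only_params()
  pr <- build_step_protocol(rbind(c(2, 0), c(T_total, I)))
  make_twin_dataset(rvlm_model(), p, pr, sigma = sigma, zeta = zeta,
                    dt_base = dt, T_total = T_total)
}

# Short RVLM twin dataset containing one action potential
rvlm_short_dataset <- function(T_total = 24, dt = 0.02, sigma = 0,
                               zeta = 1L) {
  make_twin_dataset(rvlm_model(), rvlm_true_params(),
                    default_protocol("mixed-200ms-v1"), sigma = sigma,
                    zeta = zeta, dt_base = dt, T_total = T_total)
}

solver_ctrl_fast <- function(...) {
  modifyList(list(mu0 = 1e3, nu0 = 1e-2, max_total = 250,
                  max_inner = 80, max_outer = 25), list(...))
}
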