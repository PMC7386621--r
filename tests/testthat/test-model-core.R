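test_that("gate steady state follows the tanh activation curve", {
  g <- list(V_t = -39.92, dV = 10, dV_tau = 23.39, t0 = 0.143, eps = 1.099)
  expect_equal(gate_steady_state(g$V_t, g), 0.5)
  expect_equal(gate_steady_state(g$V_t + g$dV, g),
               0.5 * (1 + tanh(1)), tolerance = 1e-12)
  # activation gate of the sodium channel at -60 mV (direct evaluation)
  expect_equal(gate_steady_state(-60, g),
               0.5 * (1 + tanh((-60 + 39.92) / 10)), tolerance = 1e-12)
  expect_lt(gate_steady_state(-60, g), 0.02)
  # monotone increasing for dV > 0, decreasing for dV < 0
  V <- seq(-100, 40, by = 1)
  expect_true(all(diff(gate_steady_state(V, g)) > 0))
  g$dV <- -10
  expect_true(all(diff(gate_steady_state(V, g)) < 0))
  g$dV <- 0
  expect_error(gate_steady_state(-60, g), "dV")
})

test_that("gate time constant is bell-shaped and bounded", {
  g <- list(V_t = -65.37, dV = -17.65, dV_tau = 27.22, t0 = 0.701,
            eps = 12.9)
  expect_equal(gate_time_constant(g$V_t, g), g$t0 + g$eps)
  expect_equal(gate_time_constant(g$V_t + g$dV_tau, g),
               0.701 + 12.9 * (1 - tanh(1)^2), tolerance = 1e-12)
  expect_equal(gate_time_constant(g$V_t + 50 * g$dV_tau, g), g$t0,
               tolerance = 1e-9)
  V <- seq(-150, 100, by = 0.5)
  tau <- gate_time_constant(V, g)
  expect_true(all(tau >= g$t0 & tau <= g$t0 + g$eps))
})

test_that("gate relaxation matches the closed-form linear ODE", {
  g <- list(V_t = -34.58, dV = 22.17, dV_tau = 23.58, t0 = 1.291,
            eps = 4.314)
  V <- -50  # frozen voltage
  expect_equal(gate_rhs(gate_steady_state(V, g), V, g), 0)
  expect_gt(gate_rhs(0, V, g), 0)  # below steady state -> rises
  x0 <- 0.9
  tt <- seq(0, 20, by = 0.1)
  num <- deSolve::lsoda(x0, tt, function(t, y, parms)
    list(gate_rhs(y, V, g)), NULL, rtol = 1e-10, atol = 1e-10)[, 2]
  xinf <- gate_steady_state(V, g)
  tau <- gate_time_constant(V, g)
  expect_equal(num, xinf + (x0 - xinf) * exp(-tt / tau),
               tolerance = 1e-7)
})

test_that("ohmic current densities follow the conductance model table", {
  p <- rvlm_true_params()
  gates <- list(m = 0.5, h = 0.4, n = 0.3, z = 0.2)
  # zero at the reversal potential
  expect_equal(ionic_current_density("NaT", p[["E_Na"]], gates, p), 0)
  expect_equal(ionic_current_density("K", p[["E_K"]], gates, p), 0)
  # leak at -75 mV with published values: 0.465 * (-65 + 75)
  expect_equal(ionic_current_density("Leak", -75, gates, p), 4.65,
               tolerance = 1e-12)
  gates$m <- 0
  expect_equal(ionic_current_density("NaT", -30, gates, p), 0)
  expect_error(ionic_current_density("CaX", -30, gates, p), "unknown")
})

test_that("GHK current has the analytic V -> 0 limit and reversal", {
  k <- physical_constants()
  pbar <- 1.035
  lim <- pbar * 100 * 0.3^2 * 0.2 * k[["z"]] * k[["F"]] *
    (k[["Ca_in"]] - k[["Ca_out"]])
  expect_equal(ghk_current_density(0, 0.3, 0.2, pbar, k), lim,
               tolerance = 1e-10)
  # continuity through the series branch
  Vs <- c(-2e-3, -1e-4, 0, 1e-4, 2e-3)
  J <- ghk_current_density(Vs, 0.3, 0.2, pbar, k)
  expect_true(all(is.finite(J)))
  expect_lt(max(abs(J - lim)), abs(lim) * 1e-4)
  # closed activation gate
  expect_equal(ghk_current_density(-50, 0, 0.5, pbar, k), 0)
  # zero where Ca_in = Ca_out * exp(-zFV/RT)
  a <- k[["z"]] * k[["F"]] / (k[["Rgas"]] * k[["T"]]) * 1e-3
  Vrev <- log(k[["Ca_out"]] / k[["Ca_in"]]) / a
  expect_equal(ghk_current_density(Vrev, 0.3, 0.2, pbar, k), 0,
               tolerance = 1e-8)
  k2 <- k; k2[["Ca_in"]] <- -1
  expect_error(ghk_current_density(-50, 0.3, 0.2, pbar, k2), "positive")
})

test_that("membrane RHS: leak equilibrium, control term, dimensions", {
  p <- leak_only_params()
  I <- 800
  Veq <- p[["E_L"]] + I * 1e-2 / (p[["A"]] * p[["g_L"]])
  x <- c(Veq, neuroassim:::gate_steady_states(Veq, p))
  r <- membrane_rhs(x, p, I)
  expect_length(r, 7)
  expect_equal(unname(r), rep(0, 7), tolerance = 1e-12)
  # control contributes nothing when V = V_exp
  r2 <- membrane_rhs(x, p, I, u = 0.7, V_exp = Veq)
  expect_equal(r, r2)
  # and pulls toward the data otherwise
  r3 <- membrane_rhs(x, p, I, u = 0.5, V_exp = Veq + 10)
  expect_equal(unname(r3["V"] - r["V"]), 0.5 * 10)
  expect_error(membrane_rhs(x, p, I, u = 0.5), "together")
  # purity: bit-identical repeat evaluations
  xr <- c(-48.3, 0.2, 0.7, 0.1, 0.05, 0.6, 0.12)
  pt <- rvlm_true_params()
  expect_identical(membrane_rhs(xr, pt, 250),
                   membrane_rhs(xr, pt, 250))
})

test_that("assembled model exposes 7 states and 41 bounded parameters", {
  m <- rvlm_model()
  expect_identical(m$n_states, 7L)
  expect_identical(m$n_params, 41L)
  tab <- rvlm_parameter_table()
  expect_identical(nrow(tab), 41L)
  p <- rvlm_true_params()
  expect_silent(validate_params(p))
  wb <- rvlm_bounds("table_widened")
  expect_true(all(p >= wb$lower & p <= wb$upper))
  expect_silent(validate_params(p, wb))
  # the printed intervals exclude some generating values; the widened
  # set must bracket all of them while the printed set errors
  pb <- rvlm_bounds("table_as_printed")
  expect_error(validate_params(p, pb), "outside")
  p_bad <- p; p_bad[["dV_m"]] <- 0
  expect_error(validate_params(p_bad), "non-zero")
  expect_error(validate_params(p[1:40]), "41")
})

test_that("configuration round-trips losslessly through JSON", {
  tmp <- tempfile(fileext = ".json")
  p <- rvlm_true_params()
  b <- rvlm_bounds("table_widened")
  write_config_json(p, b, physical_constants(), tmp)
  cf <- read_config_json(tmp)
  expect_equal(unname(cf$params[neuroassim:::.param_names]),
               unname(p[neuroassim:::.param_names]), tolerance = 1e-14)
  expect_equal(unname(cf$bounds$lower), unname(b$lower),
               tolerance = 1e-14)
  unlink(tmp)
})
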