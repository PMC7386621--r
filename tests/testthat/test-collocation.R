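test_that("Boole residual is exact for polynomial dynamics", {
  dt <- 0.07
  tg <- seq(0, 4 * dt, by = dt)
  # constant F: weights must sum to 4*dt
  x <- 3 + 2.5 * tg
  expect_equal(boole_residual(cbind(x), cbind(rep(2.5, 5)), dt), 0)
  # degree-5 F with exact antiderivative: residual at machine precision
  set.seed(1)
  for (rep in 1:5) {
    cf <- rnorm(6)
    Fv <- outer(tg, 0:5, `^`) %*% cf
    xv <- outer(tg, 1:6, `^`) %*% (cf / (1:6))
    r <- boole_residual(cbind(xv), cbind(Fv), dt)
    expect_lt(abs(r), 1e-14 * max(1, max(abs(xv))))
  }
  # degree-6 dynamics break exactness (sanity that the test has teeth)
  cf <- c(rnorm(6), 2)
  Fv <- outer(tg, 0:6, `^`) %*% cf
  xv <- outer(tg, 1:7, `^`) %*% (cf / (1:7))
  expect_gt(abs(boole_residual(cbind(xv), cbind(Fv), dt)), 1e-12)
  expect_error(boole_residual(cbind(x[1:4]), cbind(rep(1, 4)), dt),
               "5 evenly spaced")
})

test_that("Hermite conditions are exact for cubic trajectories", {
  dt <- 0.11
  tg <- seq(0.3, 0.3 + 4 * dt, by = dt)
  # constant state, zero F
  expect_equal(unname(hermite_residuals(cbind(rep(2, 5)),
                                        cbind(rep(0, 5)), dt)),
               cbind(c(0, 0)))
  # linear state with constant F
  x <- 1 + 4 * tg
  expect_equal(max(abs(hermite_residuals(cbind(x), cbind(rep(4, 5)),
                                         dt))), 0)
  # random cubics with F = dx/dt
  set.seed(2)
  for (rep in 1:5) {
    cf <- rnorm(4)
    xv <- outer(tg, 0:3, `^`) %*% cf
    Fv <- outer(tg, 0:2, `^`) %*% (cf[2:4] * (1:3))
    expect_lt(max(abs(hermite_residuals(cbind(xv), cbind(Fv), dt))),
              1e-13 * max(1, max(abs(xv))))
  }
  # quartics are not matched exactly
  xv <- tg^4; Fv <- 4 * tg^3
  expect_gt(max(abs(hermite_residuals(cbind(xv), cbind(Fv), dt))), 1e-9)
})

test_that("assembled problem has the documented dimensions", {
  ds <- leak_dataset(T_total = 4, dt = 0.05)  # 80 intervals
  mesh <- uniform_mesh(ds)
  prob <- assemble_nlp(ds, mesh)
  G <- 20
  expect_equal(prob$G, G)
  expect_equal(prob$n_boole, 7L * G)          # L x G
  expect_equal(prob$n_hermite, 2L * 8L * G)   # 2 (L + 1) x G
  expect_equal(prob$N, 8L * 81L + 41L)        # 8 per point + parameters
  ev <- prob$eval_fn(init_decision_vector(prob, "midpoint"), TRUE)
  expect_length(ev$c, 23L * G)
  expect_equal(dim(ev$Jc), c(23L * G, prob$N))
  # parameter bounds propagated into the decision-vector box
  wb <- rvlm_bounds("table_widened")
  expect_equal(unname(prob$z_lower[8 * prob$npts + 1:41]),
               unname(wb$lower))
  expect_equal(unname(prob$z_upper[8 * prob$npts + 1:41]),
               unname(wb$upper))
  bad <- wb; bad$lower[["g_L"]] <- bad$upper[["g_L"]] + 1
  expect_error(assemble_nlp(ds, mesh, bounds = bad), "lower > upper")
})

test_that("assimilation cost follows the least-squares definition", {
  V <- c(-65, -64, -63)
  expect_equal(assemble_cost(V, NULL, V), 0)
  V2 <- V; V2[2] <- V[2] + 0.3
  expect_equal(assemble_cost(V2, NULL, V), 0.3^2 / 2)
  expect_equal(assemble_cost(V, c(0.1, 0.2, 0.3), V),
               (0.01 + 0.04 + 0.09) / 2)
  expect_error(assemble_cost(V, c(1, 2), V), "equal lengths")
})

test_that("leak-only toy recovers its two free parameters", {
  ds <- leak_dataset(T_total = 10, dt = 0.05, sigma = 0, I = 500)
  p_true <- leak_only_params()
  bounds <- pinned_bounds(p_true, list(g_L = c(0.1, 0.9),
                                       E_L = c(-90, -40)))
  sol <- assimilate(ds, init = "midpoint", bounds = bounds,
                    control = solver_ctrl_fast())
  expect_lt(abs(sol$p_est[["g_L"]] - p_true[["g_L"]]) / p_true[["g_L"]],
            1e-4)
  expect_lt(abs(sol$p_est[["E_L"]] - p_true[["E_L"]]) /
              abs(p_true[["E_L"]]), 1e-4)
  expect_lt(sol$feasibility, 1e-6)
  # KKT bookkeeping is reported
  expect_true(is.finite(sol$kkt_optimality))
  # restarting from the converged point terminates almost immediately
  prob <- assemble_nlp(ds, uniform_mesh(ds), bounds = bounds)
  sol2 <- solve_nlp(prob, init = sol$z, control = solver_ctrl_fast())
  expect_lt(sol2$iterations, 6)
  expect_equal(sol2$p_est[["g_L"]], sol$p_est[["g_L"]], tolerance = 1e-8)
})

test_that("leak+potassium toy recovers conductances and E_K", {
  p_true <- rvlm_true_params()
  p_true[c("g_NaT", "g_H", "p_T")] <- 0
  pr <- build_step_protocol(rbind(c(2, 0), c(6, 2500), c(4, -500)))
  ds <- make_twin_dataset(rvlm_model(), p_true, pr, sigma = 0,
                          dt_base = 0.05, T_total = 12)
  bounds <- pinned_bounds(p_true, list(g_L = c(0.1, 0.9),
                                       g_K = c(2, 12),
                                       E_K = c(-120, -80)))
  sol <- assimilate(ds, init = "midpoint", bounds = bounds,
                    control = solver_ctrl_fast())
  for (nm in c("g_L", "g_K", "E_K"))
    expect_lt(abs(sol$p_est[[nm]] - p_true[[nm]]) / abs(p_true[[nm]]),
              1e-4)
})

test_that("collocation solution is consistent with forward integration", {
  ds <- leak_dataset(T_total = 8, dt = 0.05, sigma = 0, I = 400)
  p_true <- leak_only_params()
  bounds <- pinned_bounds(p_true, list(g_L = c(0.1, 0.9)))
  sol <- assimilate(ds, init = "midpoint", bounds = bounds,
                    control = solver_ctrl_fast())
  tr <- integrate_forward(rvlm_model(), sol$p_est,
                          x0 = sol$states[1, ], ds$protocol, ds$t)
  expect_lt(max(abs(tr[, "V"] - sol$states[, "V"])), 1e-4)
})

test_that("solutions are classified against interval-scaled tolerance", {
  p <- rvlm_true_params()
  expect_equal(classify_solution(p, p)$class, "optimal")
  p0l <- rvlm_reference_params("p0_local")
  cl <- classify_solution(p0l, p, tol_rel = 0.01)
  expect_equal(cl$class, "suboptimal")
  # the sodium conductance alone is off by >1.5 interval widths
  expect_gt(cl$dev[["g_NaT"]], 1)
  # boundary case: deviation exactly at tolerance counts as optimal
  tab <- rvlm_parameter_table()
  w <- tab$upper - tab$lower
  p2 <- p
  p2[["E_Na"]] <- p[["E_Na"]] + 0.01 * w[tab$name == "E_Na"]
  expect_equal(classify_solution(p2, p, tol_rel = 0.01)$class, "optimal")
})
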