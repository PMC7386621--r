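# 1-D double-well fixture: cost f(x) = x^4/4 - x^2/2 + sigma*x.
# Minima satisfy x^3 - x + sigma = 0; the local minimum near x = +1
# merges with the saddle at the fold sigma_crit = 2/(3*sqrt(3)).
quartic_solver <- function() {
  newton <- function(x, sigma) {
    for (i in 1:100) {
      g <- x^3 - x + sigma
      h <- 3 * x^2 - 1
      if (abs(h) < 1e-9) h <- sign(h + 1e-12) * 1e-9
      step <- g / h
      x <- x - step
      if (abs(step) < 1e-13) break
    }
    x
  }
  function(sigma, warm) {
    x <- newton(warm$par, sigma)
    list(par = x, cost = x^4 / 4 - x^2 / 2 + sigma * x)
  }
}

test_that("ramp detection locates the quartic fold within one grid step", {
  fold <- 2 / (3 * sqrt(3))
  solver <- quartic_solver()
  start <- list(par = 1, cost = 1 / 4 - 1 / 2)  # local min at sigma = 0
  grid <- seq(0.02, 0.6, by = 0.02)
  leg <- neuroassim:::ramp_sigma_core(solver, grid, start,
                                      jump_factor = 10, min_jump = 0.05,
                                      dist_fn = function(a, b) abs(a - b))
  expect_false(is.na(leg$sigma_crit))
  expect_lt(abs(leg$sigma_crit - fold), 0.02 + 1e-9)
  # after the jump the solution sits in the global basin (x < 0)
  expect_lt(leg$records[[leg$jump_at]]$sol$par, 0)
})

test_that("no jump is flagged when the start is already global", {
  solver <- quartic_solver()
  start <- list(par = -1, cost = -1 / 4 - 1 / 2)  # global for sigma > 0
  grid <- seq(0.02, 0.6, by = 0.02)
  leg <- neuroassim:::ramp_sigma_core(solver, grid, start,
                                      jump_factor = 10, min_jump = 0.05,
                                      dist_fn = function(a, b) abs(a - b))
  expect_true(is.na(leg$sigma_crit))
  expect_length(leg$records, length(grid))
})

test_that("annealing from sigma = 0 returns the input unchanged", {
  ds <- leak_dataset(T_total = 4, dt = 0.05, sigma = 0)
  p_true <- leak_only_params()
  bounds <- pinned_bounds(p_true, list(g_L = c(0.1, 0.9)))
  sol <- assimilate(ds, init = "midpoint", bounds = bounds,
                    control = solver_ctrl_fast())
  out <- anneal_to_zero(ds, zeta = 5, sigma_from = 0, p_from = sol)
  expect_identical(out$p_est, sol$p_est)
})

test_that("interval-scaled jump norm behaves like a weighted distance", {
  p <- rvlm_true_params()
  expect_equal(param_jump_norm(p, p), 0)
  p2 <- p; p2[["g_NaT"]] <- p[["g_NaT"]] + 16.4  # one tenth of its width
  expect_equal(param_jump_norm(p2, p), 0.1, tolerance = 1e-6)
})

test_that("regularized search on an easy problem is a clean no-op", {
  # global basin from the start: ramp finds no bifurcation and the
  # plain solution is returned with the no-bifurcation flag
  ds <- leak_dataset(T_total = 4, dt = 0.05, sigma = 0)
  p_true <- leak_only_params()
  bounds <- pinned_bounds(p_true, list(g_L = c(0.2, 0.8)))
  res <- regularized_search(ds, init = "midpoint", zeta = 3,
                            sigma_grid = seq(0.05, 0.2, by = 0.05),
                            bounds = bounds,
                            control = solver_ctrl_fast())
  expect_equal(res$flag, "no-bifurcation")
  expect_lt(abs(res$record$p_est[["g_L"]] - p_true[["g_L"]]) /
              p_true[["g_L"]], 1e-4)
  # the regularized result never has higher cost than the plain solve
  expect_lte(res$record$cost, res$plain$cost + 1e-12)
})
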