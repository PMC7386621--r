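test_that("sample covariance matches hand-computed cases", {
  p2 <- c(1.5, -2)
  M <- rbind(p2, -p2)
  cs <- covariance_and_spectrum(M)
  expect_equal(unname(cs$Sigma),
               2 * outer(p2, p2), tolerance = 1e-12)
  # identical rows give the zero matrix
  M0 <- rbind(c(3, 1, 2), c(3, 1, 2), c(3, 1, 2))
  expect_equal(max(abs(covariance_and_spectrum(M0)$Sigma)), 0)
  expect_error(covariance_and_spectrum(M0[1, , drop = FALSE]),
               "at least 2")
  # eigenvalues sorted descending, spectrum invariant to reordering
  set.seed(5)
  E <- matrix(rnorm(200), 50, 4)
  s1 <- covariance_and_spectrum(E)$eigenvalues
  s2 <- covariance_and_spectrum(E[, c(3, 1, 4, 2)])$eigenvalues
  expect_true(all(diff(s1) <= 1e-12))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("linear-Gaussian ensemble covariance matches sigma^2 (X'X)^-1", {
  set.seed(42)
  n <- 60; K <- 3; sigma <- 0.4; R <- 200
  X <- matrix(rnorm(n * K), n, K)
  colnames(X) <- c("a", "b", "c")
  theta <- c(a = 1, b = -0.5, c = 2)
  fm <- linear_forward_model(X)
  V0 <- fm$predict(theta)
  est <- matrix(NA_real_, R, K)
  for (r in 1:R) {
    y <- V0 + sigma * rnorm(n)
    est[r, ] <- fit_forward_model(fm, y, theta)$par
  }
  Sig <- covariance_and_spectrum(est)$Sigma
  Sig_th <- sigma^2 * solve(crossprod(X))
  # Monte-Carlo error on covariance entries is O(sqrt(2/R)) ~ 10%
  expect_lt(max(abs(Sig - Sig_th)) / max(abs(Sig_th)), 0.3)
})

test_that("noise-induced offset matches direct re-minimization exactly
           on a linear model", {
  set.seed(7)
  n <- 40; K <- 3
  X <- matrix(rnorm(n * K), n, K)
  colnames(X) <- paste0("p", 1:K)
  theta <- c(p1 = 0.3, p2 = -1, p3 = 2)
  fm <- linear_forward_model(X)
  eps <- 0.2 * rnorm(n)
  ds <- list(V_use = fm$predict(theta), V_exp = fm$predict(theta) + eps)
  geom <- misfit_terms(theta, ds, fm, second_order = FALSE)
  off <- parameter_offset(geom)
  # oracle: explicit least-squares re-minimization with the noise
  theta_hat <- drop(solve(crossprod(X), crossprod(X, ds$V_exp)))
  expect_equal(unname(off$dp), unname(theta_hat - theta),
               tolerance = 1e-8)
  # eigenbasis representation is an orthogonal transform
  expect_equal(sum(off$dp^2), sum(off$dp_eigen^2), tolerance = 1e-10)
  # G = 0 (no noise) gives a zero offset
  ds0 <- list(V_use = ds$V_use, V_exp = ds$V_use)
  off0 <- parameter_offset(misfit_terms(theta, ds0, fm,
                                        second_order = FALSE))
  expect_equal(max(abs(off0$dp)), 0)
})

test_that("misfit geometry matches finite differences on a leak toy", {
  ds <- leak_dataset(T_total = 6, dt = 0.1, sigma = 0.3, zeta = 4)
  p <- leak_only_params()
  free <- c("g_L", "E_L")
  fm <- rvlm_forward_model(rvlm_model(), p, ds$protocol, ds$t,
                           free = free,
                           x0 = c(ds$V_use[1],
                                  neuroassim:::gate_steady_states(
                                    ds$V_use[1], p)))
  geom <- misfit_terms(p[free], ds, fm, model_error = rep(0, length(ds$t)),
                       second_order = FALSE)
  # F term: pure noise entropy when model error is zero
  eps <- ds$V_exp - ds$V_use
  expect_equal(geom$F, 0.5 * sum(eps^2), tolerance = 1e-12)
  # G_k = sum eps dV/dp_k vs central finite differences of sum eps V(p)
  for (k in seq_along(free)) {
    h <- 1e-5 * abs(p[[free[k]]])
    pp <- p[free]; pp[k] <- pp[k] + h
    pm <- p[free]; pm[k] <- pm[k] - h
    fd <- (sum(eps * fm$predict(pp)) - sum(eps * fm$predict(pm))) / (2 * h)
    expect_equal(geom$G[[k]], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
  # Gauss-Newton Hessian is S'S
  S <- fm$sens(p[free])
  expect_equal(unname(geom$H), unname(crossprod(S)), tolerance = 1e-10)
})

test_that("one-dimensional offset reduces to G/h", {
  # G is the noise-correlation vector of the expansion; the cost
  # gradient is -G, so the scalar minimizer sits at +G/h
  g1 <- structure(list(F = 1, G = c(a = 3), H = matrix(4),
                       eigenvectors = matrix(1),
                       hessian_eigenvalues = 4, semi_axes = 0.5,
                       par_names = "a"), class = "misfit_geometry")
  expect_equal(unname(parameter_offset(g1)$dp), 3 / 4)
})

test_that("noise energy and equivalent temperature scale correctly", {
  expect_equal(noise_energy_and_temperature(0, 100)$energy_mV2, 0)
  e1 <- noise_energy_and_temperature(0.5, 999)
  e2 <- noise_energy_and_temperature(1.0, 999)
  expect_equal(e2$energy_mV2 / e1$energy_mV2, 4)
  expect_equal(e1$energy_mV2, 1000 * 0.25 / 2)
  expect_gt(e1$T_sigma_K, 0)
  expect_equal(e2$T_sigma_K / e1$T_sigma_K, 4)
  expect_error(noise_energy_and_temperature(0.5, 10, R_membrane = -1),
               "positive")
  # Monte-Carlo mean of the half-sum of squared noise
  n <- 100; sigma <- 0.5; R <- 1000
  set.seed(12)
  vals <- replicate(R, 0.5 * sum((sigma * rnorm(n + 1))^2))
  expected <- (n + 1) * sigma^2 / 2
  se <- sd(vals) / sqrt(R)
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("pdf summaries recover known Gaussian shape", {
  set.seed(31)
  x <- rnorm(2000, mean = 5, sd = 0.7)
  s <- pdf_summary(x)
  expect_lt(abs(s$mle - 5), 0.1)
  expect_lt(abs(s$sd - 0.7), 0.05)
  expect_false(s$non_gaussian)
  # strongly skewed sample is flagged
  y <- rexp(2000)
  expect_true(pdf_summary(y)$non_gaussian)
  # degenerate sample
  s0 <- pdf_summary(rep(2, 50))
  expect_equal(s0$sd, 0)
  expect_error(pdf_summary(rnorm(10)), "30")
})

test_that("RVLM forward-model sensitivities match finite differences", {
  p <- rvlm_true_params()
  pr <- build_step_protocol(rbind(c(2, 0), c(6, 1500)))
  tt <- seq(0, 8, by = 0.1)
  x0 <- c(-65, neuroassim:::gate_steady_states(-65, p))
  fm <- rvlm_forward_model(rvlm_model(), p, pr, tt,
                           free = c("g_L", "E_Na"), x0 = x0)
  S <- fm$sens(p[c("g_L", "E_Na")])
  for (k in 1:2) {
    nm <- c("g_L", "E_Na")[k]
    h <- 1e-5 * abs(p[[nm]])
    pp <- p[c("g_L", "E_Na")]; pp[k] <- pp[k] + h
    pm <- p[c("g_L", "E_Na")]; pm[k] <- pm[k] - h
    fd <- (fm$predict(pp) - fm$predict(pm)) / (2 * h)
    expect_lt(max(abs(fd - S[, k])) / max(abs(fd)), 1e-4)
  }
})
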