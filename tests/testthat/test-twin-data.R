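test_that("step protocols resolve amplitudes on left-closed intervals", {
  pr <- build_step_protocol(rbind(c(100, 0), c(100, 250)))
  expect_equal(pr$T_total, 200)
  expect_equal(protocol_current(pr, 150), 250)
  expect_equal(protocol_current(pr, 0), 0)
  expect_equal(protocol_current(pr, 100), 250)  # left-closed second step
  expect_equal(protocol_current(pr, c(50, 150)), c(0, 250))
  expect_error(build_step_protocol(rbind(c(0, 5))), "positive")
  single <- build_step_protocol(rbind(c(40, 120)))
  expect_true(all(protocol_current(single, c(0, 10, 39.9)) == 120))
})

test_that("leak-only forward integration matches the RC closed form", {
  p <- leak_only_params()
  I <- 500
  pr <- build_step_protocol(rbind(c(20, I)))
  mdl <- rvlm_model()
  V0 <- p[["E_L"]]
  x0 <- c(V0, neuroassim:::gate_steady_states(V0, p))
  tt <- seq(0, 20, by = 0.05)
  tr <- integrate_forward(mdl, p, x0, pr, tt)
  Vinf <- p[["E_L"]] + I * 1e-2 / (p[["A"]] * p[["g_L"]])
  tau <- 1 / p[["g_L"]]  # C = 1 uF cm^-2
  expect_equal(tr[, "V"], Vinf + (V0 - Vinf) * exp(-tt / tau),
               tolerance = 1e-7)
})

test_that("forward integration is self-convergent under refinement", {
  mdl <- rvlm_model(); p <- rvlm_true_params()
  pr <- default_protocol("mixed-200ms-v1")
  # sub-threshold window: pointwise comparison is meaningful (across a
  # spike, a tolerance-level time shift dominates the pointwise error)
  tt <- seq(0, 14, by = 0.02)
  a <- integrate_forward(mdl, p, NULL, pr, tt, rtol = 1e-6, atol = 1e-6)
  b <- integrate_forward(mdl, p, NULL, pr, tt, rtol = 1e-9, atol = 1e-9)
  expect_lt(max(abs(a[, "V"] - b[, "V"])), 1e-3)
  # gates remain within [0,1] along a spiking trace
  tt2 <- seq(0, 24, by = 0.02)
  b2 <- integrate_forward(mdl, p, NULL, pr, tt2, rtol = 1e-8,
                          atol = 1e-8)
  expect_true(all(b2[, 3:8] >= 0 & b2[, 3:8] <= 1))
})

test_that("noise realizations are seed-determined and sign-antisymmetric", {
  expect_identical(sample_noise(0, 42, 100), rep(0, 100))
  e1 <- sample_noise(0.5, 42, 1000)
  e2 <- sample_noise(0.5, 42, 1000)
  expect_identical(e1, e2)
  expect_identical(sample_noise(-0.5, 42, 1000), -e1)
  expect_false(identical(sample_noise(0.5, 43, 1000), e1))
  # sample sd concentrates around sigma (chi-square bound, n = 1e4)
  n <- 1e4
  s <- sd(sample_noise(0.5, 7, n))
  expect_lt(abs(s - 0.5), 3 * 0.5 / sqrt(2 * n))
  # caller's RNG stream is untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(sample_noise(1, 9, 10)); b <- runif(1)
  expect_identical(a, b)
})

test_that("twin datasets carry provenance and are bit-reproducible", {
  ds <- leak_dataset(T_total = 5, dt = 0.05, sigma = 0.25, zeta = 9)
  ds2 <- leak_dataset(T_total = 5, dt = 0.05, sigma = 0.25, zeta = 9)
  expect_identical(ds$V_exp, ds2$V_exp)
  expect_equal(ds$V_exp - ds$V_use, sample_noise(0.25, 9, length(ds$t)))
  ds0 <- leak_dataset(T_total = 5, dt = 0.05, sigma = 0)
  expect_identical(ds0$V_exp, ds0$V_use)
  # 200 ms at 20 us steps spans 10,000 mesh intervals
  dsf <- make_twin_dataset(rvlm_model(), rvlm_true_params(),
                           default_protocol("mixed-200ms-v1"),
                           sigma = 0, dt_base = 0.02)
  expect_length(dsf$t, 10001L)
  expect_equal(max(dsf$t), 200)
  # with_noise swaps the realization without re-integrating
  dsn <- with_noise(ds0, 0.1, 5)
  expect_identical(dsn$V_use, ds0$V_use)
  expect_equal(dsn$V_exp - dsn$V_use, sample_noise(0.1, 5, length(ds0$t)))
})

test_that("twin dataset CSV round-trips through the sidecar", {
  ds <- leak_dataset(T_total = 4, dt = 0.05, sigma = 0.2, zeta = 3)
  tmp <- tempfile(fileext = ".csv")
  write_twin_csv(ds, tmp)
  back <- read_twin_csv(tmp)
  expect_equal(back$V_exp, unname(ds$V_exp))
  expect_equal(back$sigma, 0.2)
  expect_equal(back$zeta, 3)
  expect_equal(back$protocol$T_total, ds$protocol$T_total)
  unlink(c(tmp, paste0(tmp, ".json")))
})

test_that("adaptive mesh retains, groups and trims correctly", {
  ds <- rvlm_short_dataset(T_total = 24)
  # threshold below everything: uniform mesh at the base step
  mp <- adaptive_mesh(ds, threshold = -200, m = 4)
  expect_true(all(mp$grp_dt == ds$dt_base))
  expect_equal(mp$index, seq_len(mp$n_retained + 1L))
  # threshold above everything: every m-th sample retained
  mp4 <- adaptive_mesh(ds, threshold = 100, m = 4)
  expect_true(all(mp4$grp_dt == 4 * ds$dt_base))
  expect_equal(diff(mp4$index[1:9]), rep(4L, 8))
  # group structure: 5 points spanning 4 intervals, shared endpoints
  mp2 <- adaptive_mesh(ds, threshold = -60, m = 2)
  expect_equal(mp2$n_retained %% 4, 0)
  expect_equal(length(mp2$grp_start), mp2$n_retained / 4)
  expect_equal(mp2$grp_start, seq(0L, mp2$n_retained - 4L, by = 4L))
  # mixed steps appear when the trace crosses the threshold
  expect_true(length(unique(mp2$grp_dt)) == 2)
  # n_retained cap gives fixed problem size
  mp_c <- adaptive_mesh(ds, threshold = -60, m = 2, n_retained = 400)
  expect_equal(mp_c$n_retained, 400L)
  expect_length(mp_c$index, 401L)
  expect_error(adaptive_mesh(ds, threshold = -65, m = 3), "m must be")
})

test_that("a 200 ms supra-threshold trace yields 2,500 uniform groups", {
  # uniform grid of n = 10,000 intervals grouped in fives -> n/4 groups
  fake <- structure(list(t = seq(0, 200, by = 0.02),
                         V_exp = rep(0, 10001), I_inj = rep(0, 10001),
                         V_use = rep(0, 10001), dt_base = 0.02),
                    class = "twin_dataset")
  mp <- adaptive_mesh(fake, threshold = -65, m = 1)
  expect_equal(length(mp$grp_start), 2500L)
  um <- uniform_mesh(fake)
  expect_equal(length(um$grp_start), 2500L)
  expect_equal(um$n_retained, 10000L)
})
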