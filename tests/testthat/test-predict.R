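# synthetic spike train: Gaussian bumps on a resting baseline
bump_trace <- function(t, centers, height = 80, width = 0.6,
                       base = -65) {
  V <- rep(base, length(t))
  for (cc in centers) V <- V + height * exp(-(t - cc)^2 / (2 * width^2))
  V
}

test_that("identical traces give zero error and no mismatches", {
  t <- seq(0, 100, by = 0.1)
  V <- bump_trace(t, c(20, 50, 80))
  rep <- compare_traces(V, V, t)
  expect_equal(rep$rms, 0)
  expect_equal(rep$missed, 0)
  expect_equal(rep$spurious, 0)
  expect_length(rep$spikes_reference, 3)
  expect_error(compare_traces(V[-1], V, t), "common time grid")
})

test_that("shifted and deleted spikes are counted as mismatches", {
  t <- seq(0, 100, by = 0.1)
  ref <- bump_trace(t, c(20, 40, 60, 75, 90))
  # all five shifted beyond the matching window
  shifted <- bump_trace(t, c(20, 40, 60, 75, 90) + 5)
  rep <- compare_traces(shifted, ref, t, match_window = 2)
  expect_equal(rep$missed, 5)
  expect_equal(rep$spurious, 5)
  # one deleted spike
  del <- bump_trace(t, c(20, 40, 60, 90))
  rep2 <- compare_traces(del, ref, t)
  expect_equal(rep2$missed, 1)
  expect_equal(rep2$spurious, 0)
  # small shifts within the window still match
  close <- bump_trace(t, c(20, 40, 60, 75, 90) + 0.8)
  rep3 <- compare_traces(close, ref, t, match_window = 2)
  expect_equal(rep3$missed + rep3$spurious, 0)
})

test_that("spike counts are invariant to sub-threshold offsets", {
  t <- seq(0, 60, by = 0.1)
  ref <- bump_trace(t, c(15, 45))
  rep0 <- compare_traces(ref, ref, t)
  rep1 <- compare_traces(ref + 5, ref, t)  # offset below threshold margin
  expect_equal(length(rep1$spikes_predicted),
               length(rep0$spikes_predicted))
  expect_equal(rep1$missed, 0)
  expect_gt(rep1$rms, 0)
})

test_that("refractory gap suppresses double counting", {
  t <- seq(0, 20, by = 0.01)
  # two bumps 1 ms apart: one spike at 2 ms refractory
  V <- bump_trace(t, c(10, 11), width = 0.3)
  expect_length(detect_spikes(t, V, -20, refractory = 2), 1)
  expect_length(detect_spikes(t, V, -20, refractory = 0.5), 2)
})

test_that("prediction is nudging-free and reproduces the generating trace", {
  p <- leak_only_params()
  pr <- build_step_protocol(rbind(c(3, 0), c(5, 600)))
  ds <- make_twin_dataset(rvlm_model(), p, pr, sigma = 0, dt_base = 0.05)
  tr <- predict_voltage(p, pr, t_grid = ds$t,
                        x0 = c(ds$V_use[1],
                               neuroassim:::gate_steady_states(
                                 ds$V_use[1], p)))
  expect_lt(max(abs(tr[, "V"] - ds$V_use)), 1e-5)
})

test_that("parameter distances follow the published table ordering", {
  p_true <- rvlm_true_params()
  p0l <- rvlm_reference_params("p0_local")
  psz <- rvlm_reference_params("p_sigma_zeta")
  d_local <- parameter_distance(p0l, p_true)
  d_shift <- parameter_distance(psz, p_true)
  # the nearest local minimum lies farther from truth than the
  # noise-shifted global minimum, in both metrics
  expect_gt(d_local$euclidean, d_shift$euclidean)
  expect_gt(d_local$interval_scaled, d_shift$interval_scaled)
  expect_equal(parameter_distance(p_true, p_true)$euclidean, 0)
  # symmetry
  expect_equal(parameter_distance(p0l, p_true)$euclidean,
               parameter_distance(p_true, p0l)$euclidean)
  expect_error(parameter_distance(p_true[1:5], p_true), "mismatch")
})
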