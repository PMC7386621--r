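#' Predict the membrane voltage of a fitted model
#'
#' Nudging-free forward integration (no control term, no data coupling):
#' the prediction depends only on the parameters, protocol and initial
#' state, never on any observed trace.
#'
#' @param p_set named parameter vector
#' @param protocol current protocol (typically held out from fitting)
#' @param t_grid output times (ms); default 0.02 ms steps over the
#'   protocol
#' @param x0 initial state or NULL (relaxed default)
#' @param model an [rvlm_model()]
#' @param rtol,atol integrator tolerances
#' @return matrix with columns time, V, m, h, n, q, r, z
#' @export
predict_voltage <- function(p_set, protocol, t_grid = NULL, x0 = NULL,
                            model = rvlm_model(), rtol = 1e-8,
                            atol = 1e-8) {
  if (is.null(t_grid))
    t_grid <- seq(0, protocol$T_total, by = 0.02)
  integrate_forward(model, p_set, x0, protocol, t_grid, rtol, atol)
}

#' Detect spike times by threshold crossing
#'
#' Upward crossings of the threshold with a refractory gap.
#'
#' @param t,V trace
#' @param threshold spike threshold (mV)
#' @param refractory minimum inter-spike time (ms)
#' @export
detect_spikes <- function(t, V, threshold = -20, refractory = 2) {
  up <- which(V[-1] > threshold & V[-length(V)] <= threshold) + 1L
  if (!length(up)) return(numeric(0))
  keep <- up[1]
  for (i in up[-1]) if (t[i] - t[keep[length(keep)]] >= refractory)
    keep <- c(keep, i)
  t[keep]
}

#' Compare a predicted trace with a reference trace
#'
#' Pointwise error trace (predicted - reference), RMS error, and a spike
#' mismatch summary: spikes are upward threshold crossings with a
#' refractory gap, matched greedily within a tolerance window; unmatched
#' reference spikes are "missed", unmatched predicted spikes "spurious".
#'
#' @param predicted,reference voltage traces on a common time grid (mV)
#' @param t common time grid (ms)
#' @param spike_threshold detection threshold (mV)
#' @param refractory refractory gap (ms)
#' @param match_window matching tolerance (ms)
#' @return object of class "prediction_report"
#' @export
compare_traces <- function(predicted, reference, t,
                           spike_threshold = -20, refractory = 2,
                           match_window = 2) {
  if (length(predicted) != length(reference) ||
      length(t) != length(predicted))
    stop("traces must share a common time grid")
  err <- predicted - reference
  sp_p <- detect_spikes(t, predicted, spike_threshold, refractory)
  sp_r <- detect_spikes(t, reference, spike_threshold, refractory)
  used <- logical(length(sp_p))
  matched <- 0L
  for (s in sp_r) {
    cand <- which(!used & abs(sp_p - s) <= match_window)
    if (length(cand)) {
      used[cand[which.min(abs(sp_p[cand] - s))]] <- TRUE
      matched <- matched + 1L
    }
  }
  structure(list(
    error = err, rms = sqrt(mean(err^2)),
    spikes_reference = sp_r, spikes_predicted = sp_p,
    missed = length(sp_r) - matched,
    spurious = sum(!used)), class = "prediction_report")
}

#' @exportS3Method base::print
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction: RMS error %.4g mV; %d reference spikes, %d missed, %d spurious\n",
              x$rms, length(x$spikes_reference), x$missed, x$spurious))
  invisible(x)
}

#' Distance between parameter sets
#'
#' Raw Euclidean norm of the difference (the published convention) and
#' the interval-normalized variant (each coordinate divided by its search
#' width, appropriate given the heterogeneous units); both are reported.
#'
#' @param p,p_ref named parameter vectors over the same names
#' @param widths optional per-parameter widths for the normalized form
#' @return list(euclidean, interval_scaled)
#' @export
parameter_distance <- function(p, p_ref, widths = NULL) {
  nm <- names(p)
  if (is.null(nm) || !setequal(nm, names(p_ref)))
    stop("parameter name mismatch")
  d <- p[nm] - p_ref[nm]
  if (is.null(widths)) {
    b <- rvlm_bounds("table_widened")
    widths <- (b$upper - b$lower)[nm]
    widths[widths <= 0] <- 1
  }
  list(euclidean = sqrt(sum(d^2)),
       interval_scaled = sqrt(sum((d / widths[nm])^2)))
}
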