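#' Common average referencing
#'
#' Subtracts the per-sample mean across channels from every channel, the
#' standard first step for removing signals shared across an electrode
#' array.
#'
#' @param traces channels x samples numeric matrix.
#' @return Matrix of the same shape whose per-sample channel mean is zero.
#' @export
common_average_reference <- function(traces) {
  if (!is.matrix(traces) || nrow(traces) < 2) {
    stop("common average referencing needs >= 2 channels", call. = FALSE)
  }
  sweep(traces, 2, colMeans(traces), "-")
}

#' Band-pass filter specification
#'
#' @param low_hz,high_hz band edges (Hz).
#' @param order Butterworth design order.
#' @return List of class `"filter_spec"`.
#' @export
filter_spec <- function(low_hz = 300, high_hz = 5000, order = 4L) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the band-pass of `spec` forward and backward
#' (`signal::filtfilt`), giving zero phase shift so spike and response
#' latencies downstream are not biased by filter delay.
#'
#' @param trace numeric vector (one channel).
#' @param fs sampling rate (Hz); must exceed twice the upper band edge.
#' @param spec a [filter_spec()].
#' @return Filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$high_hz) {
    stop("sampling rate ", fs, " Hz violates Nyquist for high edge ",
         spec$high_hz, " Hz", call. = FALSE)
  }
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  n <- length(trace)
  # forward-backward pass over an odd-reflection-padded trace; the pad
  # spans many time constants of the low band edge so the zero-state
  # startup transients decay outside the returned segment
  pad <- min(n - 1, ceiling(10 * fs / spec$low_hz))
  head_pad <- 2 * trace[1] - trace[(pad + 1):2]
  tail_pad <- 2 * trace[n] - trace[(n - 1):(n - pad)]
  y <- signal::filter(bf, c(head_pad, trace, tail_pad))
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Spike detection specification
#'
#' The detection threshold is `threshold_factor` times a median-based noise
#' estimate of the filtered trace: `median_abs` reads the estimator
#' literally as `median(|x|)`; `scaled_median_abs` applies the conventional
#' Gaussian calibration `median(|x|) / 0.6745`.
#'
#' @param threshold_factor multiplier on the noise estimate (default 7.5).
#' @param noise_estimator `"median_abs"` or `"scaled_median_abs"`.
#' @param refractory_window events closer than this (s) collapse to the
#'   largest-amplitude one.
#' @param polarity which threshold crossings count as events.
#' @return List of class `"detection_spec"`.
#' @export
detection_spec <- function(threshold_factor = 7.5,
                           noise_estimator = c("median_abs",
                                               "scaled_median_abs"),
                           refractory_window = 0.001,
                           polarity = c("negative", "positive", "both")) {
  stopifnot(threshold_factor > 0, refractory_window >= 0)
  structure(list(threshold_factor = threshold_factor,
                 noise_estimator = match.arg(noise_estimator),
                 refractory_window = refractory_window,
                 polarity = match.arg(polarity)),
            class = "detection_spec")
}

#' Amplitude-threshold spike detection
#'
#' Detects putative spike events as excursions beyond
#' `threshold_factor x noise_estimate(|trace|)`. Contiguous supra-threshold
#' runs are reduced to the sample of extreme amplitude, and events closer
#' than the refractory window are merged, keeping the larger excursion. An
#' all-zero trace has noise estimate 0 and returns no events.
#'
#' @param trace filtered single-channel trace.
#' @param fs sampling rate (Hz).
#' @param spec a [detection_spec()].
#' @return Event times in seconds (first sample = time 0).
#' @export
detect_spikes <- function(trace, fs, spec = detection_spec()) {
  noise <- stats::median(abs(trace))
  if (spec$noise_estimator == "scaled_median_abs") noise <- noise / 0.6745
  theta <- spec$threshold_factor * noise
  if (theta <= 0) return(numeric(0))

  x <- switch(spec$polarity,
              negative = -trace,
              positive = trace,
              both = abs(trace))
  above <- x > theta
  if (!any(above)) return(numeric(0))
  # contiguous supra-threshold runs -> sample of extreme amplitude
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peak_idx <- vapply(runs, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    i0 + which.max(x[i0:i1]) - 1L
  }, integer(1))
  peak_amp <- x[peak_idx]

  # merge events inside the refractory window, keeping the larger one
  if (spec$refractory_window > 0 && length(peak_idx) > 1) {
    min_gap <- spec$refractory_window * fs
    keep <- rep(TRUE, length(peak_idx))
    last <- 1L
    for (i in 2:length(peak_idx)) {
      if (peak_idx[i] - peak_idx[last] < min_gap) {
        if (peak_amp[i] > peak_amp[last]) {
          keep[last] <- FALSE
          last <- i
        } else {
          keep[i] <- FALSE
        }
      } else {
        last <- i
      }
    }
    peak_idx <- peak_idx[keep]
  }
  (peak_idx - 1L) / fs
}

#' Retain units above a mean-rate floor
#'
#' Keeps units whose overall mean firing rate (spike count divided by the
#' session duration) exceeds `min_rate`; used as the inclusion rule for
#' sparsely firing cortical populations.
#'
#' @param units list of units (`unit_id`, `tetrode_id`, `spike_times`).
#' @param duration session duration (s), > 0.
#' @param min_rate rate floor (Hz), default 0.5.
#' @return The retained subset of `units`.
#' @export
filter_units_by_rate <- function(units, duration, min_rate = 0.5) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("session duration must be > 0", call. = FALSE)
  }
  keep <- vapply(units, function(u) {
    length(u$spike_times) / duration > min_rate
  }, logical(1))
  units[keep]
}

#' Deduplicate units recorded on the same tetrode across sessions
#'
#' The same cells can be picked up on the same tetrode in subsequent
#' recording sessions of one animal. For pooled analyses, only units from
#' the first session in which a tetrode appears are retained; units on
#' that tetrode in later sessions are dropped.
#'
#' @param sessions list of `"recording_session"` objects in temporal order.
#' @return The sessions with duplicated-tetrode units removed.
#' @export
dedup_units <- function(sessions) {
  seen <- numeric(0)
  lapply(sessions, function(s) {
    tet <- vapply(s$units, function(u) {
      if (is.null(u$tetrode_id)) {
        stop("unit ", u$unit_id, " in session ", s$session_id,
             " has no tetrode_id", call. = FALSE)
      }
      as.numeric(u$tetrode_id)
    }, numeric(1))
    s$units <- s$units[!(tet %in% seen)]
    seen <<- union(seen, tet)
    s
  })
}
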