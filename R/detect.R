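#' Spike-detection parameters
#'
#' Defaults follow the standard MEA chain for these recordings: 2nd-order
#' Butterworth high-pass at 300 Hz, detection threshold at 7 times the
#' MAD-based noise sigma, 2 ms dead time between accepted events, and
#' (when a stimulation protocol is supplied) 2 ms of blanking after each
#' pulse onset to keep the stimulus artifact out of the peak search.
#'
#' @param highpass_cutoff_hz high-pass cutoff, Hz.
#' @param filter_order Butterworth order.
#' @param threshold_multiplier threshold in units of noise sigma.
#' @param dead_time_ms minimum spacing between accepted events, ms.
#' @param artifact_blank_ms post-pulse blanking, ms (used only when a
#'   protocol is given to [detect_spikes()]).
#' @param mad_normalize if TRUE (default) the noise sigma is MAD/0.6745,
#'   the Quiroga convention for Gaussian noise; if FALSE the raw MAD.
#' @param zero_phase if TRUE filter with a zero-phase forward-backward
#'   pass; default is a causal forward pass mimicking online acquisition.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(highpass_cutoff_hz = 300,
                             filter_order = 2L,
                             threshold_multiplier = 7,
                             dead_time_ms = 2,
                             artifact_blank_ms = 2,
                             mad_normalize = TRUE,
                             zero_phase = FALSE) {
  stopifnot(highpass_cutoff_hz > 0, filter_order >= 1,
            threshold_multiplier > 0, dead_time_ms >= 0,
            artifact_blank_ms >= 0)
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 filter_order = as.integer(filter_order),
                 threshold_multiplier = threshold_multiplier,
                 dead_time_ms = dead_time_ms,
                 artifact_blank_ms = artifact_blank_ms,
                 mad_normalize = isTRUE(mad_normalize),
                 zero_phase = isTRUE(zero_phase)),
            class = "detection_params")
}

#' High-pass filter a raw recording
#'
#' Butterworth high-pass (order and cutoff from `params`), applied as a
#' causal forward pass by default (`zero_phase = TRUE` in the params
#' switches to `signal::filtfilt`).
#'
#' @param raw a `raw_recording`.
#' @param params a [detection_params()].
#' @return A filtered `raw_recording` of the same shape.
#' @export
highpass <- function(raw, params = detection_params()) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$sampling_rate / 2
  if (params$highpass_cutoff_hz >= nyq)
    stop("high-pass cutoff ", params$highpass_cutoff_hz,
         " Hz is at or above the Nyquist frequency ", nyq, " Hz")
  bf <- signal::butter(params$filter_order,
                       params$highpass_cutoff_hz / nyq, type = "high")
  out <- raw
  for (j in seq_len(ncol(raw$samples))) {
    # subtracting the first sample removes the onset step of any constant
    # offset, so the causal filter's startup transient cannot create
    # spurious super-threshold excursions; the filter is linear, so the
    # output is otherwise unchanged
    x <- raw$samples[, j] - raw$samples[1L, j]
    out$samples[, j] <- if (params$zero_phase)
      signal::filtfilt(bf, x) else as.numeric(signal::filter(bf, x))
  }
  out
}

#' MAD-based noise estimate of a filtered trace
#'
#' `sigma = median(|x - median(x)|) / 0.6745` (the Quiroga convention:
#' for Gaussian noise this is a consistent estimate of the SD, robust to
#' the spikes themselves). With `mad_normalize = FALSE` the raw MAD is
#' returned instead.
#'
#' @param x numeric vector, one channel of filtered samples.
#' @param params a [detection_params()].
#' @return noise sigma in the units of `x` (microvolts).
#' @export
estimate_noise <- function(x, params = detection_params()) {
  if (length(x) < 1000L)
    warning("noise estimated from only ", length(x), " samples")
  k <- if (params$mad_normalize) 1 / 0.6745 else 1
  sigma <- stats::mad(x, constant = k)
  if (sigma == 0)
    warning("all samples identical: noise sigma is 0 and the detection ",
            "threshold would be 0")
  sigma
}

# candidate peaks: strict local maxima; plateaus take their first sample.
# A sample i is a candidate iff the last non-zero slope before i is
# positive and the first non-zero slope at/after i is negative.
local_maxima <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(d[nz])
  chg <- which(s[-length(s)] == 1 & s[-1] == -1)
  nz[chg] + 1L
}

#' Detect spikes on a filtered recording
#'
#' A spike is a positive local-maximum sample whose value exceeds
#' `threshold_multiplier * sigma` for that channel. Scanning in time
#' order, any event closer than the dead time to the last accepted event
#' is discarded (the earliest of a run survives). If a stimulation
#' protocol is supplied, samples within `artifact_blank_ms` after each
#' pulse onset are excluded from the peak search. Event time is the time
#' of the peak sample.
#'
#' @param filtered a high-pass filtered `raw_recording`.
#' @param noise per-channel noise sigma: a numeric vector aligned with
#'   `filtered$channels`, or NULL to estimate it with [estimate_noise()].
#' @param params a [detection_params()].
#' @param protocol optional [stimulation_protocol()] for artifact
#'   blanking.
#' @return A `spike_events` object.
#' @export
detect_spikes <- function(filtered, noise = NULL,
                          params = detection_params(), protocol = NULL) {
  stopifnot(inherits(filtered, "raw_recording"))
  fs <- filtered$sampling_rate
  if (is.null(noise))
    noise <- apply(filtered$samples, 2L, estimate_noise, params = params)
  if (length(noise) != length(filtered$channels))
    stop("need one noise sigma per channel")
  dead_n <- params$dead_time_ms / 1000 * fs
  el <- integer(0); tm <- numeric(0)
  for (j in seq_along(filtered$channels)) {
    sigma <- noise[j]
    if (sigma == 0)
      stop("noise sigma is 0 on electrode ", filtered$channels[j],
           ": inspect the channel (flat or clipped trace?)")
    x <- filtered$samples[, j]
    cand <- local_maxima(x)
    cand <- cand[x[cand] > params$threshold_multiplier * sigma]
    if (!is.null(protocol) && length(cand)) {
      t_cand <- (cand - 1L) / fs
      blank <- params$artifact_blank_ms / 1000
      pulse <- findInterval(t_cand, protocol$pulse_times)
      in_blank <- pulse >= 1L &
        t_cand < protocol$pulse_times[pmax(pulse, 1L)] + blank
      cand <- cand[!in_blank]
    }
    if (length(cand) > 1L && dead_n > 0) {
      keep <- logical(length(cand))
      last <- -Inf
      for (i in seq_along(cand)) {
        if (cand[i] - last >= dead_n) {
          keep[i] <- TRUE
          last <- cand[i]
        }
      }
      cand <- cand[keep]
    }
    el <- c(el, rep(filtered$channels[j], length(cand)))
    tm <- c(tm, (cand - 1L) / fs)
  }
  spike_events(el, tm + filtered$t0, recording_duration(filtered) + filtered$t0)
}
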