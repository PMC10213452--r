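#' Stimulation protocol
#'
#' One set of biphasic voltage pulses applied to a single electrode. The
#' standard paradigm is a 400 microsecond +/-500 mV biphasic square pulse
#' repeated at 4 Hz for 2 min (480 repeats per set), with 30 s of idle
#' time between sets stimulating different electrodes.
#'
#' @param stimulated_electrode electrode id receiving the pulses.
#' @param pulse_times pulse onset times in seconds; defaults to
#'   `t_start + (0:(n_repeats-1))/frequency`.
#' @param frequency pulse rate in Hz.
#' @param n_repeats number of pulses in the set.
#' @param pulse_width_s pulse width in seconds.
#' @param amplitude_mV positive-phase amplitude in millivolts.
#' @param inter_set_idle_s idle time between sets, seconds.
#' @param t_start onset of the first pulse, seconds.
#' @return An object of class `stim_protocol`.
#' @export
stimulation_protocol <- function(stimulated_electrode,
                                 pulse_times = NULL,
                                 frequency = 4,
                                 n_repeats = 480L,
                                 pulse_width_s = 400e-6,
                                 amplitude_mV = 500,
                                 inter_set_idle_s = 30,
                                 t_start = 0) {
  if (is.null(pulse_times))
    pulse_times <- t_start + (seq_len(n_repeats) - 1) / frequency
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times) > 1L && any(diff(pulse_times) <= 0))
    stop("pulse_times must be strictly increasing")
  structure(list(stimulated_electrode = as.integer(stimulated_electrode),
                 pulse_times = pulse_times,
                 frequency = frequency,
                 n_repeats = length(pulse_times),
                 pulse_width_s = pulse_width_s,
                 amplitude_mV = amplitude_mV,
                 inter_set_idle_s = inter_set_idle_s),
            class = "stim_protocol")
}

#' Read / write a stimulation protocol as JSON
#' @param path JSON file path.
#' @return `read_protocol`: a `stim_protocol`; `write_protocol`: `path`.
#' @export
read_protocol <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulation_protocol(stimulated_electrode = m$stimulated_electrode,
                       pulse_times = m$pulse_times,
                       frequency = m$frequency,
                       pulse_width_s = m$pulse_width_s,
                       amplitude_mV = m$amplitude_mV,
                       inter_set_idle_s = m$inter_set_idle_s)
}

#' @rdname read_protocol
#' @param protocol a `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> electrode %d: %d pulses @ %g Hz, %.0f us, +/-%g mV\n",
              x$stimulated_electrode, x$n_repeats, x$frequency,
              x$pulse_width_s * 1e6, x$amplitude_mV))
  invisible(x)
}
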