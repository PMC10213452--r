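#' Raw multichannel recording
#'
#' A block of sampled extracellular voltage, one column per electrode.
#'
#' @param samples numeric matrix, `n_samples x n_channels`, in microvolts.
#' @param channels integer vector of electrode ids, one per column.
#' @param sampling_rate sampling rate in Hz (default 20000, the
#'   acquisition rate of the 60-electrode MEA system).
#' @param t0 recording start time in seconds (default 0).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, channels, sampling_rate = 20000, t0 = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(channels))
    stop("number of sample columns (", ncol(samples),
         ") != number of channels (", length(channels), ")")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(list(samples = samples, channels = as.integer(channels),
                 sampling_rate = as.numeric(sampling_rate), t0 = as.numeric(t0)),
            class = "raw_recording")
}

#' Duration of a raw recording in seconds
#' @param rec a `raw_recording`.
#' @return `n_samples / sampling_rate`.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$sampling_rate

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              ncol(x$samples), nrow(x$samples), x$sampling_rate,
              recording_duration(x)))
  invisible(x)
}

#' Write a raw recording (float32 payload + JSON sidecar)
#'
#' The payload is flat little-endian 32-bit float, channel-major (all of
#' channel 1, then all of channel 2, ...). The sidecar `<path>.json`
#' records `channels`, `sampling_rate_hz`, `n_samples`, `t0_s` and
#' `units`.
#'
#' @param rec a `raw_recording`.
#' @param path payload path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4L, endian = "little")
  meta <- list(channels = rec$channels,
               sampling_rate_hz = rec$sampling_rate,
               n_samples = nrow(rec$samples),
               t0_s = rec$t0, units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raw recording written by [write_raw_recording()]
#' @param path payload path (sidecar expected at `<path>.json`).
#' @return A `raw_recording`. Samples come back as float32-rounded values.
#' @export
read_raw_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_expect <- as.integer(meta$n_samples) * length(meta$channels)
  n_avail <- file.info(path)$size / 4
  if (n_avail != n_expect)
    stop("payload holds ", n_avail, " float32 values but sidecar implies ",
         n_expect, " (", length(meta$channels), " channel(s) x ",
         meta$n_samples, " samples)")
  con <- file(path, open = "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_expect, size = 4L,
               endian = "little")
  raw_recording(matrix(x, nrow = meta$n_samples,
                       ncol = length(meta$channels)),
                channels = meta$channels,
                sampling_rate = meta$sampling_rate_hz,
                t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}
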