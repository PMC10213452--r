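#' Spike events
#'
#' The lingua franca between all stages: a set of (electrode, time) spike
#' events over a recording of known duration. Times are seconds from the
#' start of the recording.
#'
#' @param electrode integer vector of electrode ids.
#' @param time numeric vector of spike times in seconds.
#' @param duration recording span in seconds.
#' @return An object of class `spike_events`: a data frame with columns
#'   `electrode` and `time`, sorted by time (ties broken by electrode),
#'   with attribute `duration`.
#' @export
spike_events <- function(electrode = integer(), time = numeric(), duration) {
  if (length(electrode) != length(time))
    stop("electrode and time must have equal length")
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
    stop("duration must be a single non-negative number")
  if (length(time) && (any(time < 0) || any(time > duration)))
    stop("spike times must lie in [0, duration]")
  ev <- data.frame(electrode = as.integer(electrode), time = as.numeric(time))
  ev <- ev[order(ev$time, ev$electrode), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "duration") <- as.numeric(duration)
  class(ev) <- c("spike_events", "data.frame")
  ev
}

#' Recording duration of a `spike_events` object
#' @param events a `spike_events` object.
#' @return duration in seconds.
#' @export
events_duration <- function(events) attr(events, "duration")

#' Read spike events from the package's columnar text format
#'
#' The format is tab-separated text with a header comment line
#' `# duration_s=<float>`, an optional column-name line
#' `electrode<TAB>time_s`, then one row per event. Decimal separator is
#' always `.`; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return A `spike_events` object.
#' @export
read_spike_events <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#\\s*duration_s=", lines[1]))
    stop("missing '# duration_s=' header on line 1 of ", path)
  duration <- suppressWarnings(as.numeric(sub("^#\\s*duration_s=", "", lines[1])))
  if (is.na(duration)) stop("non-numeric duration in header of ", path)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  body_idx <- body_idx[body_idx > 1L]
  # optional column-name line
  if (length(body_idx) && grepl("^electrode\\b", lines[body_idx[1]]))
    body_idx <- body_idx[-1L]
  if (!length(body_idx)) return(spike_events(duration = duration))
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("expected 2 tab-separated fields on line ", body_idx[bad[1]], " of ", path)
  el <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(el) | is.na(tm))
  if (length(bad))
    stop("non-numeric field on line ", body_idx[bad[1]], " of ", path)
  bad <- which(tm < 0 | tm > duration)
  if (length(bad))
    stop("event time outside [0, duration] on line ", body_idx[bad[1]], " of ", path)
  spike_events(el, tm, duration)
}

#' Write spike events to the columnar text format
#'
#' Output is deterministic: events are sorted by (time, electrode) and
#' times are printed with fixed 6-decimal formatting, so identical inputs
#' produce byte-identical files.
#'
#' @param events a `spike_events` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(events, path) {
  stopifnot(inherits(events, "spike_events"))
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  hdr <- c(sprintf("# duration_s=%.6f", events_duration(events)),
           "electrode\ttime_s")
  rows <- if (nrow(events))
    sprintf("%d\t%.6f", events$electrode, events$time) else character()
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events on %d electrode(s), duration %g s\n",
              nrow(x), length(unique(x$electrode)), events_duration(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# restrict events to a set of electrodes, keeping the duration attribute
subset_events <- function(events, electrodes) {
  keep <- events$electrode %in% electrodes
  spike_events(events$electrode[keep], events$time[keep], events_duration(events))
}
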