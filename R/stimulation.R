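#' Build a stacked peri-stimulus raster
#'
#' Every spike on the circuit's four electrodes falling strictly after a
#' pulse onset and within the response window is assigned to that pulse
#' with latency `t - pulse_time`; the latency interval is open at 0 and
#' closed at the window (a spike exactly at the pulse sample is
#' indistinguishable from the artifact). At 4 Hz the 250 ms window tiles
#' the inter-pulse interval, so a spike belongs to at most one repeat;
#' windows longer than the inter-pulse interval are rejected.
#'
#' @param events a `spike_events` object (detected with artifact blanking
#'   consistent with the protocol).
#' @param layout a `circuit_layout`.
#' @param protocol a [stimulation_protocol()]; the raster covers the
#'   circuit of its stimulated electrode.
#' @param window_ms response window, ms (default 250).
#' @return An object of class `stacked_raster`: list with
#'   `stimulated_electrode`, `circuit`, `n_repeats`, `window_ms` and
#'   `entries` (data frame: `repeat_idx`, `electrode`, `latency_ms`).
#' @export
build_raster <- function(events, layout, protocol, window_ms = 250) {
  stopifnot(inherits(events, "spike_events"),
            inherits(protocol, "stim_protocol"), window_ms > 0)
  pt <- protocol$pulse_times
  if (length(pt) > 1L && window_ms / 1000 > min(diff(pt)) + 1e-12)
    stop("response window (", window_ms, " ms) exceeds the inter-pulse ",
         "interval: spikes would be double-assigned")
  circ <- circuit_of(layout, protocol$stimulated_electrode)
  if (is.na(circ))
    stop("stimulated electrode is not part of any circuit")
  elecs <- circuit_electrodes(layout, circ)
  keep <- events$electrode %in% elecs
  el <- events$electrode[keep]; tm <- events$time[keep]
  # assign to the latest pulse strictly before the spike: a spike exactly
  # at a pulse onset belongs to the previous window (latency 250 ms, the
  # closed end), not to the new pulse at latency 0 (the open end)
  pulse <- findInterval(tm, pt)
  on_pulse <- pulse >= 1L & tm == pt[pmax(pulse, 1L)]
  pulse[on_pulse] <- pulse[on_pulse] - 1L
  lat_ms <- (tm - pt[pmax(pulse, 1L)]) * 1000
  ok <- pulse >= 1L & lat_ms > 0 & lat_ms <= window_ms
  entries <- data.frame(repeat_idx = pulse[ok], electrode = el[ok],
                        latency_ms = lat_ms[ok])
  entries <- entries[order(entries$repeat_idx, entries$latency_ms,
                           entries$electrode), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(stimulated_electrode = protocol$stimulated_electrode,
                 circuit = circ, n_repeats = length(pt),
                 window_ms = window_ms, entries = entries),
            class = "stacked_raster")
}

#' @export
print.stacked_raster <- function(x, ...) {
  cat(sprintf("<stacked_raster> electrode %d (circuit %d): %d spikes over %d repeats\n",
              x$stimulated_electrode, x$circuit, nrow(x$entries), x$n_repeats))
  invisible(x)
}

#' Plot a stacked raster (repeats stacked vertically)
#'
#' Spikes occurring with a consistent post-stimulus delay line up as
#' vertical bands.
#' @param x a `stacked_raster`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stacked_raster <- function(x, ...) {
  graphics::plot(x$entries$latency_ms, x$entries$repeat_idx, pch = ".",
                 cex = 2, xlim = c(0, x$window_ms), ylim = c(1, x$n_repeats),
                 xlab = "latency after stimulus (ms)", ylab = "repeat",
                 main = sprintf("stimulated electrode %d",
                                x$stimulated_electrode), ...)
  invisible(x)
}

#' Classify a stimulated electrode as activity-inducing
#'
#' An electrode is activity-inducing if the set of stimuli evoked at
#' least `n_repeats` spikes summed over all four circuit electrodes,
#' i.e. at least one spike per stimulus on average. The boundary is an
#' exact integer comparison.
#'
#' @param raster a [build_raster()] result.
#' @param n_repeats number of pulses in the set (default from the
#'   raster).
#' @return one-row data frame: `stimulated_electrode`, `circuit`,
#'   `total_spikes`, `activity_inducing`, `mean_induced_per_stimulus`.
#' @export
classify_activity_inducing <- function(raster, n_repeats = raster$n_repeats) {
  stopifnot(inherits(raster, "stacked_raster"))
  total <- nrow(raster$entries)
  data.frame(stimulated_electrode = raster$stimulated_electrode,
             circuit = raster$circuit,
             total_spikes = total,
             activity_inducing = total >= n_repeats,
             mean_induced_per_stimulus = total / n_repeats)
}

#' Group summary of stimulation responses
#'
#' Percent of activity-inducing electrodes over the included electrodes,
#' and the mean (with SEM, electrodes treated as independent) number of
#' induced spikes per stimulus over the activity-inducing electrodes
#' only.
#'
#' @param rows rows from [classify_activity_inducing()] (stacked), with
#'   an optional `group` column and optional logical `include` column.
#' @return data frame per group: `n_electrodes`, `n_inducing`,
#'   `pct_inducing`, `mean_induced` (NA when no inducing electrode),
#'   `sem_induced`.
#' @export
group_stimulation_summary <- function(rows) {
  if (!nrow(rows)) stop("empty summary table")
  if (is.null(rows$group)) rows$group <- "all"
  if (!is.null(rows$include)) rows <- rows[rows$include, , drop = FALSE]
  if (!nrow(rows)) {
    warning("no included electrodes; empty summary")
    return(data.frame(group = character(), n_electrodes = integer(),
                      n_inducing = integer(), pct_inducing = numeric(),
                      mean_induced = numeric(), sem_induced = numeric()))
  }
  out <- lapply(split(rows, rows$group), function(g) {
    ind <- g$activity_inducing
    data.frame(group = g$group[1], n_electrodes = nrow(g),
               n_inducing = sum(ind),
               pct_inducing = 100 * mean(ind),
               mean_induced = if (any(ind))
                 mean(g$mean_induced_per_stimulus[ind]) else NA_real_,
               sem_induced = if (sum(ind) >= 2)
                 sem(g$mean_induced_per_stimulus[ind]) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
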