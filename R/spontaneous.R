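#' Mean firing rate of an electrode
#'
#' Spike count divided by recording time, in Hz.
#'
#' @param events a `spike_events` object.
#' @param electrode electrode id; if NULL, a named vector over all
#'   electrodes present in `events`.
#' @return firing rate(s) in Hz.
#' @export
mean_firing_rate <- function(events, electrode = NULL) {
  dur <- events_duration(events)
  if (is.null(dur) || dur <= 0) stop("recording duration must be > 0")
  if (is.null(electrode)) {
    tab <- table(events$electrode)
    return(stats::setNames(as.numeric(tab) / dur, names(tab)))
  }
  sum(events$electrode == electrode) / dur
}

#' Classify an electrode as active
#'
#' An electrode is active if its mean firing rate is strictly above the
#' threshold (default 0.1 Hz); an electrode at exactly 0.1 Hz is not
#' active.
#'
#' @param mfr firing rate(s), Hz.
#' @param threshold activity threshold, Hz.
#' @return logical vector.
#' @export
classify_active <- function(mfr, threshold = 0.1) {
  stopifnot(all(mfr >= 0))
  mfr > threshold
}

#' Per-electrode firing-rate table for one session
#'
#' @param events a `spike_events` object.
#' @param electrodes electrode ids to tabulate (silent electrodes get
#'   rate 0); default: electrodes present in `events`.
#' @param threshold active-electrode threshold, Hz.
#' @return data frame with columns `electrode`, `n_spikes`, `mfr`,
#'   `active`.
#' @export
firing_rate_table <- function(events, electrodes = NULL, threshold = 0.1) {
  dur <- events_duration(events)
  if (dur <= 0) stop("recording duration must be > 0")
  if (is.null(electrodes)) electrodes <- sort(unique(events$electrode))
  n <- vapply(electrodes, function(e) sum(events$electrode == e), integer(1))
  mfr <- n / dur
  data.frame(electrode = as.integer(electrodes), n_spikes = n, mfr = mfr,
             active = classify_active(mfr, threshold))
}

sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Aggregate firing-rate tables per condition and day in vitro
#'
#' Percent active electrodes is computed over all *included* electrodes
#' of a group; mean MFR and its SEM are computed over the active
#' electrodes only (absent, not zero, when a group has no active
#' electrode — including silent electrodes would bias condition curves).
#'
#' @param rates data frame with at least columns `condition`, `div`,
#'   `electrode`, `mfr` (one row per electrode and session), and
#'   optionally a logical `include` column (e.g. electrodes of
#'   independent circuits only; defaults to all TRUE).
#' @param threshold active-electrode threshold, Hz.
#' @return data frame per (condition, div): `n_electrodes`, `n_active`,
#'   `pct_active`, `mean_mfr_active` (NA when no active electrode),
#'   `sem_mfr_active` (NA when fewer than 2 active electrodes).
#' @export
aggregate_condition <- function(rates, threshold = 0.1) {
  stopifnot(all(c("condition", "div", "electrode", "mfr") %in% names(rates)))
  if (is.null(rates$include)) rates$include <- TRUE
  rates <- rates[rates$include, , drop = FALSE]
  if (!nrow(rates)) {
    warning("no included electrodes; empty summary")
    return(data.frame(condition = character(), div = integer(),
                      n_electrodes = integer(), n_active = integer(),
                      pct_active = numeric(), mean_mfr_active = numeric(),
                      sem_mfr_active = numeric()))
  }
  groups <- split(rates, list(rates$condition, rates$div), drop = TRUE)
  out <- lapply(groups, function(g) {
    act <- classify_active(g$mfr, threshold)
    data.frame(condition = g$condition[1], div = g$div[1],
               n_electrodes = nrow(g), n_active = sum(act),
               pct_active = 100 * mean(act),
               mean_mfr_active = if (any(act)) mean(g$mfr[act]) else NA_real_,
               sem_mfr_active = if (sum(act) >= 2) sem(g$mfr[act]) else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$condition, res$div), , drop = FALSE]
  rownames(res) <- NULL
  res
}
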