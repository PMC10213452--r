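#' Simulation configuration
#'
#' Parameters of the synthetic-recording generator. The generator
#' emulates the statistical structure the analysis assumes: homogeneous
#' Poisson background firing per electrode, clockwise-biased spike
#' propagation between adjacent ring electrodes with sub-5 ms latency,
#' stimulus-locked evoked "bands" with consistent latency, extra late
#' post-stimulus activity, magnesium-dependent suppression of all rates,
#' and raw-trace rendering (biphasic waveform plus Gaussian noise).
#'
#' @param seed integer seed; every operation derives its own stream from
#'   `(seed, operation tag)`.
#' @param background_rate spontaneous Poisson rate per electrode, Hz.
#' @param p_forward probability that a spike at ring position k elicits a
#'   spike at position k+1 (clockwise neighbour).
#' @param p_backward same for the counter-clockwise neighbour.
#' @param latency_range_ms uniform support of the propagation latency in
#'   ms; kept inside (0, 5) so propagated pairs fall within the 5 ms
#'   pairing window of the directionality analysis.
#' @param evoked_bands data frame with columns `latency_ms`, `jitter_ms`,
#'   `prob`: each row is a stimulus-locked response band (mean latency,
#'   Gaussian jitter SD, per-pulse response probability).
#' @param late_response_rate Poisson rate (Hz) of extra evoked activity in
#'   the (15, 250] ms post-stimulus window.
#' @param mg_tau decay constant tau (mM) of magnesium suppression: rates
#'   are scaled by `exp(-concentration / tau)`.
#' @param mg_exempt_early if TRUE, evoked bands with latency <= 15 ms are
#'   exempt from magnesium suppression (early, possibly direct responses
#'   persist at high Mg2+).
#' @param waveform_amp_uV positive-peak amplitude of the rendered spike
#'   waveform, microvolts (must be > 0: the detector looks for positive
#'   peaks).
#' @param waveform_width_ms total width of the biphasic waveform, ms.
#' @param noise_sd_uV SD of the additive Gaussian trace noise, microvolts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       background_rate = 2,
                       p_forward = 0.3,
                       p_backward = 0.1,
                       latency_range_ms = c(0.5, 4.5),
                       evoked_bands = data.frame(latency_ms = c(5, 30),
                                                 jitter_ms = c(0.3, 3),
                                                 prob = c(0.9, 0.5)),
                       late_response_rate = 10,
                       mg_tau = 3,
                       mg_exempt_early = FALSE,
                       waveform_amp_uV = 60,
                       waveform_width_ms = 1,
                       noise_sd_uV = 6) {
  stopifnot(background_rate >= 0, late_response_rate >= 0,
            p_forward >= 0, p_forward <= 1,
            p_backward >= 0, p_backward <= 1,
            length(latency_range_ms) == 2L,
            waveform_amp_uV > 0, noise_sd_uV >= 0)
  if (latency_range_ms[1] <= 0 || latency_range_ms[2] >= 5 ||
      latency_range_ms[1] > latency_range_ms[2])
    stop("latency_range_ms must lie within (0, 5) ms")
  if (!all(c("latency_ms", "jitter_ms", "prob") %in% names(evoked_bands)))
    stop("evoked_bands needs columns latency_ms, jitter_ms, prob")
  if (any(evoked_bands$prob < 0 | evoked_bands$prob > 1))
    stop("band probabilities must be in [0, 1]")
  structure(list(seed = as.integer(seed),
                 background_rate = background_rate,
                 p_forward = p_forward, p_backward = p_backward,
                 latency_range_ms = as.numeric(latency_range_ms),
                 evoked_bands = evoked_bands,
                 late_response_rate = late_response_rate,
                 mg_tau = mg_tau, mg_exempt_early = isTRUE(mg_exempt_early),
                 waveform_amp_uV = waveform_amp_uV,
                 waveform_width_ms = waveform_width_ms,
                 noise_sd_uV = noise_sd_uV),
            class = "sim_config")
}

# electrode lookup table: circuit/position -> electrode id
elmap <- function(layout) {
  stats::setNames(layout$electrode,
                  paste(layout$circuit, layout$position, sep = "/"))
}

#' Simulate spontaneous activity with ground truth
#'
#' Background spikes are homogeneous Poisson per electrode. Every spike
#' (background or propagated) independently triggers one spike on its
#' clockwise neighbour with probability `p_forward` and on its
#' counter-clockwise neighbour with probability `p_backward`, after a
#' latency drawn uniformly from `latency_range_ms`; propagated spikes may
#' themselves propagate (a branching cascade). Children falling past the
#' end of the recording are dropped and not counted.
#'
#' @param config a [sim_config()].
#' @param layout a `circuit_layout`.
#' @param duration recording length, seconds.
#' @return A `ground_truth` list: `spikes` (a `spike_events`),
#'   `parentage` (data frame aligned with `spikes`: `source` one of
#'   "background"/"propagated", `parent_electrode`, `parent_time`,
#'   `direction` "cw"/"ccw"), `n_forward`, `n_backward`, and
#'   `true_clockwise_fraction = n_forward / (n_forward + n_backward)`.
#' @export
simulate_spontaneous <- function(config, layout, duration) {
  stopifnot(inherits(config, "sim_config"), duration > 0)
  mu <- config$p_forward + config$p_backward
  if (mu >= 1.5)
    stop("expected offspring per spike is ", mu,
         " >= 1.5: supercritical cascade would not terminate")
  if (mu >= 1)
    warning("expected offspring per spike is ", mu,
            " >= 1: cascade is (super)critical, sizes may be very large")
  em <- elmap(layout)
  with_op_seed(config$seed, "spontaneous", {
    counts <- stats::rpois(nrow(layout), config$background_rate * duration)
    el <- rep(layout$electrode, counts)
    tm <- stats::runif(length(el), 0, duration)
    all_el <- el
    all_tm <- tm
    all_src <- rep("background", length(el))
    all_pel <- rep(NA_integer_, length(el))
    all_ptm <- rep(NA_real_, length(el))
    all_dir <- rep(NA_character_, length(el))
    n_fw <- 0L
    n_bw <- 0L
    cur_el <- el
    cur_tm <- tm
    lo <- config$latency_range_ms[1] / 1000
    hi <- config$latency_range_ms[2] / 1000
    while (length(cur_el)) {
      pos <- position_of(layout, cur_el)
      circ <- circuit_of(layout, cur_el)
      nxt_el <- integer(0); nxt_tm <- numeric(0)
      for (dir in c("cw", "ccw")) {
        p <- if (dir == "cw") config$p_forward else config$p_backward
        fire <- !is.na(circ) & stats::runif(length(cur_el)) < p
        if (!any(fire)) next
        child_pos <- if (dir == "cw") cw_position(pos[fire]) else ccw_position(pos[fire])
        child_el <- unname(em[paste(circ[fire], child_pos, sep = "/")])
        child_tm <- cur_tm[fire] + stats::runif(sum(fire), lo, hi)
        keep <- child_tm <= duration
        if (!any(keep)) next
        child_el <- child_el[keep]; child_tm <- child_tm[keep]
        if (dir == "cw") n_fw <- n_fw + length(child_el)
        else n_bw <- n_bw + length(child_el)
        all_el <- c(all_el, child_el)
        all_tm <- c(all_tm, child_tm)
        all_src <- c(all_src, rep("propagated", length(child_el)))
        all_pel <- c(all_pel, cur_el[fire][keep])
        all_ptm <- c(all_ptm, cur_tm[fire][keep])
        all_dir <- c(all_dir, rep(dir, length(child_el)))
        nxt_el <- c(nxt_el, child_el)
        nxt_tm <- c(nxt_tm, child_tm)
      }
      cur_el <- nxt_el
      cur_tm <- nxt_tm
    }
    ord <- order(all_tm, all_el)
    truth <- list(spikes = spike_events(all_el[ord], all_tm[ord], duration),
                  parentage = data.frame(source = all_src[ord],
                                         parent_electrode = all_pel[ord],
                                         parent_time = all_ptm[ord],
                                         direction = all_dir[ord]),
                  n_forward = n_fw, n_backward = n_bw,
                  true_clockwise_fraction =
                    if (n_fw + n_bw > 0) n_fw / (n_fw + n_bw) else NA_real_)
    class(truth) <- "ground_truth"
    truth
  })
}

#' Simulate stimulation-evoked activity with ground truth
#'
#' For each pulse of the protocol and each evoked band, with the band's
#' per-pulse probability one spike is emitted on each of the four
#' electrodes of the stimulated electrode's circuit, at pulse time +
#' band latency + Gaussian jitter (per spike). Additional "late" spikes
#' are Poisson at `late_response_rate` per electrode within the
#' (15, 250] ms post-pulse window.
#'
#' @param config a [sim_config()].
#' @param layout a `circuit_layout`.
#' @param protocol a [stimulation_protocol()].
#' @return A `ground_truth` list; `parentage$source` is "evoked" or
#'   "late" with `pulse` and `band` indices.
#' @export
simulate_stimulation <- function(config, layout, protocol) {
  stopifnot(inherits(config, "sim_config"), inherits(protocol, "stim_protocol"))
  bands <- config$evoked_bands
  if (nrow(bands) && any(bands$latency_ms > 250))
    stop("evoked band latency beyond the 250 ms response window")
  circ <- circuit_of(layout, protocol$stimulated_electrode)
  if (is.na(circ))
    stop("stimulated electrode ", protocol$stimulated_electrode,
         " is not part of any circuit")
  elecs <- circuit_electrodes(layout, circ)
  pt <- protocol$pulse_times
  duration <- max(pt) + 0.25
  with_op_seed(config$seed, "stimulation", {
    el <- integer(0); tm <- numeric(0)
    src <- character(0); pulse <- integer(0); band <- integer(0)
    if (nrow(bands)) for (b in seq_len(nrow(bands))) {
      fired <- which(stats::runif(length(pt)) < bands$prob[b])
      if (!length(fired)) next
      for (e in elecs) {
        lat <- bands$latency_ms[b] +
          stats::rnorm(length(fired), 0, bands$jitter_ms[b])
        lat <- pmin(pmax(lat, 0.05), 250)  # clamp inside the response window
        el <- c(el, rep(e, length(fired)))
        tm <- c(tm, pt[fired] + lat / 1000)
        src <- c(src, rep("evoked", length(fired)))
        pulse <- c(pulse, fired)
        band <- c(band, rep(b, length(fired)))
      }
    }
    if (config$late_response_rate > 0) {
      win <- 0.235  # (15, 250] ms
      for (e in elecs) {
        n_late <- stats::rpois(length(pt), config$late_response_rate * win)
        if (!sum(n_late)) next
        p_idx <- rep(seq_along(pt), n_late)
        t_late <- pt[p_idx] + stats::runif(sum(n_late), 0.015, 0.250)
        el <- c(el, rep(e, sum(n_late)))
        tm <- c(tm, t_late)
        src <- c(src, rep("late", sum(n_late)))
        pulse <- c(pulse, p_idx)
        band <- c(band, rep(NA_integer_, sum(n_late)))
      }
    }
    tm <- pmin(tm, duration)
    ord <- order(tm, el)
    truth <- list(spikes = spike_events(el[ord], tm[ord], duration),
                  parentage = data.frame(source = src[ord],
                                         pulse = pulse[ord],
                                         band = band[ord]),
                  n_forward = 0L, n_backward = 0L,
                  true_clockwise_fraction = NA_real_)
    class(truth) <- "ground_truth"
    truth
  })
}

#' Scale simulator rates for an extracellular Mg2+ concentration
#'
#' Returns a copy of `config` with `background_rate`,
#' `late_response_rate` and all evoked-band probabilities multiplied by
#' `exp(-concentration / mg_tau)`. With `mg_exempt_early = TRUE`, bands
#' with latency <= 15 ms keep their probability, mimicking early direct
#' responses that persist at high magnesium.
#'
#' @param config a [sim_config()].
#' @param concentration Mg2+ concentration, mM (>= 0).
#' @return A modified `sim_config`.
#' @export
apply_mg_suppression <- function(config, concentration) {
  stopifnot(inherits(config, "sim_config"))
  if (concentration < 0) stop("concentration must be >= 0")
  if (config$mg_tau <= 0) stop("mg_tau must be > 0")
  f <- exp(-concentration / config$mg_tau)
  config$background_rate <- config$background_rate * f
  config$late_response_rate <- config$late_response_rate * f
  if (nrow(config$evoked_bands)) {
    scale <- rep(f, nrow(config$evoked_bands))
    if (config$mg_exempt_early)
      scale[config$evoked_bands$latency_ms <= 15] <- 1
    config$evoked_bands$prob <- config$evoked_bands$prob * scale
  }
  config
}

# biphasic spike waveform template; positive peak exactly at index `peak`
make_waveform <- function(amp_uV, width_ms, sampling_rate) {
  n <- max(5L, round(width_ms / 1000 * sampling_rate))
  t <- seq_len(n) / n  # (0, 1]
  # sharp positive lobe + deeper repolarisation lobe: near-zero net area,
  # so a 300 Hz high-pass passes the peak largely unattenuated
  w <- exp(-((t - 0.3) / 0.05)^2) - 0.8 * exp(-((t - 0.65) / 0.1)^2)
  w <- w / max(w) * amp_uV
  list(template = w, peak = which.max(w))
}

#' Render ground-truth spikes into a raw voltage recording
#'
#' Each spike stamps the biphasic waveform template onto its channel with
#' the positive peak at the spike's sample, plus additive white Gaussian
#' noise. Templates overhanging the recording edges are truncated.
#'
#' @param truth a `ground_truth` or a `spike_events` object.
#' @param config a [sim_config()] (waveform and noise parameters used).
#' @param channels electrode ids to render (default: all electrodes
#'   appearing in the events; pass a layout's electrodes to render silent
#'   channels too).
#' @param duration recording length, seconds (default: event duration).
#' @param sampling_rate Hz, default 20000.
#' @return A `raw_recording`.
#' @export
render_raw <- function(truth, config, channels = NULL, duration = NULL,
                       sampling_rate = 20000) {
  events <- if (inherits(truth, "ground_truth")) truth$spikes else truth
  stopifnot(inherits(events, "spike_events"), inherits(config, "sim_config"))
  if (is.null(duration)) duration <- events_duration(events)
  if (is.null(channels)) channels <- sort(unique(events$electrode))
  n <- round(duration * sampling_rate)
  wf <- make_waveform(config$waveform_amp_uV, config$waveform_width_ms,
                      sampling_rate)
  tpl <- wf$template; pk <- wf$peak; ntpl <- length(tpl)
  samples <- matrix(0, nrow = n, ncol = length(channels))
  # one noise stream per channel id, so rendering a channel subset
  # reproduces the corresponding columns of a whole-array render
  for (j in seq_along(channels)) {
    x <- with_op_seed(config$seed, paste0("render/ch", channels[j]), {
      if (config$noise_sd_uV > 0)
        stats::rnorm(n, 0, config$noise_sd_uV) else numeric(n)
    })
    tms <- events$time[events$electrode == channels[j]]
    if (length(tms)) {
      centers <- round(tms * sampling_rate) + 1L
      for (c0 in centers) {
        i0 <- c0 - pk + 1L
        idx <- i0:(i0 + ntpl - 1L)
        ok <- idx >= 1L & idx <= n
        if (any(ok)) x[idx[ok]] <- x[idx[ok]] + tpl[seq_len(ntpl)[ok]]
      }
    }
    samples[, j] <- x
  }
  raw_recording(samples, channels, sampling_rate)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d spikes (%s)\n", nrow(x$spikes),
              paste(sprintf("%s: %d", names(table(x$parentage$source)),
                            as.integer(table(x$parentage$source))),
                    collapse = ", ")))
  if (!is.na(x$true_clockwise_fraction))
    cat(sprintf("  true clockwise fraction %.3f (%d forward / %d backward)\n",
                x$true_clockwise_fraction, x$n_forward, x$n_backward))
  invisible(x)
}
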