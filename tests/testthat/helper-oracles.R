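# Independent brute-force oracles and small fixtures used across tests.

ring4 <- function() circuit_layout(1:4, rep(1L, 4L), 1:4)

# nearest-match rate of times in `a` against reference times `b` (per
# electrode handled by the caller); tol in seconds
match_fraction <- function(a, b, tol) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  b <- sort(b)
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(b))
  d <- pmin(abs(a - b[lo]), abs(a - b[hi]))
  mean(d <= tol)
}

# recall/precision of detected vs true spike events, matched per electrode
detection_scores <- function(detected, truth, tol = 0.25e-3) {
  els <- union(unique(truth$electrode), unique(detected$electrode))
  n_true <- n_det <- hit_true <- hit_det <- 0
  for (e in els) {
    tt <- truth$time[truth$electrode == e]
    dt <- detected$time[detected$electrode == e]
    n_true <- n_true + length(tt)
    n_det <- n_det + length(dt)
    if (length(tt)) hit_true <- hit_true +
        length(tt) * match_fraction(tt, dt, tol)
    if (length(dt)) hit_det <- hit_det +
        length(dt) * match_fraction(dt, tt, tol)
  }
  list(recall = hit_true / n_true, precision = hit_det / n_det)
}

# brute-force consecutive-pair extraction: explicit loop over the merged
# stream, direction classified via a hand-written 4x4 lookup table
oracle_pairs <- function(el, tm, pos_of, window_ms) {
  lut <- matrix("diagonal", 4, 4)
  diag(lut) <- "same_electrode"
  for (k in 1:4) {
    lut[k, k %% 4 + 1] <- "clockwise"
    lut[k %% 4 + 1, k] <- "counterclockwise"
  }
  pos <- pos_of[as.character(el)]
  ord <- order(tm, pos)
  el <- el[ord]; tm <- tm[ord]; pos <- pos[ord]
  out <- NULL
  if (length(el) >= 2) for (i in 1:(length(el) - 1)) {
    d <- (tm[i + 1] - tm[i]) * 1000
    if (d < window_ms)
      out <- rbind(out, data.frame(pre = el[i], post = el[i + 1],
                                   delta_ms = d,
                                   class = lut[pos[i], pos[i + 1]],
                                   ambiguous = d == 0 && el[i] != el[i + 1]))
  }
  out
}

# brute-force peak detection: sample-by-sample scan applying the
# threshold / local-max (plateau-first) / dead-time rules literally
oracle_detect <- function(x, sigma, mult = 7, dead_ms = 2, fs = 20000) {
  thr <- mult * sigma
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] <= thr) next
    if (x[i] <= x[i - 1]) next
    j <- i + 1
    while (j <= n && x[j] == x[i]) j <- j + 1
    if (j <= n && x[j] < x[i]) cand <- c(cand, i)
  }
  dead_n <- dead_ms / 1000 * fs
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= dead_n) { keep <- c(keep, i); last <- i }
  }
  (keep - 1) / fs
}

# brute-force raster assignment: double loop over spikes x pulses
oracle_raster <- function(el, tm, elecs, pulse_times, window_ms) {
  out <- NULL
  for (i in seq_along(tm)) {
    if (!(el[i] %in% elecs)) next
    for (r in seq_along(pulse_times)) {
      lat <- (tm[i] - pulse_times[r]) * 1000
      if (lat > 0 && lat <= window_ms)
        out <- rbind(out, data.frame(repeat_idx = r, electrode = el[i],
                                     latency_ms = lat))
    }
  }
  out
}
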