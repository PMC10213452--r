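#' Classify a spike pair by ring positions
#'
#' On the clockwise-numbered ring 1 -> 2 -> 3 -> 4 -> 1: transitions
#' (1,2), (2,3), (3,4), (4,1) are clockwise; their reverses are
#' counter-clockwise; equal positions are `same_electrode`; (1,3) and
#' (2,4) in either order are `diagonal`. Only clockwise and
#' counter-clockwise pairs carry directional information.
#'
#' @param pre_pos,post_pos positions in 1..4 (vectorised).
#' @return character vector: "clockwise", "counterclockwise",
#'   "same_electrode" or "diagonal".
#' @export
classify_pair <- function(pre_pos, post_pos) {
  stopifnot(all(pre_pos %in% 1:4), all(post_pos %in% 1:4),
            length(pre_pos) == length(post_pos))
  out <- rep("diagonal", length(pre_pos))
  out[pre_pos == post_pos] <- "same_electrode"
  out[post_pos == cw_position(pre_pos)] <- "clockwise"
  out[post_pos == ccw_position(pre_pos)] <- "counterclockwise"
  out
}

#' Extract consecutive spike pairs of one circuit
#'
#' The spikes of the circuit's active electrodes are merged into one
#' time-sorted stream; every pair of *consecutive* spikes in that stream
#' separated by strictly less than the pairing window yields one pair
#' record (pairs overlap: a spike can be the post of one pair and the pre
#' of the next). Inactive electrodes are removed before merging. Two
#' spikes with identical timestamps on different electrodes are ordered
#' by ascending ring position and flagged `ambiguous`; direction is
#' undefined for them and downstream summaries exclude them from the
#' clockwise/counter-clockwise counts.
#'
#' @param events a `spike_events` object (any electrodes; filtered to the
#'   circuit internally).
#' @param layout a `circuit_layout`.
#' @param circuit circuit id.
#' @param window_ms pairing window, ms; pairs require `delta < window`
#'   (strict). Default 5 ms, an upper bound on the synaptic latency
#'   between two neurons of a circuit.
#' @param active_electrodes electrodes to keep; NULL (default) keeps
#'   electrodes with MFR strictly above `active_threshold`.
#' @param active_threshold Hz, used only when `active_electrodes` is NULL.
#' @return data frame with columns `circuit`, `pre_electrode`,
#'   `post_electrode`, `pre_pos`, `post_pos`, `pre_time`, `delta_ms`,
#'   `class`, `ambiguous`.
#' @export
extract_pairs <- function(events, layout, circuit, window_ms = 5,
                          active_electrodes = NULL, active_threshold = 0.1) {
  stopifnot(window_ms > 0)
  elecs <- circuit_electrodes(layout, circuit)
  if (is.null(active_electrodes)) {
    mfr <- vapply(elecs, function(e) mean_firing_rate(events, e), numeric(1))
    active_electrodes <- elecs[classify_active(mfr, active_threshold)]
  }
  keep <- events$electrode %in% intersect(elecs, active_electrodes)
  el <- events$electrode[keep]
  tm <- events$time[keep]
  pos <- position_of(layout, el)
  ord <- order(tm, pos)  # ties: ascending ring position
  el <- el[ord]; tm <- tm[ord]; pos <- pos[ord]
  empty <- data.frame(circuit = integer(), pre_electrode = integer(),
                      post_electrode = integer(), pre_pos = integer(),
                      post_pos = integer(), pre_time = numeric(),
                      delta_ms = numeric(), class = character(),
                      ambiguous = logical())
  if (length(el) < 2L) return(empty)
  d_ms <- diff(tm) * 1000
  i <- which(d_ms < window_ms)
  if (!length(i)) return(empty)
  data.frame(circuit = circuit,
             pre_electrode = el[i], post_electrode = el[i + 1L],
             pre_pos = pos[i], post_pos = pos[i + 1L],
             pre_time = tm[i], delta_ms = d_ms[i],
             class = classify_pair(pos[i], pos[i + 1L]),
             ambiguous = d_ms[i] == 0 & el[i] != el[i + 1L])
}

#' 4x4 pre/post frequency map of spike pairs
#'
#' Counts of consecutive-pair occurrences indexed by (pre position, post
#' position), plus percentages normalised per pre-electrode: for each pre
#' position the percentages over its four post positions sum to 100 (in
#' the standard figure orientation, pre positions are columns, so each
#' column of the transposed percent matrix sums to 100%).
#'
#' @param pairs a pair table from [extract_pairs()].
#' @return An object of class `frequency_map`: list with `counts` and
#'   `percent`, both 4x4 matrices `[pre, post]`.
#' @export
frequency_map <- function(pairs) {
  counts <- matrix(0L, 4L, 4L,
                   dimnames = list(pre = 1:4, post = 1:4))
  if (nrow(pairs)) {
    tab <- table(factor(pairs$pre_pos, levels = 1:4),
                 factor(pairs$post_pos, levels = 1:4))
    counts[] <- as.integer(tab)
  }
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs > 0, rs, NA) * 100
  structure(list(counts = counts, percent = percent),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("<frequency_map> counts [pre x post]:\n")
  print(x$counts)
  invisible(x)
}

#' Per-circuit and group clockwise summary
#'
#' For each circuit, the percentage of clockwise pairs is computed out of
#' the clockwise and counter-clockwise pairs only (ambiguous pairs
#' excluded); same-electrode and diagonal pairs carry no direction and
#' enter the non-directional fraction. Group means are *unweighted* means
#' of per-circuit percentages (every circuit counts equally regardless of
#' its pair count); circuits with no directional pairs are excluded from
#' the mean and tallied.
#'
#' @param pairs pair table from [extract_pairs()] (rows from several
#'   circuits may be concatenated), with an optional `group` column.
#' @param include circuits to include (e.g. independent, closed
#'   circuits); NULL includes all circuits present.
#' @return list with `per_circuit` (circuit, n_cw, n_ccw, n_same, n_diag,
#'   n_ambiguous, pct_clockwise, pct_nondirectional) and `summary`
#'   (group, mean_pct_clockwise, sem, n_circuits, n_excluded,
#'   pct_nondirectional_pooled).
#' @export
clockwise_summary <- function(pairs, include = NULL) {
  if (!nrow(pairs)) stop("empty pair table")
  if (is.null(pairs$group)) pairs$group <- "all"
  if (!is.null(include)) pairs <- pairs[pairs$circuit %in% include, , drop = FALSE]
  per <- lapply(split(pairs, list(pairs$group, pairs$circuit), drop = TRUE),
                function(p) {
    dir_ok <- !p$ambiguous
    n_cw <- sum(p$class == "clockwise" & dir_ok)
    n_ccw <- sum(p$class == "counterclockwise" & dir_ok)
    data.frame(group = p$group[1], circuit = p$circuit[1],
               n_cw = n_cw, n_ccw = n_ccw,
               n_same = sum(p$class == "same_electrode"),
               n_diag = sum(p$class == "diagonal"),
               n_ambiguous = sum(p$ambiguous),
               pct_clockwise = if (n_cw + n_ccw > 0)
                 100 * n_cw / (n_cw + n_ccw) else NA_real_,
               pct_nondirectional = 100 *
                 sum(p$class %in% c("same_electrode", "diagonal")) / nrow(p))
  })
  per_circuit <- do.call(rbind, per)
  rownames(per_circuit) <- NULL
  summ <- lapply(split(per_circuit, per_circuit$group), function(g) {
    ok <- !is.na(g$pct_clockwise)
    tot <- g$n_cw + g$n_ccw + g$n_same + g$n_diag
    data.frame(group = g$group[1],
               mean_pct_clockwise = if (any(ok)) mean(g$pct_clockwise[ok]) else NA_real_,
               sem_pct_clockwise = if (sum(ok) >= 2) sem(g$pct_clockwise[ok]) else NA_real_,
               n_circuits = sum(ok), n_excluded = sum(!ok),
               pct_nondirectional_pooled =
                 100 * sum(g$n_same + g$n_diag) / sum(tot))
  })
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(per_circuit = per_circuit, summary = summary)
}
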