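test_that("raster assignment respects the (0, 250] ms window", {
  lay <- ring4()
  pr <- stimulation_protocol(1L, n_repeats = 4L)  # pulses at 0, .25, .5, .75
  # a spike exactly at a pulse onset has latency 0 there (open end) and
  # is assigned to the previous pulse at latency 250 ms (closed end)
  ev <- spike_events(c(2L, 3L, 4L), c(0.25, 0.255, 0.50 + 0.250), 1.0)
  ra <- build_raster(ev, lay, pr)
  expect_equal(nrow(ra$entries), 3L)
  expect_equal(ra$entries$latency_ms, c(250, 5, 250))
  expect_equal(ra$entries$repeat_idx, c(1L, 2L, 3L))
  # a spike at the first pulse onset has no previous window and is dropped
  ra1 <- build_raster(spike_events(2L, 0, 1.0), lay, pr)
  expect_equal(nrow(ra1$entries), 0L)
  # empty events -> empty raster but the full repeat count
  ra0 <- build_raster(spike_events(duration = 1), lay, pr)
  expect_equal(nrow(ra0$entries), 0L)
  expect_equal(ra0$n_repeats, 4L)
  # window longer than the inter-pulse interval would double-assign
  expect_error(build_raster(ev, lay, pr, window_ms = 300), "double-assigned")
})

test_that("a deterministic band fills every repeat with 4 spikes at its latency", {
  cfg <- sim_config(seed = 2,
                    evoked_bands = data.frame(latency_ms = 5, jitter_ms = 0,
                                              prob = 1),
                    late_response_rate = 0)
  pr <- stimulation_protocol(3L, n_repeats = 100L)
  tr <- simulate_stimulation(cfg, ring4(), pr)
  ra <- build_raster(tr$spikes, ring4(), pr)
  per_repeat <- table(ra$entries$repeat_idx)
  expect_equal(length(per_repeat), 100L)
  expect_true(all(per_repeat == 4L))
  expect_equal(unique(round(ra$entries$latency_ms, 9)), 5)
  # raster latency variance equals the configured jitter^2 (here 0)
  expect_equal(var(ra$entries$latency_ms), 0)
  row <- classify_activity_inducing(ra)
  expect_equal(row$total_spikes, 400L)
  expect_equal(row$mean_induced_per_stimulus, 4)
  expect_true(row$activity_inducing)
})

test_that("the activity-inducing boundary is exact at total = n_repeats", {
  mk_row <- function(total) data.frame(
    stimulated_electrode = 1L, circuit = 1L, total_spikes = total,
    activity_inducing = total >= 480L,
    mean_induced_per_stimulus = total / 480)
  cfg <- sim_config(seed = 2, late_response_rate = 0,
                    evoked_bands = data.frame(latency_ms = 10, jitter_ms = 1,
                                              prob = 0.9))
  pr <- stimulation_protocol(1L, n_repeats = 480L)
  tr <- simulate_stimulation(cfg, ring4(), pr)
  ra <- build_raster(tr$spikes, ring4(), pr)
  row <- classify_activity_inducing(ra)
  expect_equal(row$activity_inducing, row$total_spikes >= 480)
  # boundary arithmetic without floating point
  expect_false(mk_row(479L)$activity_inducing)
  expect_true(mk_row(480L)$activity_inducing)
  expect_true(classify_activity_inducing(ra, n_repeats = row$total_spikes)$activity_inducing)
})

test_that("group summary averages induced spikes over inducing electrodes only", {
  rows <- data.frame(stimulated_electrode = 1:4, circuit = 1L,
                     total_spikes = c(0L, 100L, 480L, 960L),
                     activity_inducing = c(FALSE, FALSE, TRUE, TRUE),
                     mean_induced_per_stimulus = c(0, 100, 480, 960) / 480)
  g <- group_stimulation_summary(rows)
  expect_equal(g$pct_inducing, 50)
  expect_equal(g$mean_induced, 1.5)
  # no inducing electrode: mean absent
  rows0 <- rows; rows0$activity_inducing <- FALSE
  g0 <- group_stimulation_summary(rows0)
  expect_equal(g0$pct_inducing, 0)
  expect_true(is.na(g0$mean_induced))
  # identical electrodes: SEM 0
  rows1 <- rows[c(3, 3, 3), ]
  expect_equal(group_stimulation_summary(rows1)$sem_induced, 0)
})

test_that("raster assignment equals the brute-force oracle on random data", {
  set.seed(123)
  lay <- ring4()
  for (i in 1:150) {
    n_pulse <- sample(2:8, 1)
    pr <- stimulation_protocol(1L, pulse_times = sort(runif(n_pulse, 0, 2)) +
                                 (0:(n_pulse - 1)))  # spacing >= uniform gap
    n <- sample(0:60, 1)
    ev <- spike_events(sample(1:4, n, replace = TRUE),
                       runif(n, 0, max(pr$pulse_times) + 0.3),
                       max(pr$pulse_times) + 0.3)
    w <- floor(min(diff(pr$pulse_times)) * 1000 * 0.8)
    got <- build_raster(ev, lay, pr, window_ms = w)$entries
    want <- oracle_raster(ev$electrode, ev$time, 1:4, pr$pulse_times, w)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$repeat_idx, want$latency_ms, want$electrode), ]
      expect_equal(got$repeat_idx, want$repeat_idx)
      expect_equal(got$electrode, want$electrode)
      expect_equal(got$latency_ms, want$latency_ms, tolerance = 1e-9)
    }
  }
})

test_that("every spike lands in exactly one repeat or the pre-pulse region", {
  cfg <- sim_config(seed = 8, late_response_rate = 40)
  pr <- stimulation_protocol(2L, n_repeats = 50L, t_start = 1)
  tr <- simulate_stimulation(cfg, ring4(), pr)
  extra <- spike_events(c(tr$spikes$electrode, 1L),
                        c(tr$spikes$time, 0.5),  # one pre-first-pulse spike
                        events_duration(tr$spikes))
  ra <- build_raster(extra, ring4(), pr)
  n_pre <- sum(extra$time <= pr$pulse_times[1])
  expect_equal(nrow(ra$entries) + n_pre, nrow(extra))
  # no (repeat, electrode, latency) duplication
  expect_equal(anyDuplicated(ra$entries), 0L)
})
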