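test_that("pair classification matches the ring adjacency rules", {
  expect_equal(classify_pair(4, 1), "clockwise")
  expect_equal(classify_pair(1, 2), "clockwise")
  expect_equal(classify_pair(2, 1), "counterclockwise")
  expect_equal(classify_pair(1, 4), "counterclockwise")
  expect_equal(classify_pair(1, 3), "diagonal")
  expect_equal(classify_pair(4, 2), "diagonal")
  expect_equal(classify_pair(2, 2), "same_electrode")
  # every ordered position pair lands in exactly one class
  grid <- expand.grid(pre = 1:4, post = 1:4)
  cls <- classify_pair(grid$pre, grid$post)
  expect_equal(sum(cls == "clockwise"), 4L)
  expect_equal(sum(cls == "counterclockwise"), 4L)
  expect_equal(sum(cls == "same_electrode"), 4L)
  expect_equal(sum(cls == "diagonal"), 4L)
})

test_that("a clockwise chain yields overlapping clockwise pairs", {
  ev <- spike_events(1:4, c(0, 2, 4, 6) / 1000, 1)
  pairs <- extract_pairs(ev, ring4(), 1, active_electrodes = 1:4)
  expect_equal(nrow(pairs), 3L)
  expect_true(all(pairs$class == "clockwise"))
  # the middle spikes serve as post of one pair and pre of the next
  expect_equal(pairs$pre_electrode, 1:3)
  expect_equal(pairs$post_electrode, 2:4)
})

test_that("the 5 ms pairing window is strict", {
  ev <- spike_events(c(1L, 2L), c(0, 0.005), 1)
  expect_equal(nrow(extract_pairs(ev, ring4(), 1, active_electrodes = 1:4)), 0L)
  ev2 <- spike_events(c(1L, 2L), c(0, 0.00499), 1)
  expect_equal(nrow(extract_pairs(ev2, ring4(), 1, active_electrodes = 1:4)), 1L)
})

test_that("inactive electrodes are removed before pairing", {
  # electrode 2 fires once in 100 s (0.01 Hz, inactive): its spike must
  # not break the 1 -> 3 gap into sub-window pieces
  ev <- spike_events(c(1L, 2L, 3L), c(10.000, 10.002, 10.004), 100)
  pairs <- extract_pairs(ev, ring4(), 1)
  expect_true(all(pairs$pre_electrode != 2 & pairs$post_electrode != 2))
})

test_that("identical timestamps across electrodes are flagged ambiguous", {
  ev <- spike_events(c(2L, 1L), c(0.010, 0.010), 1)
  pairs <- extract_pairs(ev, ring4(), 1, active_electrodes = 1:4)
  expect_equal(nrow(pairs), 1L)
  expect_true(pairs$ambiguous)
  # ordered by ascending position
  expect_equal(pairs$pre_pos, 1L)
  expect_equal(pairs$post_pos, 2L)
  # and excluded from the clockwise counts downstream
  cs <- clockwise_summary(pairs)
  expect_equal(cs$per_circuit$n_cw, 0L)
  expect_equal(cs$per_circuit$n_ambiguous, 1L)
})

test_that("pair extraction equals the brute-force oracle on random data", {
  set.seed(99)
  pos_of <- setNames(1:4, as.character(1:4))
  for (i in 1:250) {
    n <- sample(2:200, 1)
    el <- sample(1:4, n, replace = TRUE)
    # discretise at 20 kHz so identical timestamps do occur
    tm <- round(runif(n, 0, 0.5) * 20000) / 20000
    ev <- spike_events(el, tm, 0.5)
    got <- extract_pairs(ev, ring4(), 1, active_electrodes = 1:4)
    want <- oracle_pairs(ev$electrode, ev$time, pos_of, 5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$pre_electrode, want$pre)
      expect_equal(got$post_electrode, want$post)
      expect_equal(got$delta_ms, want$delta_ms)
      expect_equal(got$class, want$class)
      expect_equal(got$ambiguous, want$ambiguous)
    }
  }
})

test_that("frequency map counts and normalisation are consistent", {
  empty <- frequency_map(extract_pairs(spike_events(duration = 1), ring4(), 1,
                                       active_electrodes = 1:4))
  expect_true(all(empty$counts == 0))
  ev <- spike_events(rep(c(1L, 2L), 10),
                     sort(rep(seq(0, 0.9, by = 0.1), 2)) + rep(c(0, 0.002), 10),
                     1)
  fm <- frequency_map(extract_pairs(ev, ring4(), 1, active_electrodes = 1:4))
  expect_equal(fm$counts[1, 2], 10L)
  expect_equal(fm$percent[1, 2], 100)
  # random pair lists: percentages per pre position sum to 100 where defined
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:100, 1)
    pairs <- data.frame(pre_pos = sample(1:4, n, TRUE),
                        post_pos = sample(1:4, n, TRUE))
    fm <- frequency_map(pairs)
    rs <- rowSums(fm$percent, na.rm = TRUE)
    expect_true(all(abs(rs[rowSums(fm$counts) > 0] - 100) < 1e-9))
  }
})

test_that("clockwise summary averages per circuit, unweighted", {
  pairs <- rbind(
    data.frame(circuit = 1, class = c(rep("clockwise", 6),
                                      rep("counterclockwise", 4)),
               ambiguous = FALSE),   # 60% over 10 pairs
    data.frame(circuit = 2, class = c(rep("clockwise", 80),
                                      rep("counterclockwise", 20)),
               ambiguous = FALSE))   # 80% over 100 pairs
  cs <- clockwise_summary(pairs)
  expect_equal(cs$summary$mean_pct_clockwise, 70)  # not the pooled 78.2
  expect_equal(cs$summary$n_circuits, 2L)
  # all-clockwise circuits average to 100
  all_cw <- data.frame(circuit = rep(1:3, each = 5), class = "clockwise",
                       ambiguous = FALSE)
  expect_equal(clockwise_summary(all_cw)$summary$mean_pct_clockwise, 100)
  # circuits without directional pairs are excluded and tallied
  nd <- rbind(pairs, data.frame(circuit = 3, class = "diagonal",
                                ambiguous = FALSE))
  cs2 <- clockwise_summary(nd)
  expect_equal(cs2$summary$n_excluded, 1L)
  expect_equal(cs2$summary$mean_pct_clockwise, 70)
})

test_that("swapping propagation probabilities mirrors the clockwise percentage", {
  run <- function(pf, pb, seed) {
    lay <- circuit_layout(1:40, rep(1:10, each = 4), rep(1:4, 10))
    cfg <- sim_config(seed = seed, background_rate = 1, p_forward = pf,
                      p_backward = pb)
    tr <- simulate_spontaneous(cfg, lay, 120)
    pairs <- do.call(rbind, lapply(1:10, function(circ)
      extract_pairs(tr$spikes, lay, circ, active_electrodes = 1:40)))
    clockwise_summary(pairs)$summary$mean_pct_clockwise
  }
  p1 <- run(0.35, 0.05, 17)
  p2 <- run(0.05, 0.35, 17)
  expect_gt(p1, 75)
  expect_lt(p2, 25)
  expect_lt(abs((p1 - 50) - (50 - p2)), 8)  # approximate mirror symmetry
})
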