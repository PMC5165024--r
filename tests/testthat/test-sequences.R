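map66 <- grid_electrode_map(6, 6)

test_that("chaining follows the leader-window and inter-spike-gap rules", {
  cfg <- extraction_config()
  # 58 joins via the 15 ms gap (58-45=13), 70 likewise (70-58=12), 200 terminates
  ds <- make_ds(1:6, c(0, 20, 45, 58, 70, 200), map66)
  seqs <- extract_raw_sequences(ds, cfg)
  expect_length(seqs, 1L)
  expect_equal(seqs[[1]]$time_ms, c(0, 20, 45, 58, 70))
  expect_equal(seqs[[1]]$latency_ms, c(0, 20, 45, 58, 70))

  # a 4-spike candidate is discarded by the >= 5 filter
  ds4 <- make_ds(1:5, c(0, 20, 40, 60, 300), map66)
  expect_length(extract_raw_sequences(ds4, cfg), 0L)

  # boundary inclusivity: exactly 50 ms from the leader still appends
  ds_b <- make_ds(1:5, c(0, 10, 20, 30, 50), map66)
  expect_length(extract_raw_sequences(ds_b, cfg), 1L)

  # empty input
  expect_length(extract_raw_sequences(make_ds(integer(0), numeric(0), map66),
                                      cfg), 0L)
})

test_that("extraction matches the naive chaining oracle on random streams", {
  cfg <- extraction_config()
  for (case in 1:300) {
    set.seed(case)
    n <- sample(5:60, 1)
    times <- sort(round(cumsum(rexp(n, rate = 1 / sample(c(5, 15, 40), 1))), 1))
    ch <- sample(map66$channel_id, n, replace = TRUE)
    ds <- spike_dataset(data.frame(channel_id = ch, time_ms = times),
                        map66, 1)
    got <- extract_raw_sequences(ds, cfg)
    want <- oracle_chain(ds$events$time_ms)
    expect_length(got, length(want))
    for (k in seq_along(want))
      expect_equal(got[[k]]$time_ms, ds$events$time_ms[want[[k]]])
  }
})

test_that("each event lands in exactly one pre-filter candidate", {
  set.seed(42)
  times <- sort(runif(200, 0, 5000))           # a.s. distinct
  ds <- make_ds(sample(map66$channel_id, 200, TRUE), times, map66)
  seqs <- extract_raw_sequences(ds, extraction_config(min_length = 2L))
  all_t <- unlist(lapply(seqs, function(s) s$time_ms))
  expect_lte(length(all_t), 200)
  expect_false(any(duplicated(all_t)))         # no spike in two sequences
  for (s in seqs) expect_true(all(diff(s$time_ms) >= 0))
})

test_that("widening the chain gap never loses sequence-assigned spikes", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 100
    ds <- make_ds(sample(map66$channel_id, n, TRUE),
                  sort(runif(n, 0, 3000)), map66)
    n_assigned <- function(gap) {
      seqs <- extract_raw_sequences(ds, extraction_config(chain_gap = gap))
      sum(vapply(seqs, nrow, 0L))
    }
    expect_lte(n_assigned(10), n_assigned(15))
    expect_lte(n_assigned(15), n_assigned(25))
  }
})

test_that("tied spikes reorder by distance from the preceding anchor", {
  # anchor channel 1 at (0,0); tied channels at 30 mm and 10 mm
  map <- electrode_map(1:3, c(0, 30, 10), c(0, 0, 0))
  ds <- make_ds(c(1, 2, 3), c(0, 20, 20), map)
  out <- reorder_tied_spikes(ds, map)
  expect_equal(out$events$channel_id, c(1L, 3L, 2L))  # nearer first

  # singleton runs unchanged
  ds1 <- make_ds(c(1, 2), c(0, 20), map)
  expect_equal(reorder_tied_spikes(ds1, map)$events$channel_id, c(1L, 2L))

  # equidistant ties fall back to channel-id order
  mape <- electrode_map(1:3, c(0, 10, -10), c(0, 0, 0))
  dse <- make_ds(c(1, 2, 3), c(0, 20, 20), mape)
  expect_equal(reorder_tied_spikes(dse, mape)$events$channel_id, c(1L, 2L, 3L))

  # run opening the record anchors on the following event
  mapo <- electrode_map(1:3, c(0, 40, 10), c(0, 0, 0))
  dso <- make_ds(c(2, 3, 1), c(0, 0, 20), mapo)
  out_o <- reorder_tied_spikes(dso, mapo)
  expect_equal(out_o$events$channel_id, c(3L, 2L, 1L))  # ch3 nearer to ch1

  # fully tied record keeps channel order with a warning
  dsa <- make_ds(c(1, 2, 3), c(5, 5, 5), map)
  expect_warning(out_a <- reorder_tied_spikes(dsa, map), "tied")
  expect_equal(out_a$events$channel_id, c(1L, 2L, 3L))
})

test_that("connection matrix counts consecutive transitions", {
  s123 <- spikeprop:::new_sequence(c(1L, 2L, 3L), c(0, 10, 20))
  C <- build_connection_matrix(list(s123), map66)
  expect_equal(C$C["1", "2"], 1L)
  expect_equal(C$C["2", "3"], 1L)
  expect_equal(sum(C$C), 2L)
  # repeats of the same pair accumulate; self-transitions don't count
  s447 <- spikeprop:::new_sequence(c(4L, 4L, 7L), c(0, 5, 10))
  C2 <- build_connection_matrix(rep(list(s447), 6), map66)
  expect_equal(C2$C["4", "7"], 6L)
  expect_equal(C2$C["4", "4"], 0L)
  expect_equal(C2$row_sums[["4"]], 6)
  # empty list -> zero matrix
  expect_equal(sum(build_connection_matrix(list(), map66)$C), 0L)
})

test_that("constraints keep adjacent-partition steps and frequent jumps", {
  map <- grid_electrode_map(4, 8)             # partitions into 2x2 tiles
  part <- auto_partition(map)
  cfg <- extraction_config()
  # a wavefront walking along the grid rows stays in adjacent partitions
  walk <- spikeprop:::new_sequence(c(1L, 2L, 5L, 6L, 9L, 10L),
                                   c(0, 5, 10, 15, 20, 25))
  C <- build_connection_matrix(list(walk), map)
  out <- apply_spatial_constraints(list(walk), part, C, cfg, map)
  expect_length(out, 1L)
  expect_equal(out[[1]]$channel_id, walk$channel_id)

  # remote jump with transition fraction > threshold is retained
  jump <- spikeprop:::new_sequence(c(1L, 2L, 3L, 4L, 29L, 30L, 31L, 32L, 0L + 28L),
                                   c(0, 4, 8, 12, 16, 20, 24, 28, 32))
  # fabricate C so that 4 -> 29 is frequent (fraction 1 > 0.05)
  Cj <- build_connection_matrix(list(jump), map)
  outj <- apply_spatial_constraints(list(jump), part, Cj, cfg, map)
  expect_length(outj, 1L)
  expect_equal(nrow(outj[[1]]), 9L)

  # same jump with diluted frequency (0.04) splits; the 4-spike tail of a
  # 4+4 split is dropped by the length filter
  dil <- lapply(1:24, function(k)
    spikeprop:::new_sequence(c(4L, sample(c(3L, 8L), 1)), c(0, 5)))
  set.seed(1)
  Cd <- build_connection_matrix(c(list(jump), dil), map)
  frac <- Cd$C["4", "29"] / Cd$row_sums[["4"]]
  expect_lte(frac, 0.05)
  outd <- apply_spatial_constraints(list(jump), part, Cd, cfg, map)
  expect_length(outd, 1L)       # only the 5-spike remote half survives
  expect_equal(nrow(outd[[1]]), 5L)
  expect_equal(outd[[1]]$latency_ms[1], 0)   # latencies from its own leader
})

test_that("split mode yields temporally overlapping candidates, strict terminates", {
  map <- electrode_map(1:4, c(0, 10, 100, 110), c(0, 0, 0, 0))
  part <- suppressWarnings(auto_partition(map))   # two separate strips
  # interleaved near/far spikes: two true concurrent trains
  ch <- c(1L, 3L, 2L, 4L, 1L, 3L, 2L, 4L, 1L, 3L)
  s <- spikeprop:::new_sequence(ch, seq(0, 45, by = 5))
  # C from a large cohort of within-strip transitions, so the cross-strip
  # steps of s stay infrequent (< 0.05)
  dil <- c(rep(list(spikeprop:::new_sequence(c(1L, 2L), c(0, 5))), 100),
           rep(list(spikeprop:::new_sequence(c(3L, 4L), c(0, 5))), 100),
           rep(list(spikeprop:::new_sequence(c(2L, 1L), c(0, 5))), 100),
           rep(list(spikeprop:::new_sequence(c(4L, 3L), c(0, 5))), 100))
  C <- build_connection_matrix(c(list(s), dil), map)
  cfg <- extraction_config(min_length = 5L)
  out_split <- apply_spatial_constraints(list(s), part, C, cfg, map)
  expect_length(out_split, 2L)
  sides <- vapply(out_split, function(q) all(q$channel_id %in% c(1L, 2L)), NA)
  expect_setequal(sides, c(TRUE, FALSE))
  # the two recovered trains overlap in time
  rng <- vapply(out_split, function(q) range(q$time_ms), numeric(2))
  expect_lt(max(rng[1, ]), min(rng[2, ]))
  # strict mode closes the chain at each violation: fragments all < 5 spikes
  cfg_strict <- extraction_config(min_length = 5L, mode = "strict")
  out_strict <- apply_spatial_constraints(list(s), part, C, cfg_strict, map)
  expect_length(out_strict, 0L)
})

test_that("every consecutive retained pair satisfies adjacency or frequency", {
  map <- grid_electrode_map(4, 8)
  part <- auto_partition(map)
  cfg <- extraction_config(min_length = 2L)
  set.seed(11)
  ds <- make_ds(sample(map$channel_id, 300, TRUE),
                sort(runif(300, 0, 20000)), map)
  raw <- extract_raw_sequences(ds, cfg)
  C <- build_connection_matrix(raw, map)
  out <- apply_spatial_constraints(raw, part, C, cfg, map)
  frac <- C$C / ifelse(C$row_sums > 0, C$row_sums, Inf)
  for (s in out) {
    expect_true(all(diff(s$time_ms) >= 0))
    ids <- as.character(s$channel_id)
    for (k in seq_len(nrow(s) - 1L)) {
      p <- part$assignment[ids[k]]; q <- part$assignment[ids[k + 1L]]
      ok <- spikeprop:::partitions_linked(part, p, q) ||
        frac[ids[k], ids[k + 1L]] > cfg$freq_threshold
      expect_true(ok)
    }
  }
  # no spike duplicated across constrained sequences
  keys <- unlist(lapply(seq_along(out), function(i)
    paste(out[[i]]$channel_id, out[[i]]$time_ms)))
  expect_lte(length(keys), nrow(ds$events))
})
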