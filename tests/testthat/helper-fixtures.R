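# shared fixture builders (all data generated in code)

# random scattered electrode map with distinct coordinates
random_map <- function(n, seed) {
  set.seed(seed)
  repeat {
    x <- round(stats::runif(n, 0, 100), 1)
    y <- round(stats::runif(n, 0, 100), 1)
    if (!anyDuplicated(cbind(x, y))) break
  }
  electrode_map(seq_len(n), x, y)
}

# dataset helper on an existing map
make_ds <- function(channel_id, time_ms, map, minutes = 1) {
  spike_dataset(data.frame(channel_id = channel_id, time_ms = time_ms),
                map, analyzed_minutes = minutes)
}

# independent naive re-implementation of the chaining rules: walks the
# stream event by event, tracking the open candidate explicitly
oracle_chain <- function(times, leader_window = 50, chain_gap = 15,
                         min_length = 5) {
  out <- list()
  cur <- integer(0)
  for (i in seq_along(times)) {
    if (!length(cur)) { cur <- i; next }
    within_leader <- (times[i] - times[cur[1]]) <= leader_window
    within_gap <- (times[i] - times[cur[length(cur)]]) <= chain_gap
    if (within_leader || within_gap) {
      cur <- c(cur, i)
    } else {
      out <- c(out, list(cur))
      cur <- i
    }
  }
  out <- c(out, list(cur))
  Filter(function(ix) length(ix) >= min_length, out)
}

# brute-force gini: population mean absolute difference / (2 * mean)
oracle_gini <- function(f) {
  n <- length(f)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(f[i] - f[j])
  tot / (2 * n^2 * mean(f))
}

# exact rank-sum p by enumerating group assignments as bitmasks (independent
# of the combn-based implementation path)
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b); r <- rank(x); n <- length(x); n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != n1) next
    ws <- c(ws, sum(r[bits == 1L]))
  }
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
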