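#' Extraction configuration
#'
#' Constants of the multichannel sequence-extraction algorithm. Interictal
#' spikes propagate across the cortex with roughly 10--50 ms latencies, so a
#' spike joins the open candidate sequence when it peaks within
#' `leader_window` ms of the sequence leader, or -- to capture unexpectedly
#' long sequences -- within `chain_gap` ms of the previous spike. Both
#' boundaries are inclusive (a spike exactly at the window edge is
#' appended). Candidates shorter than `min_length` spikes are discarded as
#' probable false positives. `freq_threshold` is the fraction of channel
#' *i*'s outgoing transitions above which a long-range i -> j connection is
#' deemed "frequent" and exempted from the partition constraint.
#'
#' @param leader_window ms from sequence leader (default 50).
#' @param chain_gap ms from the previous spike (default 15).
#' @param min_length minimum spikes per retained sequence (default 5).
#' @param freq_threshold frequent-connection fraction (default 0.05).
#' @param mode `"split"` (default): a constraint-violating spike seeds a new,
#'   temporally overlapping candidate; `"strict"`: it terminates the chain.
#' @return A list of class `"extraction_config"`.
#' @export
extraction_config <- function(leader_window = 50, chain_gap = 15,
                              min_length = 5L, freq_threshold = 0.05,
                              mode = c("split", "strict")) {
  stopifnot(leader_window >= chain_gap, chain_gap > 0,
            min_length >= 2L, freq_threshold > 0, freq_threshold < 1)
  structure(list(leader_window = leader_window, chain_gap = chain_gap,
                 min_length = as.integer(min_length),
                 freq_threshold = freq_threshold,
                 mode = match.arg(mode)),
            class = "extraction_config")
}

new_sequence <- function(channel_id, time_ms) {
  s <- data.frame(channel_id = as.integer(channel_id),
                  time_ms = as.numeric(time_ms))
  s$latency_ms <- s$time_ms - s$time_ms[1L]
  class(s) <- c("spike_sequence", "data.frame")
  s
}

#' Extract raw multichannel spike sequences
#'
#' Greedy single pass over the time-sorted event stream. The first spike is
#' the "leader" of a candidate sequence; each successive spike is appended
#' if it occurs within `leader_window` ms of the leader or within
#' `chain_gap` ms of the previous spike. A spike violating both conditions
#' is the "terminating spike": the candidate is closed and the terminating
#' spike becomes the leader of the next candidate, so every event belongs
#' to exactly one candidate. Candidates with fewer than `min_length` spikes
#' are then discarded.
#'
#' @param ds a [spike_dataset()] (time-sorted; run [reorder_tied_spikes()]
#'   first so acquisition ties are in spatial order).
#' @param cfg an [extraction_config()].
#' @return List of `"spike_sequence"` data.frames (`channel_id`, `time_ms`,
#'   `latency_ms` from the sequence's own leader).
#' @export
extract_raw_sequences <- function(ds, cfg = extraction_config()) {
  stopifnot(inherits(ds, "spike_dataset"), inherits(cfg, "extraction_config"))
  ev <- ds$events
  n <- nrow(ev)
  if (!n) return(list())
  t <- ev$time_ms
  starts <- integer(n); starts[1L] <- 1L; ns <- 1L
  lead_t <- t[1L]
  for (i in seq_len(n)[-1L]) {
    if ((t[i] - lead_t) <= cfg$leader_window ||
        (t[i] - t[i - 1L]) <= cfg$chain_gap) next
    ns <- ns + 1L; starts[ns] <- i; lead_t <- t[i]
  }
  starts <- starts[seq_len(ns)]
  ends <- c(starts[-1L] - 1L, n)
  keep <- (ends - starts + 1L) >= cfg$min_length
  lapply(which(keep), function(k)
    new_sequence(ev$channel_id[starts[k]:ends[k]], t[starts[k]:ends[k]]))
}

#' Spatially reorder tied spikes
#'
#' At a modest acquisition rate (200 Hz) distinct spikes are often detected
#' with the same peak time; the detector orders such "tied" events by
#' ascending channel number, which does not reflect the propagation path.
#' Each maximal run of equal-time events is re-ordered by ascending
#' Euclidean distance from an anchor -- the nearest-in-time non-tied event
#' preceding the run, or, when the run opens the record, the first non-tied
#' event following it -- under the assumption that transmission probability
#' decreases with distance. Residual ties are broken by channel id. When
#' every event in the record shares one time there is no anchor: the
#' channel-id order is kept with a warning.
#'
#' @param ds a [spike_dataset()].
#' @param map an [electrode_map()].
#' @return A [spike_dataset()] with reordered events.
#' @export
reorder_tied_spikes <- function(ds, map) {
  stopifnot(inherits(ds, "spike_dataset"), inherits(map, "electrode_map"))
  ev <- ds$events
  n <- nrow(ev)
  if (n < 2L) return(ds)
  xy <- cbind(map$x_mm, map$y_mm)[match(ev$channel_id, map$channel_id), , drop = FALSE]
  run_id <- cumsum(c(TRUE, diff(ev$time_ms) != 0))
  run_len <- tabulate(run_id)
  if (all(run_len == n)) {  # single run spanning the whole record
    warning("all events tied; keeping channel-id order")
    return(ds)
  }
  ord <- seq_len(n)
  for (r in which(run_len > 1L)) {
    idx <- which(run_id == r)
    # anchor: last event before the run; if the run opens the record, the
    # first event after it (guaranteed to exist since not all events tied)
    a <- if (idx[1L] > 1L) idx[1L] - 1L else idx[length(idx)] + 1L
    dd <- sqrt((xy[idx, 1L] - xy[a, 1L])^2 + (xy[idx, 2L] - xy[a, 2L])^2)
    ord[idx] <- idx[order(dd, ev$channel_id[idx])]
  }
  out <- ds
  out$events <- ev[ord, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' Channel-by-channel connection matrix
#'
#' `C[i, j]` counts how many times a spike propagated directly from channel
#' *i* to channel *j*, i.e. the number of consecutive (i, j) pairs across
#' all sequences. Self-transitions (detector re-firing on one channel) are
#' not counted. Row sums give each channel's total outgoing transitions,
#' the denominator of the frequent-connection rule.
#'
#' @param seqs list of `"spike_sequence"` objects.
#' @param map an [electrode_map()].
#' @return A list of class `"connection_matrix"`: `C` (integer matrix with
#'   channel-id dimnames) and `row_sums`.
#' @export
build_connection_matrix <- function(seqs, map) {
  stopifnot(inherits(map, "electrode_map"))
  ids <- map$channel_id
  C <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in seqs) {
    ch <- s$channel_id
    if (length(ch) < 2L) next
    from <- ch[-length(ch)]; to <- ch[-1L]
    ok <- from != to
    for (k in which(ok)) {
      i <- match(from[k], ids); j <- match(to[k], ids)
      C[i, j] <- C[i, j] + 1L
    }
  }
  structure(list(C = C, row_sums = rowSums(C)), class = "connection_matrix")
}

#' Apply partition and frequent-connection constraints
#'
#' Propagation velocity is bounded by neural conduction speed, so spikes at
#' very remote sites with near-zero latency difference likely belong to
#' separate, temporally overlapping sequences. Each successive spike must
#' therefore fall in the same partition as its predecessor or in an
#' immediately adjacent partition -- unless the (i, j) channel connection is
#' "frequent", i.e. `C[i, j] / row_sum_i > freq_threshold` (long-range
#' connections are allowed when a spike leaving channel *i* goes directly
#' to *j* more than 5% of the time, by default). A spike with zero outgoing
#' transitions never qualifies via the frequency rule.
#'
#' In `"split"` mode a rejected spike seeds a new concurrent candidate (a
#' later spike may continue either chain; the most recently extended chain
#' is tried first); in `"strict"` mode it closes the current chain. All
#' resulting sequences are re-filtered to `min_length`, and latencies are
#' recomputed from each sequence's own leader.
#'
#' @param seqs raw sequences from [extract_raw_sequences()].
#' @param partitions a `"partitioning"` object covering all channels.
#' @param C a [build_connection_matrix()] result built from the same raw
#'   sequences (first pass).
#' @param cfg an [extraction_config()].
#' @param map an [electrode_map()].
#' @return List of constrained `"spike_sequence"` objects, ordered by leader
#'   time.
#' @export
apply_spatial_constraints <- function(seqs, partitions, C, cfg, map) {
  stopifnot(inherits(partitions, "partitioning"),
            inherits(C, "connection_matrix"),
            inherits(cfg, "extraction_config"),
            inherits(map, "electrode_map"))
  ids <- map$channel_id
  part_of <- partitions$assignment[match(as.character(ids), names(partitions$assignment))]
  frac <- C$C / ifelse(C$row_sums > 0, C$row_sums, Inf)  # row_sum 0 -> 0
  linked <- outer(part_of, part_of, Vectorize(function(p, q)
    partitions_linked(partitions, p, q)))
  dimnames(linked) <- dimnames(frac)
  out <- list()
  for (s in seqs) {
    ch_idx <- match(s$channel_id, ids)
    chains <- list()       # each: integer vector of row positions in s
    last_upd <- numeric(0) # extension order, for most-recent-first search
    closed <- list()
    tick <- 0
    for (r in seq_len(nrow(s))) {
      placed <- FALSE
      if (length(chains)) {
        for (cix in order(last_upd, decreasing = TRUE)) {
          prev <- ch_idx[chains[[cix]][length(chains[[cix]])]]
          ok <- linked[prev, ch_idx[r]] ||
            frac[prev, ch_idx[r]] > cfg$freq_threshold
          if (ok) {
            chains[[cix]] <- c(chains[[cix]], r)
            tick <- tick + 1; last_upd[cix] <- tick
            placed <- TRUE
            break
          }
          if (cfg$mode == "strict") break  # only the open chain is tried
        }
      }
      if (!placed) {
        if (cfg$mode == "strict" && length(chains)) {
          closed <- c(closed, chains)  # rejection terminates the open chain
          chains <- list(); last_upd <- numeric(0)
        }
        chains[[length(chains) + 1L]] <- r
        tick <- tick + 1; last_upd[length(chains)] <- tick
      }
    }
    out <- c(out, lapply(c(closed, chains), function(ix)
      new_sequence(s$channel_id[ix], s$time_ms[ix])))
  }
  out <- Filter(function(s) nrow(s) >= cfg$min_length, out)
  out[order(vapply(out, function(s) s$time_ms[1L], 0))]
}
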