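#' Recruitment latency map
#'
#' Each channel's average temporal position (ms from the sequence leader)
#' across all spike sequences it joins. Channels that consistently appear
#' early mark "source" regions of spike propagation, late channels mark
#' "sinks". A channel contributes its first occurrence per sequence (its
#' recruitment moment); channels never recruited are excluded rather than
#' zero-filled, so the downstream Moran Index is restricted to channels
#' with data.
#'
#' @param seqs list of (cleaned) `"spike_sequence"` objects.
#' @param map an [electrode_map()].
#' @param min_count minimum appearances for a channel to enter the map
#'   (default 1).
#' @return A data.frame of class `"latency_map"` with columns `channel_id`,
#'   `mean_latency_ms`, `n_appearances`, restricted to included channels.
#' @export
recruitment_latency_map <- function(seqs, map, min_count = 1L) {
  stopifnot(inherits(map, "electrode_map"))
  if (!length(seqs)) stop("no sequences")
  samp <- latency_samples(seqs, map)
  keep <- lengths(samp) >= min_count & lengths(samp) > 0L
  lm <- data.frame(channel_id = map$channel_id[keep],
                   mean_latency_ms = vapply(samp[keep], mean, 0),
                   n_appearances = lengths(samp[keep]))
  rownames(lm) <- NULL
  class(lm) <- c("latency_map", "data.frame")
  lm
}

# per-channel first-occurrence latencies, one entry per sequence joined
latency_samples <- function(seqs, map) {
  samp <- stats::setNames(vector("list", nrow(map)), map$channel_id)
  for (s in seqs) {
    first <- !duplicated(s$channel_id)
    ch <- as.character(s$channel_id[first])
    lat <- s$latency_ms[first]
    for (k in seq_along(ch)) samp[[ch[k]]] <- c(samp[[ch[k]]], lat[k])
  }
  samp
}

#' Cumulative probability distribution of recruitment latencies
#'
#' Per-channel empirical CDF of the first-occurrence latencies, evaluated
#' on a fixed millisecond grid. Channels that consistently appear early in
#' spike sequences exhibit a left-shifted CPD.
#'
#' @param seqs list of `"spike_sequence"` objects.
#' @param map an [electrode_map()].
#' @param grid_ms evaluation grid (default 0 to 100 ms in 5 ms steps).
#' @return A matrix (grid x recruited channels) of class `"latency_cpd"`
#'   with attributes `grid_ms` and `samples` (the underlying latency lists).
#' @export
latency_cpd <- function(seqs, map, grid_ms = seq(0, 100, by = 5)) {
  if (!length(seqs)) stop("no sequences")
  samp <- latency_samples(seqs, map)
  samp <- samp[lengths(samp) > 0L]
  cpd <- vapply(samp, function(lat) stats::ecdf(lat)(grid_ms),
                numeric(length(grid_ms)))
  cpd <- matrix(cpd, nrow = length(grid_ms),
                dimnames = list(grid_ms, names(samp)))
  structure(cpd, grid_ms = grid_ms, samples = samp,
            class = c("latency_cpd", "matrix"))
}

#' Sequence frequency
#'
#' Number of multichannel spike sequences per analysed minute of EEG.
#'
#' @param seqs list of sequences (or an integer count).
#' @param analyzed_minutes minutes of EEG analysed (> 0).
#' @return Sequences per minute.
#' @export
sequence_frequency <- function(seqs, analyzed_minutes) {
  stopifnot(analyzed_minutes > 0)
  n <- if (is.numeric(seqs) && length(seqs) == 1L) seqs else length(seqs)
  n / analyzed_minutes
}
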