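#' Construct a spike dataset
#'
#' A spike dataset mirrors the output of an automated spike detector: one
#' event per detected interictal spike, encoded as (channel index, peak time
#' in ms). Events are kept sorted by time with ties in ascending channel
#' order -- the detector's default ordering before spatial tie reordering.
#'
#' @param events data.frame with numeric columns `channel_id`, `time_ms`.
#' @param map an [electrode_map()]; every event channel must exist in it.
#' @param analyzed_minutes minutes of interictal EEG the events represent.
#' @param sampling_rate acquisition rate in Hz (default 200, i.e. a 5 ms
#'   time step; equal quantized peak times are "tied" spikes).
#' @param patient_id optional identifier.
#' @return A list of class `"spike_dataset"` with elements `events`,
#'   `analyzed_minutes`, `sampling_rate`, `patient_id`.
#' @export
spike_dataset <- function(events, map, analyzed_minutes,
                          sampling_rate = 200, patient_id = "") {
  stopifnot(inherits(map, "electrode_map"))
  events <- as.data.frame(events)
  if (!all(c("channel_id", "time_ms") %in% names(events)))
    stop("events need columns channel_id, time_ms")
  events$channel_id <- as.integer(events$channel_id)
  events$time_ms <- as.numeric(events$time_ms)
  if (nrow(events)) {
    bad <- !(events$channel_id %in% map$channel_id)
    if (any(bad))
      stop("unknown channel id(s) in rows: ",
           paste(utils::head(which(bad), 10L), collapse = ", "),
           " (channels ", paste(unique(events$channel_id[bad]), collapse = ", "), ")")
    if (any(events$time_ms < 0)) stop("negative event times")
    events <- events[order(events$time_ms, events$channel_id), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (!is.numeric(analyzed_minutes) || analyzed_minutes <= 0)
    stop("analyzed_minutes must be > 0")
  structure(list(events = events, analyzed_minutes = analyzed_minutes,
                 sampling_rate = sampling_rate, patient_id = patient_id),
            class = "spike_dataset")
}

#' Read detector output from CSV
#'
#' The detector emits a two-column stream: channel index and peak time (ms).
#' A header line is auto-detected (non-numeric first row). Events are sorted
#' by time, ties by ascending channel.
#'
#' @param path path to the detections file.
#' @param map an [electrode_map()].
#' @param analyzed_minutes minutes of EEG analysed; when `NULL`, taken as the
#'   event time span (rounded up to at least one minute).
#' @inheritParams spike_dataset
#' @return A [spike_dataset()].
#' @export
read_detections <- function(path, map, analyzed_minutes = NULL,
                            sampling_rate = 200, patient_id = "") {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    df <- data.frame(channel_id = integer(0), time_ms = numeric(0))
    return(spike_dataset(df, map,
                         if (is.null(analyzed_minutes)) 1 else analyzed_minutes,
                         sampling_rate, patient_id))
  }
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
  df <- utils::read.csv(path, header = has_header, comment.char = "#")
  if (nrow(df) && ncol(df) < 2L) stop("detections file needs two columns")
  if (!nrow(df)) {
    df <- data.frame(channel_id = integer(0), time_ms = numeric(0))
  } else {
    df <- data.frame(channel_id = df[[1L]], time_ms = df[[2L]])
  }
  if (is.null(analyzed_minutes))
    analyzed_minutes <- max(1, if (nrow(df)) diff(range(df$time_ms)) / 60000 else 1)
  spike_dataset(df, map, analyzed_minutes, sampling_rate, patient_id)
}

#' Segment the detector output and sample fixed-size segments
#'
#' Divides the time-sorted event stream into consecutive non-overlapping
#' segments of exactly `spikes_per_segment` spikes (an incomplete trailing
#' block is discarded), then randomly selects `min(n_segments, available)`
#' segments without replacement and concatenates them. This yields
#' consistent spike datasets (default 10 segments of 10,000 spikes, i.e.
#' 100,000 spikes per recording) amenable to cross-subject comparison;
#' segments are chosen without regard to time-of-day or physiological state.
#' `analyzed_minutes` is recomputed as the summed wall-clock span of the
#' selected segments.
#'
#' @param ds a [spike_dataset()].
#' @param map the [electrode_map()] of `ds`.
#' @param spikes_per_segment events per segment (default 10000).
#' @param n_segments segments to sample (default 10).
#' @param seed integer seed; selection is reproducible.
#' @return A [spike_dataset()] with attribute `segments_used`.
#' @export
segment_and_sample <- function(ds, map, spikes_per_segment = 10000L,
                               n_segments = 10L, seed = 1L) {
  stopifnot(inherits(ds, "spike_dataset"),
            spikes_per_segment >= 1L, n_segments >= 1L)
  n <- nrow(ds$events)
  n_blocks <- n %/% spikes_per_segment
  if (n_blocks == 0L)
    stop("no complete segment: ", n, " events < ", spikes_per_segment)
  set.seed(seed)
  take <- sort(sample.int(n_blocks, min(n_segments, n_blocks)))
  rows <- unlist(lapply(take, function(b)
    ((b - 1L) * spikes_per_segment + 1L):(b * spikes_per_segment)))
  span_min <- sum(vapply(take, function(b) {
    blk <- ds$events$time_ms[((b - 1L) * spikes_per_segment + 1L):(b * spikes_per_segment)]
    (max(blk) - min(blk)) / 60000
  }, 0))
  out <- spike_dataset(ds$events[rows, , drop = FALSE], map,
                       analyzed_minutes = max(span_min, .Machine$double.eps),
                       sampling_rate = ds$sampling_rate,
                       patient_id = ds$patient_id)
  attr(out, "segments_used") <- length(take)
  out
}

#' Spike frequency map
#'
#' Per-channel spike frequency: each channel's spike count divided by the
#' total analysed EEG duration in minutes. This is the traditional
#' spatial-density view of interictal spiking; its spatial organisation is
#' later summarised by the Moran Index.
#'
#' @param ds a [spike_dataset()].
#' @param map an [electrode_map()].
#' @return A data.frame of class `"frequency_map"` with columns
#'   `channel_id`, `f` (spikes/min), and attributes `f_avg` (mean over all
#'   channels) and `spike_density` (total spikes / (channels x minutes)).
#' @export
spike_frequency_map <- function(ds, map) {
  stopifnot(inherits(ds, "spike_dataset"), inherits(map, "electrode_map"))
  counts <- table(factor(ds$events$channel_id, levels = map$channel_id))
  f <- as.numeric(counts) / ds$analyzed_minutes
  fm <- data.frame(channel_id = map$channel_id, f = f)
  attr(fm, "f_avg") <- mean(f)
  attr(fm, "spike_density") <-
    nrow(ds$events) / (nrow(map) * ds$analyzed_minutes)
  attr(fm, "analyzed_minutes") <- ds$analyzed_minutes
  class(fm) <- c("frequency_map", "data.frame")
  fm
}

#' Lorenz curve and Gini coefficient of the spike distribution
#'
#' Summarises how unevenly spikes are distributed across channels. The
#' Lorenz curve plots the cumulative spike fraction against the cumulative
#' channel fraction (channels sorted by ascending frequency); the Gini
#' coefficient is the population form
#' `G = sum_i sum_j |F_i - F_j| / (2 N^2 mean(F))`, 0 for a perfectly
#' uniform distribution and approaching 1 as spikes concentrate on few
#' channels.
#'
#' @param fm a [spike_frequency_map()] result (or a bare numeric vector of
#'   per-channel frequencies).
#' @return A list of class `"lorenz_summary"`: `points` (data.frame
#'   `channel_frac`, `spike_frac` including the (0,0) origin) and `gini`.
#' @export
lorenz_gini <- function(fm) {
  f <- if (is.data.frame(fm)) fm$f else as.numeric(fm)
  if (!length(f) || all(f == 0))
    stop("all channel frequencies are zero; concentration is undefined")
  n <- length(f)
  fs <- sort(f)
  pts <- data.frame(channel_frac = c(0, seq_len(n) / n),
                    spike_frac = c(0, cumsum(fs) / sum(fs)))
  gini <- sum(abs(outer(f, f, "-"))) / (2 * n^2 * mean(f))
  structure(list(points = pts, gini = gini), class = "lorenz_summary")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("Spike dataset:", nrow(x$events), "events over",
      round(x$analyzed_minutes, 2), "min",
      if (nzchar(x$patient_id)) paste0("(", x$patient_id, ")") else "", "\n")
  invisible(x)
}
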