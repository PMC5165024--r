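#' Cleaning configuration
#'
#' Thresholds of the trajectory "cleaning" procedure that removes
#' artifact-driven outlier sequences. Sequences are compared as point sets
#' of (x, y, latency-from-leader) triples; a test point matches a reference
#' point when it lies within `ss_thresh` mm (Euclidean, in the plane) and
#' within `tt_thresh` ms in latency. The degree distribution of the
#' similarity matrix is split into Low/Mid/High clusters by 1-D k-means
#' with a fixed cluster count of k = 3.
#'
#' @param ss_thresh spatial match threshold, mm (default 15).
#' @param tt_thresh temporal match threshold, ms (default 15).
#' @param seed integer seed for k-means.
#' @param restarts k-means restarts; the best fit is kept (default 10).
#' @param degree `"both"` (default): degree = row-sum + column-sum of the
#'   non-symmetric similarity matrix, diagonal excluded; `"row"`: row-sum
#'   only.
#' @return A list of class `"cleaning_config"` (cluster count `k` is fixed
#'   at 3).
#' @export
cleaning_config <- function(ss_thresh = 15, tt_thresh = 15, seed = 1L,
                            restarts = 10L, degree = c("both", "row")) {
  stopifnot(ss_thresh > 0, tt_thresh > 0, restarts >= 1L)
  structure(list(ss_thresh = ss_thresh, tt_thresh = tt_thresh, k = 3L,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 degree = match.arg(degree)),
            class = "cleaning_config")
}

# (x, y, latency) point representation of a sequence
sequence_points <- function(s, map) {
  i <- match(s$channel_id, map$channel_id)
  cbind(x = map$x_mm[i], y = map$y_mm[i], lat = s$latency_ms)
}

#' Spatiotemporal similarity of two spike sequences
#'
#' For each point of the reference sequence, candidate matches are the test
#' points within `ss_thresh` mm and `tt_thresh` ms of latency; the
#' candidate at the smallest spatial distance `d_match` scores
#' `sim_point = 1 - d_match / ss_thresh` (0 when there is no candidate).
#' The similarity score is the mean of `sim_point` over the reference
#' points, so it lies in [0, 1], equals 1 for a sequence against itself,
#' and is not symmetric in general (a short reference can be fully
#' contained in a longer test but not vice versa).
#'
#' @param ref,test `"spike_sequence"` objects (non-empty).
#' @param cfg a [cleaning_config()].
#' @param map an [electrode_map()].
#' @return Scalar similarity in [0, 1].
#' @export
sequence_similarity <- function(ref, test, cfg = cleaning_config(), map) {
  if (!nrow(ref) || !nrow(test)) stop("empty sequence")
  pr <- sequence_points(ref, map)
  pt <- sequence_points(test, map)
  dx <- outer(pr[, "x"], pt[, "x"], "-")
  dy <- outer(pr[, "y"], pt[, "y"], "-")
  d <- sqrt(dx^2 + dy^2)
  dlat <- abs(outer(pr[, "lat"], pt[, "lat"], "-"))
  d[d > cfg$ss_thresh | dlat > cfg$tt_thresh] <- NA
  d_match <- apply(d, 1L, function(row) if (all(is.na(row))) NA else min(row, na.rm = TRUE))
  sim <- ifelse(is.na(d_match), 0, 1 - d_match / cfg$ss_thresh)
  mean(sim)
}

#' Sequence-by-sequence similarity matrix
#'
#' `S[i, j]` is the similarity score with sequence *i* as reference and *j*
#' as test, computed for every ordered pair. The matrix is non-symmetric;
#' its diagonal is 1 by construction.
#'
#' @param seqs list of at least two `"spike_sequence"` objects.
#' @param cfg a [cleaning_config()].
#' @param map an [electrode_map()].
#' @return A numeric matrix of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(seqs, cfg = cleaning_config(), map) {
  m <- length(seqs)
  if (m < 2L) stop("need at least 2 sequences")
  pts <- lapply(seqs, sequence_points, map = map)
  S <- matrix(1, m, m)
  for (i in seq_len(m)) {
    pr <- pts[[i]]
    for (j in seq_len(m)) {
      if (i == j) next
      pt <- pts[[j]]
      d <- sqrt(outer(pr[, "x"], pt[, "x"], "-")^2 +
                  outer(pr[, "y"], pt[, "y"], "-")^2)
      d[d > cfg$ss_thresh |
          abs(outer(pr[, "lat"], pt[, "lat"], "-")) > cfg$tt_thresh] <- NA
      d_match <- suppressWarnings(apply(d, 1L, min, na.rm = TRUE))
      S[i, j] <- mean(ifelse(is.finite(d_match), 1 - d_match / cfg$ss_thresh, 0))
    }
  }
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Degree-based outlier removal
#'
#' Artifact periods (motor movement, ambient electrical noise) produce
#' false sequence detections that share minimal spatiotemporal overlap with
#' genuine discharges. Each sequence's degree centrality,
#' `degree_i = sum_{j != i} (S[i,j] + S[j,i])` by default, is clustered by
#' 1-D k-means (k = 3, seeded, multi-restart, clusters relabelled by
#' ascending centroid) into "Low", "Mid", and "High" degree classes; all
#' Low-Degree sequences are eliminated as suspected outliers.
#'
#' With fewer than 10 sequences or fewer than 3 distinct degree values the
#' clustering is not meaningful: cleaning is skipped with a warning and all
#' sequences are kept.
#'
#' @param seqs the sequences `S` was built from.
#' @param S a [similarity_matrix()].
#' @param cfg a [cleaning_config()].
#' @return A list of class `"degree_classification"`: `kept_sequences`,
#'   and a data.frame `classification` (`seq_id`, `degree`, `label`,
#'   `kept`), plus `centroids` (ascending, `NA` when skipped) and `skipped`.
#' @export
classify_and_clean <- function(seqs, S, cfg = cleaning_config()) {
  m <- length(seqs)
  stopifnot(is.matrix(S), nrow(S) == m, ncol(S) == m)
  degree <- switch(cfg$degree,
                   both = rowSums(S) + colSums(S) - 2 * diag(S),
                   row  = rowSums(S) - diag(S))
  skip <- m < 10L || length(unique(degree)) < 3L
  if (skip) {
    warning("too few sequences or degenerate degrees; cleaning skipped")
    cls <- data.frame(seq_id = seq_len(m), degree = degree,
                      label = "Mid", kept = TRUE)
    return(structure(list(kept_sequences = seqs, classification = cls,
                          centroids = rep(NA_real_, 3L), skipped = TRUE),
                     class = "degree_classification"))
  }
  set.seed(cfg$seed)
  km <- stats::kmeans(degree, centers = cfg$k, nstart = cfg$restarts)
  ord <- order(km$centers)                       # ascending: Low, Mid, High
  lab <- c("Low", "Mid", "High")[match(km$cluster, ord)]
  kept <- lab != "Low"
  cls <- data.frame(seq_id = seq_len(m), degree = degree,
                    label = lab, kept = kept)
  structure(list(kept_sequences = seqs[kept], classification = cls,
                 centroids = sort(as.numeric(km$centers)), skipped = FALSE),
            class = "degree_classification")
}
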