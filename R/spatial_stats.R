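#' Moran Index of a per-channel scalar field
#'
#' Spatial autocorrelation of a map such as spike frequency or mean
#' recruitment latency:
#' \deqn{I = \frac{N}{\sum_i\sum_j w_{ij}} \cdot
#'   \frac{\sum_i\sum_j w_{ij}(F_i-\bar F)(F_j-\bar F)}{\sum_i (F_i-\bar F)^2}}
#' with inverse-distance weights `w_ij = 1/d_ij` for neighbours within the
#' weight radius (see [spatial_weights()]). `I` is near +1 when neighbouring
#' channels carry similar values (spatially organised maps), near -1 for
#' perfect neighbour anti-correlation, and near `-1/(N-1)` (approximately 0
#' for large N) when there is no spatial pattern.
#'
#' The computation is restricted to channels present in both the field and
#' the weights (e.g. recruitment maps exclude never-recruited channels);
#' `N` and the field mean are recomputed on that subset.
#'
#' @param field named numeric vector (names = channel ids), or a
#'   `"frequency_map"` / `"latency_map"` data.frame.
#' @param weights a [spatial_weights()] object.
#' @return A list of class `"moran_result"`: `I`, `n_used`, `radius_mm`.
#' @export
moran_index <- function(field, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  f <- field_values(field)
  use <- intersect(names(f)[is.finite(f)], as.character(weights$channel_id))
  if (length(use) < 2L) stop("need at least 2 channels with values")
  f <- f[use]
  w <- weights$w[use, use, drop = FALSE]
  s0 <- sum(w)
  if (s0 == 0) stop("no neighbour pairs within the weight radius")
  z <- f - mean(f)
  denom <- sum(z^2)
  if (denom == 0) stop("field has zero variance; Moran Index undefined")
  I <- (length(f) / s0) * sum(w * outer(z, z)) / denom
  structure(list(I = I, n_used = length(f), radius_mm = weights$radius_mm),
            class = "moran_result")
}

field_values <- function(field) {
  if (inherits(field, "frequency_map"))
    return(stats::setNames(field$f, field$channel_id))
  if (inherits(field, "latency_map"))
    return(stats::setNames(field$mean_latency_ms, field$channel_id))
  if (is.numeric(field)) {
    if (is.null(names(field))) stop("bare field vectors must be named by channel id")
    return(field)
  }
  stop("unsupported field type")
}

#' Permutation null for the Moran Index
#'
#' Recomputes `I` under seeded random relabelings of the field values
#' across channels, giving the no-spatial-pattern baseline. The classical
#' expectation of `I` under exchangeability is `-1/(N-1)`.
#'
#' @inheritParams moran_index
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A list: `mean`, `sd`, `p` (one-sided upper empirical p-value,
#'   `(1 + #\{I* >= I\}) / (n_perm + 1)`), `observed`, `n_perm`, `draws`.
#' @export
moran_permutation_null <- function(field, weights, n_perm = 999L, seed = 1L) {
  obs <- moran_index(field, weights)
  f <- field_values(field)
  f <- f[intersect(names(f)[is.finite(f)], as.character(weights$channel_id))]
  set.seed(seed)
  draws <- vapply(seq_len(n_perm), function(i) {
    fp <- stats::setNames(sample(unname(f)), names(f))
    moran_index(fp, weights)$I
  }, 0)
  list(mean = mean(draws), sd = stats::sd(draws),
       p = (1 + sum(draws >= obs$I)) / (n_perm + 1),
       observed = obs$I, n_perm = n_perm, draws = draws)
}

#' Wilcoxon rank-sum comparison of two outcome groups
#'
#' Two-sided rank-sum test with midranks for ties. For small samples (both
#' groups at most `exact_max`) the null distribution is obtained by full
#' enumeration of all group assignments and the p-value is twice the
#' smaller tail (capped at 1); otherwise a normal approximation with tie
#' correction and continuity correction is used. A Bonferroni-adjusted
#' significance threshold `alpha / n_comparisons` accompanies the result
#' (two map comparisons by default, so 0.05 / 2 = 0.025).
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @param n_comparisons Bonferroni divisor (default 2).
#' @param alpha family-wise level (default 0.05).
#' @param exact_max maximum per-group size for exact enumeration
#'   (default 10).
#' @return A list of class `"group_comparison"`: `statistic` (rank sum of
#'   group a), `p`, `exact`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `alpha_adjusted`, `significant`.
#' @export
group_compare <- function(values_a, values_b, n_comparisons = 2L,
                          alpha = 0.05, exact_max = 10L) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  x <- c(a, b)
  n1 <- length(a); n <- length(x)
  r <- rank(x)                                  # midranks
  w <- sum(r[seq_len(n1)])
  if (stats::sd(x) == 0) {
    p <- 1
    exact <- TRUE
  } else if (n1 <= exact_max && (n - n1) <= exact_max) {
    cmb <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[cmb], nrow = n1))
    p <- min(1, 2 * min(mean(w_all <= w), mean(w_all >= w)))
    exact <- TRUE
  } else {
    n2 <- n - n1
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  out <- list(statistic = w, p = p, exact = exact,
              mean_a = mean(a), sd_a = stats::sd(a),
              mean_b = mean(b), sd_b = stats::sd(b),
              alpha_adjusted = alpha / n_comparisons,
              significant = p < alpha / n_comparisons)
  class(out) <- "group_comparison"
  out
}

#' Load the packaged 18-patient cohort tables
#'
#' Per-patient clinical characteristics and spike statistics for the
#' 18-patient pediatric intracranial-EEG surgical cohort the methodology
#' was developed on (9 seizure-free, Engel class 1; 9 seizure-persistent,
#' Engel class >= 2), shipped as plain-text fixtures.
#'
#' @return A list with data.frames `clinical` (patient, age, gender, MRI,
#'   Engel class, implant, electrodes, SOZ percentage, analysed minutes,
#'   spikes) and `spike_stats` (spike density, frequency-map Moran Index,
#'   total sequences, sequence frequency, latency-map Moran Index), plus
#'   `group` (named "Sz-Free"/"Sz-Persist" factor).
#' @export
load_cohort_tables <- function() {
  clinical <- utils::read.csv(
    system.file("extdata", "cohort_clinical.csv", package = "spikeprop"),
    comment.char = "#", stringsAsFactors = FALSE)
  spike_stats <- utils::read.csv(
    system.file("extdata", "cohort_spike_stats.csv", package = "spikeprop"),
    comment.char = "#", stringsAsFactors = FALSE)
  group <- factor(ifelse(clinical$engel == 1, "Sz-Free", "Sz-Persist"),
                  levels = c("Sz-Free", "Sz-Persist"))
  names(group) <- clinical$patient
  list(clinical = clinical, spike_stats = spike_stats, group = group)
}

#' Recompute cohort group summaries and derived cells
#'
#' From the packaged per-patient tables, recomputes every group summary row
#' (mean +/- SD per outcome group and Wilcoxon rank-sum p-value for age,
#' electrodes, SOZ percentage, analysed minutes, spike density, both Moran
#' Index columns, total sequences, and sequence frequency) together with
#' the derived per-patient cells (spike density = spikes / (electrodes x
#' minutes); sequence frequency = sequences / minutes). Derived cells whose
#' recomputed value differs from the printed one by more than half a unit
#' in the last printed digit -- after allowing for the rounding of the
#' printed analysed-minutes (known only to 0.005 min), which propagates a
#' relative uncertainty of `0.005 / minutes` into every quotient -- are
#' flagged rather than silently accepted.
#'
#' @param tables result of [load_cohort_tables()] (default: load them).
#' @return A list of class `"cohort_report"`: `summary` (one row per
#'   variable: group means/SDs and p), `derived` (per-patient recomputed
#'   cells with `flag`), `n_flagged`.
#' @export
reproduce_cohort_stats <- function(tables = load_cohort_tables()) {
  cl <- tables$clinical; st <- tables$spike_stats; grp <- tables$group
  if (nrow(cl) != nrow(st) || !all(cl$patient == st$patient))
    stop("malformed cohort fixture: clinical and spike tables disagree")
  vars <- list(
    age_years          = cl$age_years,
    electrodes         = cl$electrodes,
    soz_pct            = cl$soz_pct,
    analyzed_minutes   = cl$analyzed_minutes,
    spike_density      = st$spike_density,
    freq_moran         = st$freq_moran,
    total_sequences    = st$total_sequences,
    sequence_frequency = st$sequence_frequency,
    latency_moran      = st$latency_moran)
  rows <- lapply(names(vars), function(v) {
    gc <- group_compare(vars[[v]][grp == "Sz-Free"], vars[[v]][grp == "Sz-Persist"])
    data.frame(variable = v,
               mean_all = mean(vars[[v]]), sd_all = stats::sd(vars[[v]]),
               mean_szfree = gc$mean_a, sd_szfree = gc$sd_a,
               mean_szpersist = gc$mean_b, sd_szpersist = gc$sd_b,
               p = gc$p)
  })
  summary <- do.call(rbind, rows)
  # derived per-patient cells, checked against the printed values at their
  # printed precision (half a unit in the last digit)
  dens <- cl$spikes / (cl$electrodes * cl$analyzed_minutes)
  sf <- st$total_sequences / cl$analyzed_minutes
  tol_of <- function(printed, minutes)
    0.5 * 10^(-vapply(printed, decimals, 0L)) +
      abs(printed) * 0.005 / minutes + 1e-12
  derived <- rbind(
    data.frame(patient = cl$patient, quantity = "spike_density",
               printed = st$spike_density, recomputed = dens,
               flag = abs(dens - st$spike_density) >
                 tol_of(st$spike_density, cl$analyzed_minutes)),
    data.frame(patient = cl$patient, quantity = "sequence_frequency",
               printed = st$sequence_frequency, recomputed = sf,
               flag = abs(sf - st$sequence_frequency) >
                 tol_of(st$sequence_frequency, cl$analyzed_minutes)))
  structure(list(summary = summary, derived = derived,
                 n_flagged = sum(derived$flag)),
            class = "cohort_report")
}

# number of decimal places in a printed value (up to 6)
decimals <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot < 0) 0L else nchar(s) - dot
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran Index I =", format(x$I, digits = 4), "on", x$n_used,
      "channels (radius", x$radius_mm, "mm)\n")
  invisible(x)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group a: %.3f +/- %.3f | group b: %.3f +/- %.3f | W = %g, p = %.4g (%s)%s\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$statistic, x$p,
              if (x$exact) "exact" else "normal approx.",
              if (x$significant) " *" else ""))
  invisible(x)
}
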