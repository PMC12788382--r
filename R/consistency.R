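# Cross-cohort consistency statistics for per-subject cluster counts: the
# headline summaries of the multi-rate comparison.

#' Cohort-wide cluster-count distance for one subject
#'
#' Sum of the three absolute pairwise differences between a subject's
#' cluster counts at the three TRs:
#' `|k_low - k_med| + |k_med - k_high| + |k_high - k_low|`,
#' which always equals `2 * (max - min)`.
#'
#' @param counts Exactly three positive integer cluster counts.
#' @return Nonnegative integer.
#' @export
#' @examples
#' cohort_distance(c(2, 3, 5))  # 6
cohort_distance <- function(counts) {
  if (length(counts) != 3L)
    stop_param("cohort_distance expects exactly three counts")
  counts <- vapply(counts, check_count, integer(1), name = "counts", min = 1L)
  as.integer(abs(counts[1] - counts[2]) + abs(counts[2] - counts[3]) +
               abs(counts[3] - counts[1]))
}

#' Pairwise cluster-count distances between cohorts
#'
#' @param counts Named vector (or list) of a subject's cluster counts per
#'   cohort, at least 2 cohorts.
#' @return Named integer vector, one entry per unordered cohort pair
#'   (`"a|b"`).
#' @export
#' @examples
#' pairwise_distances(c(tr645 = 2, tr1400 = 3, tr2500 = 5))
pairwise_distances <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) < 2L) stop_param("need at least 2 cohorts")
  vals <- vapply(counts, check_count, integer(1), name = "counts", min = 1L)
  tags <- names(counts) %||% as.character(seq_along(counts))
  pairs <- utils::combn(seq_along(vals), 2)
  out <- apply(pairs, 2, function(p) abs(vals[p[1]] - vals[p[2]]))
  names(out) <- apply(pairs, 2, function(p) paste(tags[p[1]], tags[p[2]],
                                                  sep = "|"))
  out
}

#' Percentage of subjects within a distance threshold
#'
#' @param distances Nonempty vector of per-subject (or per-pair)
#'   nonnegative integer distances.
#' @param threshold Nonnegative integer.
#' @return Percentage in `[0, 100]`, rounded (half-even) to one decimal.
#' @export
#' @examples
#' proportion_within(c(0, 1, 4), 1)  # 66.7
proportion_within <- function(distances, threshold) {
  if (length(distances) == 0L) stop_param("empty distance list")
  if (anyNA(distances)) stop_param("distances contain NA")
  threshold <- check_count(threshold, "threshold", min = 0L)
  round(100 * mean(distances <= threshold), 1)
}

#' Distribution of chosen cluster counts within a group
#'
#' Histogram (as percentages of subjects) of the chosen `k` over a fixed
#' axis `k = 1..16`, plus the modal count.
#'
#' @param ks Nonempty vector of per-subject chosen cluster counts.
#' @param group Optional group tag stored on the result.
#' @param k_range Histogram support (default `1:16`).
#' @return List with `histogram` (named percentage vector over `k_range`),
#'   `modal_k`, `modal_pct`, `n`, `group`.
#' @export
#' @examples
#' cluster_count_distribution(c(2, 2, 3, 5))
cluster_count_distribution <- function(ks, group = NULL, k_range = 1:16) {
  if (length(ks) == 0L) stop_param("empty cluster-count list")
  ks <- vapply(ks, check_count, integer(1), name = "ks", min = 1L)
  counts <- vapply(k_range, function(k) sum(ks == k), integer(1))
  if (sum(counts) != length(ks))
    warning("some cluster counts fall outside k_range")
  pct <- 100 * counts / length(ks)
  names(pct) <- as.character(k_range)
  modal <- which.max(pct)
  list(histogram = pct,
       modal_k = k_range[modal],
       modal_pct = unname(pct[modal]),
       n = length(ks),
       group = group)
}
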