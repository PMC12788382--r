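# 2-D embedding of a subject's T x T temporal distance matrix and selection
# of the number of temporal clusters by silhouette-maximizing k-means.

#' Metric MDS embedding of a distance matrix
#'
#' Least-squares metric MDS: SMACOF stress majorization started from the
#' (deterministic) classical-MDS configuration. With a deterministic
#' initialization the embedding — and hence the downstream cluster count —
#' does not depend on the random seed; `seed` is retained on the result for
#' provenance.
#'
#' @param dist Symmetric nonnegative `T x T` matrix with zero diagonal
#'   (e.g. a [pairwise_wd_matrix()] result).
#' @param n_components Embedding dimension (default 2).
#' @param seed Integer recorded on the result.
#' @param max_iter,tol SMACOF iteration cap and relative stress-change
#'   stopping tolerance.
#' @return A `tempoph_embedding`: list with `coords` (`T x n_components`),
#'   `stress` (normalized stress-1) and `seed`.
#' @export
#' @examples
#' D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
#' emb <- mds_embed(D)
#' dist(emb$coords)  # recovers 3, 4, 5
mds_embed <- function(dist, n_components = 2, seed = 1L,
                      max_iter = 300, tol = 1e-12) {
  D <- as.matrix(unclass(dist))
  Tn <- nrow(D)
  if (ncol(D) != Tn) stop_param("distance matrix must be square")
  if (anyNA(D) || any(!is.finite(D)))
    stop_param("distance matrix must be finite")
  if (max_asymmetry(D) > 1e-8)
    stop_param("distance matrix must be symmetric")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  n_components <- check_count(n_components, "n_components", min = 1L)
  if (all(D == 0)) {
    return(structure(list(coords = matrix(0, Tn, n_components),
                          stress = 0, seed = seed),
                     class = "tempoph_embedding"))
  }
  # Classical MDS initialization; pad with zero columns if the centered
  # Gram matrix has fewer positive eigenvalues than requested.
  X <- suppressWarnings(cmdscale(D, k = min(n_components, Tn - 1L)))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (ncol(X) < n_components)
    X <- cbind(X, matrix(0, Tn, n_components - ncol(X)))
  denom <- sum(D^2) / 2
  stress_of <- function(d) sum((D - d)^2) / 2
  d <- as.matrix(dist(X))
  s_prev <- stress_of(d)
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / Tn
    d <- as.matrix(dist(X))
    s <- stress_of(d)
    if (abs(s_prev - s) <= tol * max(s_prev, .Machine$double.eps)) break
    s_prev <- s
  }
  structure(list(coords = unname(X),
                 stress = sqrt(stress_of(d) / denom),
                 seed = seed),
            class = "tempoph_embedding")
}

#' Mean silhouette score
#'
#' Mean over points of `(b - a) / max(a, b)` with Euclidean distances,
#' where `a` is the mean distance to the point's own cluster (excluding
#' itself) and `b` the smallest mean distance to another cluster. Lone
#' points of singleton clusters contribute 0, and `0/0` (all relevant
#' distances zero) is taken as 0.
#'
#' @param points `N x d` coordinate matrix, `N >= 3`.
#' @param labels Length-`N` cluster labels with at least 2 distinct values
#'   and no empty cluster.
#' @return A number in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < 3L) stop_param("need at least 3 points")
  if (length(labels) != N) stop_param("labels must have length N")
  labs <- unique(labels)
  if (length(labs) < 2L)
    stop_param("silhouette is undefined for a single cluster")
  d <- as.matrix(dist(points))
  s <- vapply(seq_len(N), function(i) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1L) return(0)
    a <- sum(d[i, own]) / (n_own - 1L)
    b <- min(vapply(labs[labs != labels[i]], function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    m <- max(a, b)
    if (m == 0) 0 else (b - a) / m
  }, numeric(1))
  mean(s)
}

#' Select the number of clusters by silhouette-maximizing k-means
#'
#' Runs k-means for every candidate `k` in `[k_min, min(k_max, T - 1)]`
#' (with `restarts` deterministic restarts seeded from per-k substreams of
#' `seed`, initial centers drawn from the distinct rows) and returns the
#' labels of the silhouette-maximizing `k`; ties break toward the smaller
#' `k`. Candidates exceeding the number of distinct rows are skipped.
#'
#' @param points `T x d` coordinate matrix (`T >= k_min + 1`).
#' @param k_min,k_max Candidate range (defaults 2 and 16).
#' @param seed Integer seed.
#' @param restarts k-means restarts per candidate (default 10).
#' @param iter_max k-means iteration cap (default 300).
#' @param pipeline Tag recorded on the result.
#' @return A `tempoph_clusters`: list with `labels` (0-based, length `T`),
#'   `chosen_k`, `silhouette_by_k` (named over the candidate range, `NA`
#'   where skipped), `pipeline`, `seed`.
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
#' select_k(pts, seed = 1)$chosen_k  # 2
select_k <- function(points, k_min = 2, k_max = 16, seed = 1L,
                     restarts = 10, iter_max = 300, pipeline = "custom") {
  points <- as.matrix(points)
  Tn <- nrow(points)
  if (Tn < 3L) stop_param("need at least 3 points to cluster")
  k_min <- check_count(k_min, "k_min", min = 2L)
  k_max <- check_count(k_max, "k_max", min = k_min)
  if (Tn < k_min + 1L)
    stop_param("need at least k_min + 1 = %d points", k_min + 1L)
  ux <- unique(points)
  m <- nrow(ux)
  if (m == 1L)
    stop_param("all points are identical; silhouette is undefined for every k")
  if (k_max > Tn - 1L) {
    warning(sprintf("k_max truncated from %d to T - 1 = %d", k_max, Tn - 1L))
    k_max <- Tn - 1L
  }
  candidates <- k_min:k_max
  sil <- stats::setNames(rep(NA_real_, length(candidates)),
                         as.character(candidates))
  best_labels <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    k <- candidates[ci]
    if (k > m) next
    best <- NULL
    with_seed(seed_substream(seed, paste0("k", k)), {
      for (r in seq_len(restarts)) {
        centers <- ux[sample.int(m, k), , drop = FALSE]
        km <- tryCatch(
          suppressWarnings(kmeans(points, centers = centers,
                                  iter.max = iter_max)),
          error = function(e) NULL)
        if (is.null(km)) next
        if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
          best <- km
      }
    })
    if (is.null(best)) next
    sil[ci] <- silhouette_mean(points, best$cluster)
    best_labels[[ci]] <- as.integer(best$cluster) - 1L
  }
  if (all(is.na(sil)))
    stop_param("degenerate input: no candidate k admits a valid clustering")
  pick <- which.max(sil)  # first maximum = smallest k on ties
  structure(list(labels = best_labels[[pick]],
                 chosen_k = candidates[pick],
                 silhouette_by_k = sil,
                 pipeline = pipeline,
                 seed = seed),
            class = "tempoph_clusters")
}
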