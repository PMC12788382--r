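# The three non-topological comparison pipelines: direct clustering of
# flattened FCNs, PCA-reduced clustering, and Euclidean-distance dFCN
# clustering through MDS. They share select_k / mds_embed with the TDA
# pipeline so that only the representation differs.

#' Flatten an FCN sequence to a T x R^2 matrix
#'
#' Row `t` is the row-major flattening of FCN `t`, full matrix including
#' the diagonal and both triangles (so `R = 113` gives rows of length
#' 12,769).
#'
#' @param fcn A `tempoph_fcn`.
#' @return A `tempoph_flat`: list with `values` (`T x R^2`) and `source`.
#' @export
flatten_sequence <- function(fcn) {
  stopifnot(inherits(fcn, "tempoph_fcn"))
  d <- dim(fcn$matrices)
  Tn <- d[1]; R <- d[2]
  values <- t(vapply(seq_len(Tn), function(t) {
    as.vector(t(fcn$matrices[t, , ]))  # row-major
  }, numeric(R * R)))
  structure(list(values = values, source = "fcn"), class = "tempoph_flat")
}

#' Direct clustering of flattened FCNs
#'
#' Applies [select_k()] to the raw `T x R^2` flattened correlation matrices
#' with the silhouette computed in the full R^2-dimensional space — no
#' dimensionality reduction, by design of the baseline.
#'
#' @param fcn A `tempoph_fcn`.
#' @param k_min,k_max,seed As in [select_k()].
#' @return A `tempoph_clusters` with pipeline tag `"direct"`.
#' @export
direct_cluster <- function(fcn, k_min = 2, k_max = 16, seed = 1L) {
  flat <- flatten_sequence(fcn)
  select_k(flat$values, k_min = k_min, k_max = k_max, seed = seed,
           pipeline = "direct")
}

#' Project flattened FCNs onto the top principal components
#'
#' Column-centers the data and projects onto the leading right singular
#' directions. Sign convention: each component's largest-magnitude loading
#' is positive, making the scores deterministic.
#'
#' @param flat A [flatten_sequence()] result.
#' @param n_components Number of components (default 2).
#' @return `T x n_components` score matrix.
#' @export
pca_reduce <- function(flat, n_components = 2) {
  stopifnot(inherits(flat, "tempoph_flat"))
  n_components <- check_count(n_components, "n_components", min = 1L)
  X <- scale(flat$values, center = TRUE, scale = FALSE)
  if (max(abs(X)) == 0)
    stop_param("degenerate input: data has zero variance")
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  sweep(scores, 2, flip, `*`)
}

#' PCA-reduced clustering pipeline
#'
#' Flatten, reduce to 2 principal components, then [select_k()].
#'
#' @inheritParams direct_cluster
#' @return A `tempoph_clusters` with pipeline tag `"pca"`.
#' @export
pca_cluster <- function(fcn, k_min = 2, k_max = 16, seed = 1L) {
  scores <- pca_reduce(flatten_sequence(fcn), n_components = 2)
  select_k(scores, k_min = k_min, k_max = k_max, seed = seed,
           pipeline = "pca")
}

#' Frobenius (entrywise Euclidean) distance matrix between timepoints
#'
#' `D[t1, t2] = sqrt(sum_mn (a_mn(t1) - a_mn(t2))^2)` over the full
#' adjacency matrices — the traditional dFCN temporal distance, identical
#' to the Euclidean distance between the flattened rows.
#'
#' @param fcn A `tempoph_fcn` with `T >= 2`.
#' @param cohort,subject_id Optional tags stored on the result.
#' @return A `tempoph_sdm` (`T x T`, symmetric, zero diagonal).
#' @export
dfcn_distance_matrix <- function(fcn, cohort = NULL, subject_id = NULL) {
  stopifnot(inherits(fcn, "tempoph_fcn"))
  d <- dim(fcn$matrices)
  if (d[1] < 2L) stop_param("need at least 2 timepoints")
  flat <- matrix(fcn$matrices, nrow = d[1])  # T x R^2, column-major slices
  G <- tcrossprod(flat)
  sq <- diag(G)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  structure(D, class = c("tempoph_sdm", "matrix"),
            cohort = cohort, subject_id = subject_id)
}

#' Traditional dFCN clustering pipeline
#'
#' Frobenius temporal distance matrix, 2-D metric MDS, then [select_k()] —
#' the same embedding/selection machinery as the TDA pipeline with the
#' Wasserstein distance replaced by the entrywise Euclidean one.
#'
#' @inheritParams direct_cluster
#' @return A `tempoph_clusters` with pipeline tag `"dfcn"`.
#' @export
traditional_cluster <- function(fcn, k_min = 2, k_max = 16, seed = 1L) {
  D <- dfcn_distance_matrix(fcn)
  emb <- mds_embed(D, n_components = 2, seed = seed)
  select_k(emb$coords, k_min = k_min, k_max = k_max, seed = seed,
           pipeline = "dfcn")
}
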