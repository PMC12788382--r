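# 0-dimensional persistent homology of Vietoris-Rips filtrations and exact
# Wasserstein distances between the resulting diagrams.
#
# For a finite metric (distance matrix) the H0 barcode has a closed
# combinatorial form: all components are born at filtration value 0, and the
# finite death values are exactly the edge weights of a minimum spanning
# tree of the complete weighted graph (each MST edge merges two components).
# One component never dies. This makes H0 exact in O(R^2 log R) without any
# general simplicial reduction.

#' Construct a persistence diagram object
#'
#' @param births,deaths Numeric vectors of equal length; `deaths` may
#'   contain `Inf`. `births[i] <= deaths[i]` is required.
#' @return A `tempoph_diagram`: a 2-column matrix `(birth, death)` with
#'   attribute `dimension = 0`.
#' @export
persistence_diagram <- function(births, deaths) {
  stopifnot(length(births) == length(deaths))
  if (any(is.na(births)) || any(is.na(deaths)))
    stop_param("diagram intervals contain NA")
  if (any(births > deaths))
    stop_param("every interval needs birth <= death")
  m <- cbind(birth = as.double(births), death = as.double(deaths))
  structure(m, class = "tempoph_diagram", dimension = 0L)
}

#' H0 persistence diagram of a Vietoris-Rips filtration
#'
#' Computes the 0-dimensional persistence diagram of the VR filtration of a
#' finite metric given by a symmetric distance matrix with zero diagonal.
#' All `R` points enter at filtration value 0; the `R - 1` finite deaths are
#' the minimum-spanning-tree edge weights (Kruskal with union-find, ties
#' broken by lexicographic edge index); exactly one interval is infinite.
#'
#' @param dist Symmetric `R x R` matrix of nonnegative finite distances
#'   (asymmetry tolerance `1e-9`).
#' @return A [persistence_diagram()] with `R` intervals, finite deaths
#'   sorted ascending and the infinite interval last.
#' @export
#' @examples
#' compute_h0_diagram(matrix(c(0, 0.5, 0.5, 0), 2, 2))
compute_h0_diagram <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 1L || ncol(dist) != n)
    stop_param("distance matrix must be square")
  if (anyNA(dist) || any(!is.finite(dist)))
    stop_param("distance matrix must be finite")
  if (any(dist < -1e-12))
    stop_param("distance matrix must be nonnegative")
  if (n > 1L && max_asymmetry(dist) > 1e-9)
    stop_param("distance matrix must be symmetric (tolerance 1e-9)")
  if (n == 1L)
    return(persistence_diagram(0, Inf))
  idx <- which(upper.tri(dist), arr.ind = TRUE)
  w <- dist[idx]
  ord <- order(w, idx[, 1], idx[, 2])  # ties: lexicographic edge index
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  deaths <- numeric(0)
  for (e in ord) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      deaths <- c(deaths, w[e])
      if (length(deaths) == n - 1L) break
    }
  }
  persistence_diagram(rep(0, n), c(sort(deaths), Inf))
}

internal_norm_code <- function(internal) {
  switch(match.arg(internal, c("Linf", "L2")), Linf = 0L, L2 = 1L)
}

finite_part <- function(diagram) {
  m <- unclass(diagram)
  m[is.finite(m[, 2]), , drop = FALSE]
}

#' Wasserstein distance between persistence diagrams
#'
#' Exact q-Wasserstein distance: the minimum over partial matchings of
#' `(sum cost^q)^(1/q)`, where matched points pay the internal-norm distance
#' and unmatched points pay the distance to their diagonal projection.
#' Solved as an assignment problem on the augmented cost matrix.
#'
#' By default the single infinite interval each H0 diagram carries is
#' removed before matching (`finite_only = TRUE`). With
#' `finite_only = FALSE`, infinite intervals are matched to each other by
#' absolute birth difference; diagrams with different numbers of infinite
#' intervals are then at distance `Inf`.
#'
#' @param A,B [persistence_diagram()] objects.
#' @param q Order, `>= 1` (default 1).
#' @param internal Internal norm on the plane: `"Linf"` (default) or `"L2"`.
#' @param finite_only Drop infinite intervals before matching?
#' @return Nonnegative number.
#' @export
#' @examples
#' A <- persistence_diagram(0, 1)
#' B <- persistence_diagram(0, 10)
#' wasserstein_distance(A, B)  # 5.5: both routes through the diagonal
wasserstein_distance <- function(A, B, q = 1, internal = c("Linf", "L2"),
                                 finite_only = TRUE) {
  stopifnot(inherits(A, "tempoph_diagram"), inherits(B, "tempoph_diagram"))
  q <- check_scalar(q, "q", min = 1)
  code <- internal_norm_code(internal)
  fa <- finite_part(A)
  fb <- finite_part(B)
  base <- .wasserstein_cpp(fa, fb, q, code)
  if (finite_only) return(base)
  ia <- unclass(A)[!is.finite(unclass(A)[, 2]), 1]
  ib <- unclass(B)[!is.finite(unclass(B)[, 2]), 1]
  if (length(ia) != length(ib)) return(Inf)
  if (length(ia) == 0L) return(base)
  extra <- sum(abs(sort(ia) - sort(ib))^q)
  (base^q + extra)^(1 / q)
}

#' Pairwise Wasserstein distance matrix over a diagram sequence
#'
#' Given the `T` per-timepoint H0 diagrams of one subject-cohort, computes
#' the `T x T` matrix of pairwise Wasserstein distances (upper triangle
#' solved, then mirrored).
#'
#' @param diagrams List of `T >= 2` [persistence_diagram()] objects with a
#'   common number of intervals.
#' @param q,internal,finite_only As in [wasserstein_distance()].
#' @param cohort,subject_id Optional tags stored on the result.
#' @return A `tempoph_sdm`: symmetric `T x T` matrix with zero diagonal and
#'   attributes `cohort` and `subject_id`.
#' @export
pairwise_wd_matrix <- function(diagrams, q = 1, internal = c("Linf", "L2"),
                               finite_only = TRUE,
                               cohort = NULL, subject_id = NULL) {
  stopifnot(is.list(diagrams), length(diagrams) >= 2L)
  lapply(diagrams, function(d)
    stopifnot(inherits(d, "tempoph_diagram")))
  sizes <- vapply(diagrams, nrow, integer(1))
  if (length(unique(sizes)) != 1L)
    stop_param("all diagrams must have the same number of intervals")
  q <- check_scalar(q, "q", min = 1)
  code <- internal_norm_code(internal)
  if (!finite_only)
    return(pairwise_wd_matrix_slow(diagrams, q, internal, cohort, subject_id))
  finite <- lapply(diagrams, finite_part)
  D <- .pairwise_wd_cpp(finite, q, code)
  structure(D, class = c("tempoph_sdm", "matrix"),
            cohort = cohort, subject_id = subject_id)
}

# Fallback path when infinite intervals participate in the matching.
pairwise_wd_matrix_slow <- function(diagrams, q, internal, cohort,
                                    subject_id) {
  Tn <- length(diagrams)
  D <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn - 1L)) {
    for (j in (i + 1L):Tn) {
      D[i, j] <- D[j, i] <- wasserstein_distance(diagrams[[i]], diagrams[[j]],
                                                 q = q, internal = internal,
                                                 finite_only = FALSE)
    }
  }
  structure(D, class = c("tempoph_sdm", "matrix"),
            cohort = cohort, subject_id = subject_id)
}
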