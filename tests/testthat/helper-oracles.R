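# Independent oracles, deliberately implemented with different algorithms
# than the package (Prim vs Kruskal; exhaustive matching enumeration vs the
# Hungarian assignment).

# MST edge weights by Prim's algorithm (array-scan version).
oracle_prim_mst <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(numeric(0))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  key <- d[1, ]
  w <- numeric(0)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(key[cand])]
    w <- c(w, key[j])
    in_tree[j] <- TRUE
    key <- pmin(key, d[j, ])
  }
  sort(w)
}

# q-Wasserstein by brute-force enumeration over all partial matchings.
# a, b: matrices with columns (birth, death), finite points only.
oracle_wd <- function(a, b, q = 1, internal = "Linf") {
  pd <- function(p1, p2) {
    if (internal == "Linf") max(abs(p1 - p2)) else sqrt(sum((p1 - p2)^2))
  }
  dd <- function(p) {
    if (internal == "Linf") abs(p[2] - p[1]) / 2
    else abs(p[2] - p[1]) / sqrt(2)
  }
  n <- nrow(a); m <- nrow(b)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > n) {
      rest <- if (m > 0) sum(vapply(which(!used), function(j) {
        dd(b[j, ])^q
      }, numeric(1))) else 0
      best <<- min(best, acc + rest)
      return(invisible())
    }
    rec(i + 1L, used, acc + dd(a[i, ])^q)          # i goes to the diagonal
    if (m > 0) for (j in seq_len(m)) {
      if (!used[j])
        rec(i + 1L, replace(used, j, TRUE), acc + pd(a[i, ], b[j, ])^q)
    }
    invisible()
  }
  rec(1L, rep(FALSE, m), 0)
  best^(1 / q)
}

# Random symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Random finite 0-dimension-style diagram with n points.
random_diagram_points <- function(n) {
  if (n == 0) return(cbind(birth = numeric(0), death = numeric(0)))
  b <- runif(n, 0, 0.5)
  cbind(birth = b, death = b + runif(n, 0, 2))
}
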