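test_that("H0 diagram matches hand-worked merge events", {
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  pd <- compute_h0_diagram(d2)
  expect_equal(unclass(pd)[, "birth"], c(0, 0))
  expect_equal(unclass(pd)[, "death"], c(0.5, Inf))

  d3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  pd3 <- compute_h0_diagram(d3)
  expect_equal(unclass(pd3)[, "death"], c(1, 2, Inf))  # MST = {1, 2}

  expect_equal(nrow(compute_h0_diagram(matrix(0, 1, 1))), 1)
})

test_that("finite deaths equal the Prim MST weights on random inputs", {
  set.seed(100)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    d <- random_distance_matrix(n)
    pd <- unclass(compute_h0_diagram(d))
    expect_equal(sum(is.infinite(pd[, "death"])), 1)
    expect_equal(pd[, "birth"], rep(0, n))
    expect_equal(unname(pd[is.finite(pd[, "death"]), "death"]),
                 oracle_prim_mst(d))
  }
})

test_that("diagram is invariant to point relabeling and scales with inputs", {
  set.seed(7)
  d <- random_distance_matrix(8)
  pd <- unclass(compute_h0_diagram(d))
  perm <- sample(8)
  expect_equal(unclass(compute_h0_diagram(d[perm, perm])), pd)
  for (c_scale in c(0.25, 3)) {
    pd_s <- unclass(compute_h0_diagram(c_scale * d))
    expect_equal(pd_s[, "death"], c_scale * pd[, "death"])
  }
})

test_that("Wasserstein distance agrees with enumeration over matchings", {
  set.seed(200)
  for (rep in 1:60) {
    a <- random_diagram_points(sample(0:4, 1))
    b <- random_diagram_points(sample(0:4, 1))
    A <- persistence_diagram(a[, 1], a[, 2])
    B <- persistence_diagram(b[, 1], b[, 2])
    for (q in c(1, 2)) {
      for (internal in c("Linf", "L2")) {
        expect_lt(abs(wasserstein_distance(A, B, q = q, internal = internal) -
                        oracle_wd(a, b, q = q, internal = internal)), 1e-9)
      }
    }
  }
})

test_that("Wasserstein closed-form cases hold", {
  A <- persistence_diagram(0, 1)
  B <- persistence_diagram(0, 10)
  empty <- persistence_diagram(numeric(0), numeric(0))
  expect_equal(wasserstein_distance(A, A), 0)
  # diagonal route 0.5 + 5.0 beats the direct match at 9.0
  expect_equal(wasserstein_distance(A, B), 5.5)
  expect_equal(wasserstein_distance(A, empty), 0.5)
  expect_equal(wasserstein_distance(empty, empty), 0)
  expect_error(wasserstein_distance(A, B, q = 0.5), "range")
})

test_that("infinite intervals are excluded by default, matched on request", {
  A <- persistence_diagram(c(0, 0), c(1, Inf))
  B <- persistence_diagram(c(0.2, 0), c(1, Inf))
  expect_equal(wasserstein_distance(A, B),
               wasserstein_distance(persistence_diagram(0, 1),
                                    persistence_diagram(0.2, 1)))
  with_inf <- wasserstein_distance(A, B, finite_only = FALSE)
  expect_equal(with_inf, wasserstein_distance(A, B))  # equal births: + 0
  C <- persistence_diagram(c(0, 0.3), c(1, Inf))
  expect_equal(wasserstein_distance(A, C, finite_only = FALSE),
               wasserstein_distance(A, C) + 0.3)
  D <- persistence_diagram(0, 1)  # no infinite bar
  expect_equal(wasserstein_distance(A, D, finite_only = FALSE), Inf)
})

test_that("Wasserstein satisfies the metric axioms on random diagrams", {
  set.seed(300)
  for (rep in 1:40) {
    pts <- lapply(1:3, function(i) random_diagram_points(sample(1:4, 1)))
    dg <- lapply(pts, function(p) persistence_diagram(p[, 1], p[, 2]))
    dab <- wasserstein_distance(dg[[1]], dg[[2]])
    dba <- wasserstein_distance(dg[[2]], dg[[1]])
    dac <- wasserstein_distance(dg[[1]], dg[[3]])
    dbc <- wasserstein_distance(dg[[2]], dg[[3]])
    expect_gte(dab, 0)
    expect_lt(abs(dab - dba), 1e-9)
    expect_lte(dac, dab + dbc + 1e-9)
    expect_lt(wasserstein_distance(dg[[1]], dg[[1]]), 1e-12)
  }
})

test_that("pairwise WD matrix mirrors the elementwise distance", {
  A <- persistence_diagram(0, 1)
  B <- persistence_diagram(0, 10)
  M <- pairwise_wd_matrix(list(A, B))
  expect_equal(unclass(M)[1:2, 1:2], matrix(c(0, 5.5, 5.5, 0), 2, 2))

  same <- pairwise_wd_matrix(list(A, A, A))
  expect_true(all(unclass(same) == 0))

  set.seed(17)
  dgs <- lapply(1:5, function(i) {
    p <- random_diagram_points(4)
    persistence_diagram(p[, 1], p[, 2])
  })
  M5 <- pairwise_wd_matrix(dgs, q = 2, internal = "L2")
  expect_equal(unclass(M5), t(unclass(M5)))
  expect_equal(M5[2, 4], wasserstein_distance(dgs[[2]], dgs[[4]],
                                              q = 2, internal = "L2"))
})

test_that("H0 + WD pipeline is scale-equivariant end to end", {
  set.seed(23)
  d1 <- random_distance_matrix(6)
  d2 <- random_distance_matrix(6)
  w <- wasserstein_distance(compute_h0_diagram(d1), compute_h0_diagram(d2))
  w3 <- wasserstein_distance(compute_h0_diagram(3 * d1),
                             compute_h0_diagram(3 * d2))
  expect_equal(w3, 3 * w)
})

test_that("malformed distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(compute_h0_diagram(bad), "symmetric")
  expect_error(compute_h0_diagram(matrix(c(0, -1, -1, 0), 2, 2)),
               "nonnegative")
  expect_error(compute_h0_diagram(matrix(c(0, Inf, Inf, 0), 2, 2)), "finite")
})
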