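test_that("eigenvector centrality solves small symmetric cases exactly", {
  # 2-cycle with equal weights w: scores (1, 1)/sqrt(2), eigenvalue w
  W <- matrix(c(0, 0.75, 0.75, 0), 2, 2)
  ec <- eigenvector_centrality(topo_from_weights(W))
  expect_true(ec$converged)
  expect_equal(ec$scores, rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(ec$leading_eigenvalue, 0.75, tolerance = 1e-9)
  # directed 3-cycle, unit weights: uniform scores, eigenvalue 1
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- A[3, 1] <- 1
  ec3 <- eigenvector_centrality(topo_from_weights(A))
  expect_equal(ec3$scores, rep(1 / sqrt(3), 3), tolerance = 1e-8)
  expect_equal(ec3$leading_eigenvalue, 1, tolerance = 1e-9)
})

test_that("the out-convention scores the upstream driver of a fan highest", {
  # one cell drives a hub which drives ten targets: the driver must not be
  # ranked below the targets, and the hub's in-driver outranks the leaves
  n <- 12
  A <- matrix(0, n, n)
  A[1, 2] <- 1            # driver -> hub
  A[2, 3:12] <- 1         # hub -> ten leaves
  A[3, 1] <- 0.01         # weak feedback closing the loop
  ec <- eigenvector_centrality(topo_from_weights(A))
  expect_gt(ec$scores[1], max(ec$scores[4:12]))
  expect_equal(which.max(ec$scores), 1L)  # the upstream driver leads
})

test_that("power iteration matches a dense eigensolver on random strong graphs", {
  for (s in 1:20) {
    n <- sample(5:8, 1)
    A <- rand_strong_digraph(n, 0.45, seed = 100 + s) *
      matrix(runif(n * n, 0.5, 2), n, n)
    diag(A) <- 0
    ec <- eigenvector_centrality(topo_from_weights(A))
    expect_true(ec$converged)
    eg <- eigen(A)
    k <- which.max(Re(eg$values))
    v <- abs(Re(eg$vectors[, k])); v <- v / sqrt(sum(v^2))
    expect_equal(ec$scores, v, tolerance = 1e-8)
    expect_equal(ec$leading_eigenvalue, Re(eg$values[k]), tolerance = 1e-8)
    # fixed-point residual
    expect_lt(max(abs(A %*% ec$scores - ec$leading_eigenvalue * ec$scores)),
              1e-8)
  }
})

test_that("reducible graphs fall back to the largest strong component", {
  # two 3-cycles, one feeding the other: scores concentrate on one component
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[3, 1] <- 1
  A[4, 5] <- A[5, 6] <- A[6, 4] <- 1
  A[3, 4] <- 1  # bridge makes the graph reducible
  ec <- eigenvector_centrality(topo_from_weights(A))
  expect_false(ec$converged)
  expect_equal(sum(ec$scores > 1e-6), 3)
  expect_equal(sqrt(sum(ec$scores^2)), 1, tolerance = 1e-9)
})

test_that("degree centrality normalizes by n - 1", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 3] <- 1  # chain a -> b -> c
  topo <- topo_from_weights(A)
  expect_equal(degree_centrality(topo, "out")$scores, c(0.5, 0.5, 0))
  expect_equal(degree_centrality(topo, "in")$scores, c(0, 0.5, 0.5))
  K <- matrix(1, 4, 4); diag(K) <- 0
  expect_equal(degree_centrality(topo_from_weights(K), "total")$scores,
               rep(1, 4))
  expect_equal(degree_centrality(topo_from_weights(matrix(0, 3, 3)))$scores,
               rep(0, 3))
})

test_that("distribution fits recover known parameters and reject degeneracy", {
  set.seed(55)
  x <- rlnorm(10000, meanlog = -3.9, sdlog = 1.0)
  fit <- fit_distribution(x, "lognormal")
  expect_equal(fit$location, -3.9, tolerance = 0.03 / 3.9)
  expect_equal(fit$scale, 1.0, tolerance = 0.03)
  expect_gt(fit$ks_p, 0.01)
  y <- rnorm(5000, 0.05, 0.03)
  fitn <- fit_distribution(y, "normal")
  expect_equal(fitn$location, 0.05, tolerance = 0.05)
  expect_error(fit_distribution(rep(1, 20), "normal"), "degenerate")
  expect_error(fit_distribution(c(-1, rnorm(20)), "lognormal"), "positive")
  expect_error(fit_distribution(rlnorm(5), "lognormal"), "at least 8")
})

test_that("algebraic connectivity obeys the connectivity theorem's closed forms", {
  # two disjoint 2-cycles: disconnected, lambda2 = 0
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_equal(algebraic_connectivity(topo_from_weights(A)), 0)
  # complete graph K_n: lambda2 = n, normalized exactly 1
  for (n in c(3, 7)) {
    K <- matrix(1, n, n); diag(K) <- 0
    expect_equal(algebraic_connectivity(topo_from_weights(K)), 1,
                 tolerance = 1e-12)
  }
  # path on 3 nodes: Laplacian spectrum {0, 1, 3} -> 1/3
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  expect_equal(algebraic_connectivity(topo_from_weights(P)), 1 / 3,
               tolerance = 1e-12)
})

test_that("lambda2 is positive iff the symmetrized graph is connected", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(6:15, 1)
    A <- rand_digraph(n, runif(1, 0.05, 0.3), s)
    if (s %% 3 == 0) {  # force a disconnected block
      A[1:2, ] <- 0; A[, 1:2] <- 0; A[1, 2] <- 1; A[2, 1] <- 1
    }
    val <- algebraic_connectivity(topo_from_weights(A), "or")
    U <- pmax(A, t(A))
    g <- igraph::graph_from_adjacency_matrix(U, mode = "undirected")
    expect_equal(val > 0, igraph::is_connected(g))
  }
})

test_that("algebraic connectivity is monotone under edge-weight increase", {
  set.seed(9)
  A <- rand_digraph(10, 0.4, 9) * matrix(runif(100, 0.2, 1), 10, 10)
  diag(A) <- 0
  vals <- vapply(c(0.5, 1, 2, 4), function(f) {
    algebraic_connectivity(topo_from_weights(A * f))
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  # adding an edge never decreases it
  A2 <- A; A2[1, 5] <- A2[1, 5] + 2
  expect_gte(algebraic_connectivity(topo_from_weights(A2)),
             algebraic_connectivity(topo_from_weights(A)) - 1e-12)
})

test_that("walk counts reproduce hand-computed matrix powers", {
  # 2-cycle: closed(2) = 2, open(2) = 0
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  wc <- count_walks(topo_from_weights(A), K = 4)
  expect_equal(unname(wc$closed["2"]), 2)
  expect_equal(unname(wc$open["2"]), 0)
  # directed 3-cycle: A^3 = I
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 3] <- C[3, 1] <- 1
  wc3 <- count_walks(topo_from_weights(C), K = 4)
  expect_equal(unname(wc3$closed["3"]), 3)
  expect_equal(unname(wc3$open["3"]), 0)
  expect_equal(unname(wc3$open["2"]), 3)
  # acyclic chain: open(1) = 2, open(2) = 1, closed always 0
  Ch <- matrix(0, 3, 3); Ch[1, 2] <- Ch[2, 3] <- 1
  wch <- count_walks(topo_from_weights(Ch), K = 3)
  expect_equal(unname(wch$open[c("1", "2", "3")]), c(2, 1, 0))
  expect_true(all(wch$closed == 0))
  expect_error(count_walks(topo_from_weights(A), K = 1), ">= 2")
})

test_that("walk counts match exhaustive enumeration on small digraphs", {
  # all 64 labeled 3-node digraphs
  for (code in 0:63) {
    A <- matrix(0, 3, 3)
    A[row(A) != col(A)] <- as.integer(intToBits(code))[1:6]
    wc <- count_walks(topo_from_weights(A), K = 4)
    for (k in 2:4) {
      E <- enum_walks(A, k)
      expect_equal(unname(wc$open[as.character(k)]), sum(E) - sum(diag(E)))
      expect_equal(unname(wc$closed[as.character(k)]), sum(diag(E)))
    }
  }
  # random 4- and 5-node digraphs
  for (s in 1:30) {
    n <- 4 + s %% 2
    A <- rand_digraph(n, 0.45, 300 + s)
    wc <- count_walks(topo_from_weights(A), K = 4)
    for (k in 2:4) {
      E <- enum_walks(A, k)
      expect_equal(unname(wc$open[as.character(k)]), sum(E) - sum(diag(E)))
      expect_equal(unname(wc$closed[as.character(k)]), sum(diag(E)))
    }
  }
})

test_that("O-C ratios handle zeros, infinities and plain arithmetic", {
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 3] <- C[3, 1] <- 1
  oc <- oc_ratio(count_walks(topo_from_weights(C), K = 3))
  expect_equal(unname(oc["3"]), 0)   # 0 open / 3 closed
  Ch <- matrix(0, 4, 4); Ch[1, 2] <- Ch[2, 3] <- Ch[3, 4] <- 1
  occ <- oc_ratio(count_walks(topo_from_weights(Ch), K = 3))
  expect_true(all(is.infinite(occ[c("2", "3")])))
  wc <- structure(list(open = c("1" = 3, "2" = 10), closed = c("2" = 2),
                       K = 2L), class = "walk_counts")
  expect_equal(unname(oc_ratio(wc)["2"]), 5)
})

test_that("growth slopes linearize exponential walk growth", {
  # exact geometric counts give R^2 = 1 exactly
  wc <- structure(list(open = stats::setNames(10 * 3^(1:6), 1:6),
                       closed = stats::setNames(2 * 3^(2:6), 2:6), K = 6L),
                  class = "walk_counts")
  gs <- suppressWarnings(growth_slope(wc, "open"))  # lm flags the exact fit
  expect_equal(gs$r_squared, 1)
  expect_equal(gs$slope, log(3), tolerance = 1e-12)
  expect_equal(suppressWarnings(growth_slope(wc, "closed"))$slope, log(3),
               tolerance = 1e-12)
  # complete directed graph on n nodes: slope -> log(n - 1), R^2 ~ 1
  n <- 20
  K <- matrix(1, n, n); diag(K) <- 0
  # open(k) = (n-1)((n-1)^k - (-1)^k) is geometric only up to O((n-1)^-k)
  gk <- growth_slope(count_walks(topo_from_weights(K), K = 10), "open")
  expect_equal(gk$slope, log(n - 1), tolerance = 2e-3)
  expect_gt(gk$r_squared, 0.99999)
  # large strongly connected graph: slope within 1% of log(Perron eigenvalue)
  A <- rand_strong_digraph(60, 0.2, seed = 17)
  gs2 <- growth_slope(count_walks(topo_from_weights(A), K = 10), "open")
  lam <- max(Re(eigen(A, only.values = TRUE)$values))
  expect_equal(gs2$slope, log(lam), tolerance = 0.01)
  # zero counts are dropped; too few points is an error
  Ch <- matrix(0, 3, 3); Ch[1, 2] <- Ch[2, 3] <- 1
  expect_error(growth_slope(count_walks(topo_from_weights(Ch), K = 10),
                            "closed"), "positive counts")
})

test_that("reciprocal percentage counts bidirected pairs", {
  K <- matrix(1, 5, 5); diag(K) <- 0
  expect_equal(reciprocal_percent(topo_from_weights(K)), 100)
  Ch <- matrix(0, 3, 3); Ch[1, 2] <- Ch[2, 3] <- 1
  expect_equal(reciprocal_percent(topo_from_weights(Ch)), 0)
  # cross-check against trace(A^2) for binary graphs
  for (s in 1:6) {
    A <- rand_digraph(15, 0.4, 500 + s)
    tr2 <- sum(diag(A %*% A))
    expect_equal(reciprocal_percent(topo_from_weights(A)),
                 100 * (tr2 / 2) / (15 * 14 / 2))
  }
})

test_that("every scalar invariant is label-independent", {
  fx <- sim_fixture(n = 60, n_events = 5, seed = 71)
  topo <- fx$topology
  wc <- count_walks(topo, K = 6)
  base <- list(
    ac = algebraic_connectivity(topo),
    open = wc$open, closed = wc$closed,
    oc = unname(oc_ratio(wc)),
    slope = growth_slope(wc, "open")$slope,
    recip = reciprocal_percent(topo),
    lam = eigenvector_centrality(topo)$leading_eigenvalue)
  set.seed(72)
  for (rep in 1:20) {
    perm <- sample(length(topo$cell_ids))
    tp <- permute_topology(topo, perm)
    wcp <- count_walks(tp, K = 6)
    expect_equal(algebraic_connectivity(tp), base$ac, tolerance = 1e-9)
    expect_equal(unname(wcp$open), unname(base$open))
    expect_equal(unname(wcp$closed), unname(base$closed))
    expect_equal(unname(oc_ratio(wcp)), base$oc)
    expect_equal(growth_slope(wcp, "open")$slope, base$slope,
                 tolerance = 1e-10)
    expect_equal(reciprocal_percent(tp), base$recip)
    expect_equal(eigenvector_centrality(tp)$leading_eigenvalue, base$lam,
                 tolerance = 1e-7)
  }
})

test_that("eigenvector scores permute with the nodes on strong graphs", {
  A <- rand_strong_digraph(7, 0.5, seed = 81)
  topo <- topo_from_weights(A)
  ec <- eigenvector_centrality(topo)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  ecp <- eigenvector_centrality(permute_topology(topo, perm))
  expect_equal(ecp$scores, ec$scores[perm], tolerance = 1e-8)
})

test_that("invariant_report assembles consistent pieces", {
  fx <- sim_fixture(n = 80, n_events = 6, seed = 91)
  rep_ <- invariant_report(fx$topology, K = 8)
  expect_s3_class(rep_, "invariant_report")
  expect_equal(rep_$n_edges, sum(fx$topology$weights > 0))
  expect_equal(rep_$reciprocal_percent, reciprocal_percent(fx$topology))
  expect_equal(rep_$algebraic_connectivity_normalized,
               algebraic_connectivity(fx$topology))
  expect_true(is.null(rep_$eigenvector_fit) ||
                rep_$eigenvector_fit$family == "lognormal")
  expect_output(print(rep_), "invariant_report")
})
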