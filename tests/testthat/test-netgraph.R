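test_that("adjacency construction keeps only supra-cutoff positive r", {
  r <- diag(4)
  r[upper.tri(r)] <- c(0.5, -0.6, 0.2, 0.7, 0.05, 0.4)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  res <- structure(list(r = r, fdr_cutoff = 0.3), class = "fc_result")
  g <- build_adjacency(res)
  expect_true(all(diag(g$weights) == 0))
  # brute-force filter of the upper triangle
  expected <- r
  expected[!(r >= 0.3 & r > 0)] <- 0
  diag(expected) <- 0
  expect_equal(g$weights, expected)

  # cutoff above everything: edgeless graph
  res_inf <- structure(list(r = r, fdr_cutoff = Inf), class = "fc_result")
  expect_true(all(build_adjacency(res_inf)$weights == 0))

  # cutoff 0 with positive r: complete graph on the positive pairs
  res0 <- structure(list(r = abs(r), fdr_cutoff = 0), class = "fc_result")
  w0 <- build_adjacency(res0)$weights
  expect_true(all(w0[upper.tri(w0)] > 0))
})

test_that("Louvain modularity matches exhaustive search on two cliques", {
  # two disconnected unit-weight K4s: 8 nodes, 4140 partitions enumerated
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  parts <- all_partitions(8)
  expect_length(parts, 4140)
  best <- max(vapply(parts, function(p) modularity_of(w, p), numeric(1)))
  expect_equal(best, 0.5)

  g <- fc_graph(w)
  fit <- graph_modularity(g, n_restarts = 20, seed = 3)
  expect_equal(fit$q, 0.5)
  expect_length(unique(fit$partition[1:4]), 1)
  expect_length(unique(fit$partition[5:8]), 1)
  expect_false(fit$partition[1] == fit$partition[5])

  # complete uniform graph: no community structure, Q = 0
  wc <- matrix(1, 6, 6)
  diag(wc) <- 0
  expect_equal(graph_modularity(fc_graph(wc), 10, seed = 1)$q, 0)

  expect_error(graph_modularity(fc_graph(matrix(0, 4, 4))), "edgeless")
  # determinism under a fixed seed
  expect_identical(graph_modularity(g, 10, seed = 11),
                   graph_modularity(g, 10, seed = 11))
})

test_that("shortest paths equal the Floyd-Warshall oracle exactly", {
  # hand cases: unit path a-b-c and a 0.5-weight edge
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  d <- shortest_path_lengths(fc_graph(w))
  expect_equal(d[1, 3], 2)
  w2 <- matrix(0, 2, 2)
  w2[1, 2] <- w2[2, 1] <- 0.5
  expect_equal(shortest_path_lengths(fc_graph(w2))[1, 2], 2)

  for (s in 1:50) {
    w <- random_weight_matrix(10, p_edge = 0.35, seed = s)
    d_dijkstra <- shortest_path_lengths(fc_graph(w))
    d_fw <- floyd_warshall(weights_to_lengths(w))
    expect_equal(d_dijkstra, d_fw)
  }
})

test_that("efficiency metrics reproduce hand-enumerated values", {
  # complete unit-weight K4: everything is 1
  k4 <- matrix(1, 4, 4)
  diag(k4) <- 0
  expect_equal(global_efficiency(fc_graph(k4)), 1)
  expect_equal(local_efficiency(fc_graph(k4)), 1)
  expect_equal(clustering_coefficient(fc_graph(k4)), 1)
  expect_equal(as.numeric(characteristic_path_length(fc_graph(k4))), 1)

  # path graph P3: pairs (1,2),(2,3) at distance 1 and (1,3) at 2
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- 1
  p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(global_efficiency(fc_graph(p3)), (1 + 1 + 0.5) / 3)
  expect_equal(as.numeric(characteristic_path_length(fc_graph(p3))),
               (1 + 1 + 2) / 3)

  # edgeless graph: zero efficiency
  expect_equal(global_efficiency(fc_graph(matrix(0, 4, 4))), 0)

  # star graph: no neighbor-neighbor edges anywhere
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(fc_graph(star)), 0)
  expect_equal(clustering_coefficient(fc_graph(star)), 0)

  # two disconnected unit edges: infinite pairs excluded from the mean
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1
  two[3, 4] <- two[4, 3] <- 1
  cpl <- characteristic_path_length(fc_graph(two))
  expect_equal(as.numeric(cpl), 1)
  expect_equal(attr(cpl, "n_infinite"), 8)

  expect_error(characteristic_path_length(fc_graph(matrix(0, 3, 3))),
               "no finite")
})

test_that("local efficiency and clustering match per-node brute force", {
  for (s in 1:10) {
    w <- random_weight_matrix(10, p_edge = 0.5, seed = 100 + s)
    g <- fc_graph(w)

    le_brute <- mean(vapply(1:10, function(i) {
      nb <- which(w[i, ] > 0)
      if (length(nb) < 2) return(0)
      sub <- w[nb, nb, drop = FALSE]
      d <- floyd_warshall(weights_to_lengths(sub))
      inv <- 1 / d
      diag(inv) <- 0
      sum(inv) / (length(nb) * (length(nb) - 1))
    }, numeric(1)))
    expect_equal(local_efficiency(g), le_brute)

    wn <- w / max(w)
    cc_brute <- mean(vapply(1:10, function(i) {
      nb <- which(w[i, ] > 0)
      k <- length(nb)
      if (k < 2) return(0)
      acc <- 0
      for (j in nb) for (h in nb) {
        if (j != h && w[j, h] > 0) {
          acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
      acc / (k * (k - 1))
    }, numeric(1)))
    expect_equal(clustering_coefficient(g), cc_brute)
  }

  # unit triangle: 1; tree: 0
  tri <- matrix(1, 3, 3)
  diag(tri) <- 0
  expect_equal(clustering_coefficient(fc_graph(tri)), 1)
  tree <- matrix(0, 4, 4)
  tree[1, 2] <- tree[2, 1] <- 1
  tree[2, 3] <- tree[3, 2] <- 1
  tree[3, 4] <- tree[4, 3] <- 1
  expect_equal(clustering_coefficient(fc_graph(tree)), 0)

  # uniform weights reduce to unweighted triangle counting
  set.seed(4)
  adj <- matrix(rbinom(64, 1, 0.5), 8, 8) * 0.7
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  diag(adj) <- 0
  g_uni <- fc_graph(adj)
  unweighted <- local({
    a <- (adj > 0) * 1
    mean(vapply(1:8, function(i) {
      k <- sum(a[i, ])
      if (k < 2) return(0)
      (a %*% a %*% a)[i, i] / (k * (k - 1))
    }, numeric(1)))
  })
  expect_equal(clustering_coefficient(g_uni), unweighted)
})

test_that("graph metrics are invariant under node relabeling", {
  for (s in 1:5) {
    w <- random_weight_matrix(12, p_edge = 0.4, seed = 200 + s)
    set.seed(s)
    p <- sample(12)
    wp <- w[p, p]
    expect_equal(global_efficiency(fc_graph(w)),
                 global_efficiency(fc_graph(wp)))
    expect_equal(local_efficiency(fc_graph(w)),
                 local_efficiency(fc_graph(wp)))
    expect_equal(clustering_coefficient(fc_graph(w)),
                 clustering_coefficient(fc_graph(wp)))
    expect_equal(as.numeric(characteristic_path_length(fc_graph(w))),
                 as.numeric(characteristic_path_length(fc_graph(wp))))
  }
})

test_that("a ring lattice shows the small-world signature against a random graph", {
  n <- 96
  k <- 6
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (step in 1:(k / 2)) {
      j <- ((i - 1 + step) %% n) + 1
      w[i, j] <- w[j, i] <- 1
    }
  }
  ring <- fc_graph(w)
  ig <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  set.seed(42)
  rnd <- igraph::rewire(ig, igraph::keeping_degseq(niter = 2000))
  w_rnd <- igraph::as_adjacency_matrix(rnd, sparse = FALSE) * 1
  random <- fc_graph(w_rnd)

  expect_gt(clustering_coefficient(ring), 2 * clustering_coefficient(random))
  expect_gt(local_efficiency(ring), local_efficiency(random))
  ge_ring <- global_efficiency(ring)
  ge_rnd <- global_efficiency(random)
  expect_lt(max(ge_ring, ge_rnd) / min(ge_ring, ge_rnd), 3)
})
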