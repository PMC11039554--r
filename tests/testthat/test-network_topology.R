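test_that("density thresholding keeps exactly the prescribed edge count", {
  withr::with_seed(1, {
    m5 <- matrix(runif(25), 5, 5); m5 <- (m5 + t(m5)) / 2; diag(m5) <- 0
  })
  expect_equal(threshold_binarize(m5, 40)$n_edges, 4)  # round(0.4 * 10)

  # the paper's atlas scale: R = 246, K = 12 -> round(0.12 * 30135) = 3616
  withr::with_seed(2, {
    m <- matrix(runif(246^2), 246, 246); m <- (m + t(m)) / 2; diag(m) <- 0
  })
  bn <- threshold_binarize(m, 12)
  expect_equal(bn$n_edges, 3616)
  expect_equal(sum(bn$adjacency) / 2, 3616)
  expect_identical(bn$adjacency, t(bn$adjacency))

  expect_error(threshold_binarize(m5, 0), "in \\(0, 100\\)")
  expect_error(threshold_binarize(m5, 100), "in \\(0, 100\\)")
})

test_that("ties are broken by ascending (i, j) order, deterministically", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  a <- threshold_binarize(m, 50)  # round(0.5 * 6) = 3 edges
  expect_equal(a$n_edges, 3)
  # ascending (i, j): (1,2), (1,3), (1,4)
  expect_equal(a$adjacency[1, 2:4], c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(a$adjacency[2:4, 2:4]), 0)
  b <- threshold_binarize(m, 50)
  expect_identical(a, b)
})

test_that("strongest edges are the ones retained", {
  withr::with_seed(3, {
    m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 0
  })
  bn <- threshold_binarize(m, 20)
  w <- m[upper.tri(m)]
  kept <- bn$adjacency[upper.tri(m)] == 1
  expect_true(min(w[kept]) >= max(w[!kept]))
})

test_that("closed-form global metrics: complete graph, path, two cliques", {
  k5 <- matrix(1L, 5, 5); diag(k5) <- 0L
  gm <- global_metrics(k5, n_random = 3, seed = 1)
  expect_equal(gm[["global_efficiency"]], 1)
  expect_equal(gm[["clustering_coefficient"]], 1)

  path3 <- adjacency_from_edges(3, cbind(c(1, 2), c(2, 3)))
  gm3 <- global_metrics(path3, n_random = 3, seed = 1)
  expect_equal(gm3[["global_efficiency"]], (1 + 1 + 0.5) / 3)

  twok3 <- adjacency_from_edges(6, cbind(c(1, 1, 2, 4, 4, 5),
                                         c(2, 3, 3, 5, 6, 6)))
  gmk <- global_metrics(twok3, n_random = 3, seed = 1)
  expect_equal(gmk[["modularity"]], 0.5)
  expect_lt(gmk[["global_efficiency"]], 1)  # unreachable pairs contribute 0
  expect_error(global_metrics(matrix(0L, 4, 4)), "no edges")
})

test_that("nodal metrics on star and cycle graphs", {
  star <- adjacency_from_edges(5, cbind(1, 2:5))
  nm <- nodal_metrics(star)
  expect_equal(nm$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(nm$betweenness[1], 1)      # normalised center betweenness
  expect_equal(nm$betweenness[-1], rep(0, 4))
  expect_equal(nm$eigenvector[1], 1)

  cyc <- adjacency_from_edges(6, cbind(1:6, c(2:6, 1)))
  nmc <- nodal_metrics(cyc)
  expect_true(all(nmc$degree == 2L))
  expect_equal(max(nmc$betweenness) - min(nmc$betweenness), 0)
  expect_equal(nmc$eigenvector, rep(1, 6))  # vertex-transitive
})

test_that("betweenness matches the exhaustive path-counting oracle", {
  withr::with_seed(4, adj <- random_graph(12, 0.3))
  nm <- nodal_metrics(adj)
  expect_equal(nm$betweenness, bf_betweenness(adj), tolerance = 1e-12)
})

test_that("global efficiency is non-decreasing in density", {
  co <- simulate_cohort(simulation_spec(n_patients = 1, n_controls = 1,
                                        n_regions = 25,
                                        voxels_per_region = 60, seed = 5))
  nw <- build_network(co$samples[[1]])
  eff <- vapply(seq(10, 60, by = 10), function(K) {
    global_metrics(threshold_binarize(nw, K), n_random = 2,
                   seed = 1)[["global_efficiency"]]
  }, numeric(1))
  expect_true(all(diff(eff) >= 0))
})

test_that("threshold selection is deterministic and internally consistent", {
  co <- simulate_cohort(simulation_spec(n_patients = 3, n_controls = 3,
                                        n_regions = 30,
                                        voxels_per_region = 100, seed = 6))
  nets <- build_cohort_networks(co$samples)
  r1 <- select_threshold_range(nets, step = 5, window = c(5, 40),
                               n_random = 5, seed = 2)
  r2 <- select_threshold_range(nets, step = 5, window = c(5, 40),
                               n_random = 5, seed = 2)
  expect_identical(r1, r2)
  expect_true(all(r1$sigma_min > 1.1))
  expect_lte(r1$k_min, r1$k_max)
  # every network in the returned range is connected
  for (K in r1$k_grid) {
    for (nw in nets) {
      g <- igraph::graph_from_adjacency_matrix(
        threshold_binarize(nw, K)$adjacency, mode = "undirected")
      expect_equal(igraph::components(g)$no, 1)
    }
  }
})

test_that("AUC over thresholds integrates the metric curve", {
  k <- 12:39
  expect_equal(auc_over_thresholds(rep(3, length(k)), k), 27 * 3)
  lin <- 0.5 + 0.01 * k
  expect_equal(auc_over_thresholds(lin, k),
               0.5 * 27 + 0.01 * (39^2 - 12^2) / 2)  # exact line integral
  withr::with_seed(7, y <- runif(length(k)))
  resum <- sum((y[-1] + y[-length(y)]) / 2)  # unit-spacing oracle
  expect_equal(auc_over_thresholds(y, k), resum)
  expect_error(auc_over_thresholds(1, 12), "at least 2")
})

test_that("topology profiles share the threshold grid across subjects", {
  co <- simulate_cohort(simulation_spec(n_patients = 2, n_controls = 2,
                                        n_regions = 15,
                                        voxels_per_region = 60, seed = 8))
  nets <- build_cohort_networks(co$samples)
  prof <- compute_topology_profiles(nets, k_grid = c(20, 30, 40),
                                    n_random = 3, seed = 3)
  expect_equal(nrow(prof), 4)
  expect_equal(ncol(prof), 1 + 5 + 3 * 15)
  expect_false(anyNA(prof))
  # same edge count for every subject at fixed K
  counts <- vapply(nets, function(nw) threshold_binarize(nw, 25)$n_edges,
                   integer(1))
  expect_equal(length(unique(counts)), 1)
  # feature matrix transpose keeps alignment
  fm <- topology_features(prof)
  expect_identical(colnames(fm), co$phenotype$subject_id)
  expect_equal(fm["global_efficiency", 2],
               prof$global_efficiency[2], ignore_attr = TRUE)
})
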