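test_that("estimate_pdf recovers a Gaussian density", {
  withr::with_seed(1, x <- rnorm(500, 0.5, 0.1))
  grid <- seq(0, 1, length.out = 512)
  pdf <- estimate_pdf(x, grid)
  # unit trapezoid integral
  expect_equal(trapz(grid, pdf$density), 1, tolerance = 1e-6)
  # mode near the true mean
  expect_lt(abs(grid[which.max(pdf$density)] - 0.5), 0.05)
  # L1 distance to the closed-form normal density is small
  l1 <- trapz(grid, abs(pdf$density - dnorm(grid, 0.5, 0.1)))
  expect_lt(l1, 0.1)
})

test_that("KDE is consistent across disjoint half-samples", {
  withr::with_seed(2, x <- rnorm(2000, 0.6, 0.08))
  grid <- seq(0.2, 1, length.out = 512)
  p1 <- estimate_pdf(x[1:1000], grid)
  p2 <- estimate_pdf(x[1001:2000], grid)
  expect_lt(trapz(grid, abs(p1$density - p2$density)), 0.15)
})

test_that("estimate_pdf rejects degenerate samples", {
  expect_error(estimate_pdf(0.5, region = "r007"), "at least 2")
  expect_error(estimate_pdf(rep(0.5, 10), region = "r007"),
               "r007.*zero-variance")
})

test_that("symmetric KLD has the Jeffreys-divergence properties", {
  withr::with_seed(3, {
    x <- rnorm(300, 0.5, 0.1)
    y <- rnorm(300, 0.65, 0.12)
  })
  g <- pair_grid(x, y)
  p <- estimate_pdf(x, g)
  q <- estimate_pdf(y, g)
  expect_identical(symmetric_kld(p, p), 0)           # identity
  expect_identical(symmetric_kld(p, q), symmetric_kld(q, p))  # symmetry
  expect_gt(symmetric_kld(p, q), 0)                  # nonnegativity
  # mismatched grids are a hard error
  g2 <- seq(0, 1, length.out = 512)
  expect_error(symmetric_kld(p, estimate_pdf(y, g2)), "different grids")
})

test_that("numerical symmetric KLD approaches the Gaussian closed form", {
  # for N(mu1, s^2) vs N(mu2, s^2) the symmetric KLD is (mu1-mu2)^2/s^2 = 1
  withr::with_seed(4, {
    x <- rnorm(20000, 0.5, 0.1)
    y <- rnorm(20000, 0.6, 0.1)
  })
  g <- pair_grid(x, y)
  kld <- symmetric_kld(estimate_pdf(x, g), estimate_pdf(y, g))
  expect_lt(abs(kld - 1), 0.15)
})

test_that("kls transform maps divergence into (0, 1]", {
  expect_identical(kls(0), 1)
  expect_equal(kls(1), exp(-1), tolerance = 1e-12)
  expect_equal(round(kls(1), 5), 0.36788)
  expect_error(kls(-0.1), "nonnegative")
  withr::with_seed(5, a <- sort(runif(20, 0, 5)))
  expect_true(all(diff(kls(a)) < 0))  # strictly decreasing
})

test_that("build_network satisfies the similarity-matrix contract", {
  co <- simulate_cohort(simulation_spec(n_patients = 1, n_controls = 1,
                                        n_regions = 20,
                                        voxels_per_region = 80, seed = 6))
  nw <- build_network(co$samples[[1]])
  m <- nw$matrix
  expect_identical(m, t(m))                    # exact symmetry
  expect_true(all(diag(m) == 0))
  off <- m[upper.tri(m)]
  expect_true(all(off > 0 & off <= 1))
  expect_false(anyNA(m))
})

test_that("identical regional distributions give KLS near 1", {
  withr::with_seed(7, x <- rnorm(100, 0.5, 0.1))
  s <- regional_samples("twin", 1:3, list(x, x, x))
  nw <- build_network(s)
  expect_true(all(nw$matrix[upper.tri(nw$matrix)] >= 0.999))
})

test_that("compiled and reference engines agree", {
  co <- simulate_cohort(simulation_spec(n_patients = 1, n_controls = 1,
                                        n_regions = 12,
                                        voxels_per_region = 60, seed = 8))
  a <- build_network(co$samples[[1]], engine = "cpp")
  b <- build_network(co$samples[[1]], engine = "r")
  expect_equal(a$matrix, b$matrix, tolerance = 1e-6)
})

test_that("network is invariant to voxel order within regions", {
  co <- simulate_cohort(simulation_spec(n_patients = 1, n_controls = 1,
                                        n_regions = 6,
                                        voxels_per_region = 50, seed = 9))
  s <- co$samples[[1]]
  a <- build_network(s)
  s2 <- s
  withr::with_seed(10, {
    s2$samples <- lapply(s$samples, sample)
  })
  s2 <- regional_samples(s$subject_id, s$region_ids, s2$samples)
  b <- build_network(s2)
  expect_identical(a$matrix, b$matrix)
})

test_that("KLS decreases monotonically with Gaussian mean separation", {
  withr::with_seed(11, base <- rnorm(5000, 0.5, 0.1))
  deltas <- c(0, 0.05, 0.1, 0.2, 0.3)
  k <- vapply(deltas, function(d) kls_pair(base, base + d), numeric(1))
  expect_true(all(diff(k) < 0))
})

test_that("an effect edge increases that edge's KLS for the same seed", {
  base <- list(n_patients = 3, n_controls = 1, n_sites = 1, n_regions = 6,
               voxels_per_region = 120, age_slope = 0, gender_offset = 0,
               seed = 12)
  co0 <- simulate_cohort(do.call(simulation_spec, base))
  co1 <- simulate_cohort(do.call(simulation_spec,
    c(base, list(effect_edges = list(list(i = 1, j = 6, delta = 1))))))
  for (s in 1:3) {  # patients come first
    k0 <- kls_pair(co0$samples[[s]]$samples[[1]], co0$samples[[s]]$samples[[6]])
    k1 <- kls_pair(co1$samples[[s]]$samples[[1]], co1$samples[[s]]$samples[[6]])
    expect_gt(k1, k0)
  }
})

test_that("zero-variance regions are a hard error naming the region", {
  s <- regional_samples("z", c(1L, 5L), list(rnorm(20), rep(0.4, 20)))
  expect_error(build_network(s), "region 5.*zero-variance")
})

test_that("connectivity_features linearises networks consistently", {
  co <- simulate_cohort(simulation_spec(n_patients = 2, n_controls = 2,
                                        n_regions = 5,
                                        voxels_per_region = 40, seed = 13))
  nets <- build_cohort_networks(co$samples)
  E <- connectivity_features(nets)
  expect_equal(dim(E), c(10, 4))
  expect_identical(rownames(E)[1], "edge_r001_r002")
  # spot-check one entry against the matrix
  expect_identical(E["edge_r002_r004", 3], nets[[3]]$matrix["r002", "r004"])
})
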