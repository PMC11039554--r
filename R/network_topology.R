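#' Threshold and binarise a similarity network at density K%
#'
#' Keeps exactly `round(K/100 * R(R-1)/2)` strongest off-diagonal edges
#' (round half away from zero) and sets them to 1. Ties in edge weight are
#' broken by ascending (i, j) index order, which makes thresholding fully
#' deterministic. Using a density (rather than weight) threshold gives every
#' subject the same edge count at a given K, which is what makes group
#' comparisons of binary topology meaningful.
#'
#' @param net A `similarity_network` (or a plain symmetric matrix).
#' @param K Density in percent, 0 < K < 100.
#' @return Object of class `binary_network`: list with `adjacency` (0/1
#'   symmetric, zero diagonal), `K` and `n_edges`.
#' @export
threshold_binarize <- function(net, K) {
  if (!(K > 0 && K < 100)) stop("density K must be in (0, 100), got ", K)
  mat <- if (inherits(net, "similarity_network")) net$matrix else net
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  r <- nrow(mat)
  pairs <- edge_index_pairs(r)
  w <- mat[upper.tri(mat)]
  m <- as.integer(round_half_up(K / 100 * r * (r - 1) / 2))
  if (m < 1) stop("density K = ", K, " keeps no edges for R = ", r)
  keep <- order(-w, pairs$i, pairs$j)[seq_len(m)]
  adj <- matrix(0L, r, r, dimnames = dimnames(mat))
  adj[cbind(pairs$i[keep], pairs$j[keep])] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, K = K, n_edges = m),
            class = "binary_network")
}

as_graph <- function(bn) {
  adj <- if (inherits(bn, "binary_network")) bn$adjacency else bn
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

## Global efficiency: mean over ordered node pairs of 1/shortest-path-length;
## unreachable pairs contribute 0.
global_efficiency <- function(g) {
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- igraph::vcount(g)
  sum(inv) / (n * (n - 1))
}

## Mean nodal clustering coefficient; nodes with degree < 2 contribute 0.
mean_clustering <- function(g) {
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

## Characteristic path length: mean shortest path over reachable pairs.
char_path_length <- function(g) {
  igraph::mean_distance(g, unconnected = TRUE)
}

#' Global graph metrics of a binary network
#'
#' Computes the five global metrics of the topology profile:
#' \describe{
#'   \item{global_efficiency}{integration: mean inverse shortest path over
#'     ordered node pairs, unreachable pairs contributing 0.}
#'   \item{clustering_coefficient}{segregation: mean nodal triangle ratio.}
#'   \item{small_worldness}{sigma = (C/C_rand)/(L/L_rand), with C_rand and
#'     L_rand averaged over `n_random` degree-preserving Maslov-Sneppen
#'     rewired surrogates (10 x |E| swap attempts each, seeded).}
#'   \item{modularity}{best Q over 10 seeded Louvain restarts with randomly
#'     permuted vertex order (modularity maximisation is NP-hard; Louvain is
#'     the standard heuristic and its best-of-restarts Q is a lower bound on
#'     the true maximum).}
#'   \item{assortativity}{resilience: Pearson correlation of degrees over
#'     edge endpoints (NA on degree-regular graphs).}
#' }
#'
#' @param bn A `binary_network` (or 0/1 adjacency matrix).
#' @param n_random Number of rewired surrogates for sigma.
#' @param seed Seed for rewiring and Louvain restarts; all randomness is
#'   local (the global RNG state is untouched).
#' @return Named numeric vector of the 5 metrics.
#' @export
global_metrics <- function(bn, n_random = 20, seed = 0) {
  g <- as_graph(bn)
  if (igraph::ecount(g) == 0) stop("network has no edges")
  eff <- global_efficiency(g)
  cc <- mean_clustering(g)
  L <- char_path_length(g)
  res <- withr::with_seed(seed, {
    cr <- numeric(n_random)
    lr <- numeric(n_random)
    for (s in seq_len(n_random)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      cr[s] <- mean_clustering(gr)
      lr[s] <- char_path_length(gr)
    }
    ## Louvain's result depends on vertex order; restarts explore random
    ## orders and keep the best Q (heuristic: never exceeds, and usually
    ## attains, the exhaustive maximum on small graphs)
    q <- max(vapply(seq_len(10), function(i) {
      gp <- igraph::permute(g, sample(igraph::vcount(g)))
      igraph::modularity(igraph::cluster_louvain(gp))
    }, numeric(1)))
    list(c_rand = mean(cr), l_rand = mean(lr), q = q)
  })
  sigma <- (cc / res$c_rand) / (L / res$l_rand)
  c(global_efficiency = eff,
    clustering_coefficient = cc,
    small_worldness = sigma,
    modularity = res$q,
    assortativity = igraph::assortativity_degree(g))
}

#' Nodal centralities of a binary network
#'
#' Degree (raw row sum), betweenness (normalised by `(R-1)(R-2)/2`) and
#' eigenvector centrality (principal eigenvector of the adjacency matrix,
#' absolute values scaled to max 1, computed with a dense symmetric
#' eigendecomposition for determinism).
#'
#' @param bn A `binary_network` (or 0/1 adjacency matrix).
#' @return Data frame with columns `degree`, `betweenness`, `eigenvector`,
#'   one row per region.
#' @export
nodal_metrics <- function(bn) {
  adj <- if (inherits(bn, "binary_network")) bn$adjacency else bn
  g <- as_graph(adj)
  if (igraph::ecount(g) == 0) stop("network has no edges")
  deg <- as.integer(rowSums(adj))
  btw <- igraph::betweenness(g, normalized = TRUE)
  ev <- eigen(adj, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  v <- v / max(v)
  data.frame(degree = deg, betweenness = unname(btw), eigenvector = v)
}

all_connected <- function(nets, K) {
  for (nw in nets) {
    g <- as_graph(threshold_binarize(nw, K))
    if (igraph::components(g)$no != 1) return(FALSE)
  }
  TRUE
}

#' Select the valid density-threshold range for a cohort
#'
#' Scans densities in `window` with the given step. `k_min` is the smallest
#' density at which every subject's binarised network is a single connected
#' component; `k_max` is the largest subsequent density at which every
#' subject's small-worldness exceeds `floor` (the scan stops at the first
#' density violating the criterion, keeping the range contiguous). Surrogate
#' seeds are derived deterministically from `(seed, subject, K)` so repeated
#' runs return the identical range.
#'
#' @param nets List of `similarity_network` for the cohort.
#' @param step Density step in percent.
#' @param floor Small-worldness floor (default 1.1).
#' @param window Scan window `c(lo, hi)` in percent.
#' @param n_random Rewired surrogates per sigma estimate.
#' @param seed Base seed for surrogate rewiring.
#' @return List with `k_min`, `k_max`, `k_grid` (retained densities) and
#'   `sigma_min` (minimum sigma over subjects at each retained density).
#' @export
select_threshold_range <- function(nets, step = 1, floor = 1.1,
                                   window = c(1, 50), n_random = 20,
                                   seed = 0) {
  stopifnot(length(nets) >= 1)
  ks <- seq(window[1], window[2], by = step)
  k_min <- NA_real_
  for (K in ks) {
    if (all_connected(nets, K)) { k_min <- K; break }
  }
  if (is.na(k_min)) {
    stop("no density in [", window[1], ", ", window[2], "] connects every ",
         "subject's network; inspect the similarity matrices")
  }
  k_grid <- numeric(0)
  sigma_min <- numeric(0)
  for (K in ks[ks >= k_min]) {
    smin <- Inf
    for (s in seq_along(nets)) {
      gm <- global_metrics(threshold_binarize(nets[[s]], K),
                           n_random = n_random,
                           seed = surrogate_seed(seed, s, K))
      smin <- min(smin, gm[["small_worldness"]])
      if (smin <= floor) break
    }
    if (smin <= floor) break
    k_grid <- c(k_grid, K)
    sigma_min <- c(sigma_min, smin)
  }
  if (length(k_grid) == 0) {
    stop("empty valid threshold range: small-worldness <= ", floor,
         " already at the connectedness bound K = ", k_min,
         "; inspect the cohort")
  }
  list(k_min = k_min, k_max = k_grid[length(k_grid)],
       k_grid = k_grid, sigma_min = sigma_min)
}

#' Independently re-verify a threshold range
#'
#' Direct per-network re-check (a separate code path from
#' [select_threshold_range()]): at every density in `k_grid` and for every
#' subject, recomputes connectedness and small-worldness and returns the
#' minima. Uses the same deterministic surrogate-seed policy.
#'
#' @param nets List of `similarity_network`.
#' @param k_grid Densities to check.
#' @param n_random Rewired surrogates per sigma estimate.
#' @param seed Base seed.
#' @return List with `min_sigma`, `all_connected` and the per-(K, subject)
#'   sigma matrix.
#' @export
verify_threshold_range <- function(nets, k_grid, n_random = 20, seed = 0) {
  sig <- matrix(NA_real_, length(k_grid), length(nets))
  conn <- matrix(NA, length(k_grid), length(nets))
  for (ki in seq_along(k_grid)) {
    for (s in seq_along(nets)) {
      bn <- threshold_binarize(nets[[s]], k_grid[ki])
      conn[ki, s] <- igraph::components(as_graph(bn))$no == 1
      gm <- global_metrics(bn, n_random = n_random,
                           seed = surrogate_seed(seed, s, k_grid[ki]))
      sig[ki, s] <- gm[["small_worldness"]]
    }
  }
  list(min_sigma = min(sig), all_connected = all(conn), sigma = sig)
}

#' AUC of a metric curve over the density-threshold grid
#'
#' Trapezoidal integral of metric values against the densities at which they
#' were computed (unit spacing by default, un-normalised), removing
#' single-threshold selection bias.
#'
#' @param values Metric values, one per threshold.
#' @param k_grid Densities (same length, >= 2).
#' @return Scalar AUC.
#' @export
auc_over_thresholds <- function(values, k_grid) {
  if (length(values) < 2) stop("AUC needs at least 2 thresholds")
  stopifnot(length(values) == length(k_grid))
  trapz(k_grid, values)
}

#' Topology profiles (AUC over thresholds) for a cohort
#'
#' For every subject and every density in `k_grid`, computes the 5 global
#' metrics and 3 nodal centralities, then integrates each metric across the
#' threshold grid. The identical grid is used for every subject.
#'
#' @param nets Named list of `similarity_network`.
#' @param k_grid Retained densities (from [select_threshold_range()] or
#'   fixed, e.g. `12:39`).
#' @param n_random Rewired surrogates per sigma estimate.
#' @param seed Base seed for surrogate rewiring/Louvain.
#' @return Data frame: `subject_id`, 5 global AUC columns
#'   (`global_efficiency`, `clustering_coefficient`, `small_worldness`,
#'   `modularity`, `assortativity`), then `deg_r*`, `btw_r*`, `eig_r*` per
#'   region.
#' @export
compute_topology_profiles <- function(nets, k_grid, n_random = 20, seed = 0) {
  stopifnot(length(k_grid) >= 2)
  region_ids <- nets[[1]]$region_ids
  r <- length(region_ids)
  t0 <- Sys.time()
  rows <- lapply(seq_along(nets), function(s) {
    glob <- matrix(NA_real_, length(k_grid), 5)
    deg <- btw <- eig <- matrix(NA_real_, length(k_grid), r)
    for (ki in seq_along(k_grid)) {
      bn <- threshold_binarize(nets[[s]], k_grid[ki])
      glob[ki, ] <- global_metrics(bn, n_random = n_random,
                                   seed = surrogate_seed(seed, s, k_grid[ki]))
      nm <- nodal_metrics(bn)
      deg[ki, ] <- nm$degree
      btw[ki, ] <- nm$betweenness
      eig[ki, ] <- nm$eigenvector
    }
    auc <- function(mat) apply(mat, 2, auc_over_thresholds, k_grid = k_grid)
    c(auc(glob), auc(deg), auc(btw), auc(eig))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("global_efficiency", "clustering_coefficient",
                  "small_worldness", "modularity", "assortativity",
                  sprintf("deg_r%03d", region_ids),
                  sprintf("btw_r%03d", region_ids),
                  sprintf("eig_r%03d", region_ids))
  out <- cbind(subject_id = vapply(nets, function(nw) nw$subject_id,
                                   character(1)),
               out)
  rownames(out) <- NULL
  log_stage("topology profiles for %d subjects x %d thresholds in %.1fs",
            length(nets), length(k_grid),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Topology feature matrix for harmonisation / statistics
#'
#' Transposes a [compute_topology_profiles()] data frame into the features x
#' subjects matrix used by [combat_harmonize()] and [glm_compare()].
#'
#' @param profiles Output of [compute_topology_profiles()].
#' @return Numeric matrix, features x subjects.
#' @export
topology_features <- function(profiles) {
  m <- t(as.matrix(profiles[, setdiff(names(profiles), "subject_id")]))
  colnames(m) <- profiles$subject_id
  m
}
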