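# Brute-force graph oracles, deliberately implemented with different
# algorithms than the package (Floyd-Warshall, explicit path counting,
# exhaustive partition search, power iteration) so agreement is informative.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_efficiency <- function(adj) {
  d <- bf_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  mean(sapply(1:n, function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    (sum(adj[nb, nb]) / 2) / (k * (k - 1) / 2)
  }))
}

# shortest-path counts sigma[s, t] by dynamic programming over distance
bf_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in 1:n) {
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      pred <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_path_counts(adj, d)
  btw <- numeric(n)
  for (v in 1:n) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || !is.finite(d[s, t])) next
    if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
        d[s, v] + d[v, t] == d[s, t]) {
      btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# every set partition of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1]] <<- rgs[1:n]
      return()
    }
    for (v in 1:(mx + 1)) {
      rgs[i] <<- v
      rec(i + 1, max(mx, v))
    }
  }
  rec(1, 0)
  out
}

bf_modularity <- function(adj, parts) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  best <- -Inf
  for (p in parts) {
    q <- 0
    for (c in unique(p)) {
      idx <- p == c
      q <- q + sum(adj[idx, idx]) / 2 / m - (sum(deg[idx]) / (2 * m))^2
    }
    if (q > best) best <- q
  }
  best
}

bf_assortativity <- function(adj) {
  e <- which(adj == 1, arr.ind = TRUE)  # both orientations of each edge
  deg <- rowSums(adj)
  suppressWarnings(cor(deg[e[, 1]], deg[e[, 2]]))
}

bf_eigenvector <- function(adj) {
  n <- nrow(adj)
  v <- rep(1, n)
  A <- adj + diag(n)  # shift avoids bipartite oscillation, same eigenvectors
  for (i in 1:5000) {
    v <- A %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- abs(as.numeric(v))
  v / max(v)
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- rbinom(sum(ut), 1, p)
  adj + t(adj)
}

adjacency_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  adj[edges] <- 1L
  adj + t(adj)
}

# small helper cohorts ------------------------------------------------------

make_phenotype <- function(n, n_sites = 1, groups = NULL, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = groups %||% rep(c("patient", "control"), length.out = n),
    site = sprintf("site%02d", rep_len(seq_len(n_sites), n)),
    age = runif(n, 18, 65),
    gender = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
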