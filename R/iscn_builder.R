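#' Gaussian kernel density estimate of a region's GMV distribution
#'
#' Exact-sum Gaussian KDE evaluated on a caller-supplied grid, renormalised
#' to unit trapezoid integral over that grid. Bandwidth follows Silverman's
#' rule of thumb ([stats::bw.nrd0()]) on the input vector unless overridden.
#'
#' @param samples Numeric vector of voxel GMV values (>= 2, nonzero
#'   variance).
#' @param grid Monotone increasing evaluation grid (default spans the sample
#'   range padded by 3 bandwidths, 512 points).
#' @param bw Kernel bandwidth; default Silverman.
#' @param region Label used in error messages.
#' @return An object of class `regional_pdf`: list with `grid`, `density`
#'   (unit trapezoid integral) and `bw`.
#' @export
estimate_pdf <- function(samples, grid = NULL, bw = NULL, region = "region") {
  if (length(samples) < 2) stop(region, ": need at least 2 samples for KDE")
  if (var(samples) == 0) stop(region, ": zero-variance samples, KDE undefined")
  h <- bw %||% bw.nrd0(samples)
  if (is.null(grid)) {
    grid <- seq(min(samples) - 3 * h, max(samples) + 3 * h, length.out = 512)
  }
  stopifnot(length(grid) >= 2, !is.unsorted(grid, strictly = TRUE))
  ## exact sum over samples (no FFT binning): column k is the kernel at
  ## grid point k
  z <- outer(samples, grid, function(x, g) (g - x) / h)
  dens <- colSums(exp(-0.5 * z * z)) / (length(samples) * h * sqrt(2 * pi))
  dens <- dens / trapz(grid, dens)
  structure(list(grid = grid, density = dens, bw = h), class = "regional_pdf")
}

#' Symmetric (Jeffreys) Kullback-Leibler divergence between two PDFs
#'
#' Computes `D(P||Q) + D(Q||P) = sum (p - q) log(p / q)` by trapezoid
#' integration over the shared grid. Both densities are floored at `eps` and
#' renormalised first, which keeps the divergence finite and stable across
#' grid resolutions.
#'
#' @param p,q [estimate_pdf()] results evaluated on the identical grid.
#' @param eps Density floor (default 1e-10).
#' @return Nonnegative scalar divergence; 0 iff the densities are equal.
#' @export
symmetric_kld <- function(p, q, eps = 1e-10) {
  stopifnot(inherits(p, "regional_pdf"), inherits(q, "regional_pdf"))
  if (!identical(p$grid, q$grid)) {
    stop("symmetric_kld: PDFs are evaluated on different grids")
  }
  g <- p$grid
  pd <- pmax(p$density, eps)
  qd <- pmax(q$density, eps)
  pd <- pd / trapz(g, pd)
  qd <- qd / trapz(g, qd)
  ## (p-q) log(p/q) >= 0 elementwise, so the integral is nonnegative
  trapz(g, (pd - qd) * log(pd / qd))
}

#' Kullback-Leibler similarity transform
#'
#' `KLS = exp(-KLD)`, mapping a nonnegative divergence into (0, 1]; 1 iff the
#' divergence is 0, strictly decreasing.
#'
#' @param kld_value Nonnegative divergence (vectorised).
#' @return Similarity in (0, 1].
#' @export
kls <- function(kld_value) {
  if (any(kld_value < 0)) stop("kls: divergence must be nonnegative")
  exp(-kld_value)
}

## Shared evaluation grid for one region pair: equally spaced points spanning
## the pooled sample range, padded by 3 pooled-sample Silverman bandwidths on
## each side.
pair_grid <- function(x, y, n = 512, pad = 3) {
  h <- bw.nrd0(c(x, y))
  lo <- min(x, y) - pad * h
  hi <- max(x, y) + pad * h
  seq(lo, hi, length.out = n)
}

#' KLS between two voxel-sample vectors
#'
#' Convenience wrapper: builds the pair-pooled grid, estimates both PDFs and
#' returns `kls(symmetric_kld(...))`.
#'
#' @param x,y Voxel-value vectors.
#' @param n Grid points.
#' @param eps Density floor.
#' @return Similarity in (0, 1].
#' @export
kls_pair <- function(x, y, n = 512, eps = 1e-10) {
  g <- pair_grid(x, y, n)
  kls(symmetric_kld(estimate_pdf(x, g), estimate_pdf(y, g), eps))
}

#' Build one subject's individualised structural covariance network
#'
#' For every unordered region pair, both regional PDFs are estimated on a
#' shared 512-point grid spanning the pooled sample range (padded by 3
#' pooled-sample bandwidths per side), and the edge weight is
#' `exp(-symmetric KLD)`. The result is an exactly symmetric R x R matrix
#' with entries in (0, 1] and a zero diagonal (self-similarity is excluded
#' from all analyses).
#'
#' @param subject A [regional_samples()] object.
#' @param grid_n Evaluation points per pair (default 512).
#' @param pad Grid padding in pooled-sample bandwidths.
#' @param eps Density floor passed to the divergence.
#' @param engine `"cpp"` (compiled pair loop, default) or `"r"` (reference
#'   path through [estimate_pdf()]/[symmetric_kld()]); both produce the same
#'   matrix to numerical precision.
#' @param global_grid If `TRUE`, a single grid spanning the subject's full
#'   sample range is used for every pair (sensitivity-analysis mode) instead
#'   of the pair-pooled grid.
#' @return Object of class `similarity_network`: list with `subject_id`,
#'   `region_ids` and `matrix`.
#' @export
build_network <- function(subject, grid_n = 512, pad = 3, eps = 1e-10,
                          engine = c("cpp", "r"), global_grid = FALSE) {
  stopifnot(inherits(subject, "regional_samples"))
  engine <- match.arg(engine)
  sm <- subject$samples
  r <- length(sm)
  for (k in seq_len(r)) {
    if (var(sm[[k]]) == 0) {
      stop("region ", subject$region_ids[k],
           ": zero-variance samples, KDE undefined")
    }
  }
  h <- vapply(sm, bw.nrd0, numeric(1))
  mins <- vapply(sm, min, numeric(1))
  maxs <- vapply(sm, max, numeric(1))

  lo <- matrix(0, r, r)
  hi <- matrix(0, r, r)
  if (global_grid) {
    hg <- bw.nrd0(unlist(sm, use.names = FALSE))
    lo[] <- min(mins) - pad * hg
    hi[] <- max(maxs) + pad * hg
  } else {
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        hp <- bw.nrd0(c(sm[[i]], sm[[j]]))
        lo[i, j] <- min(mins[i], mins[j]) - pad * hp
        hi[i, j] <- max(maxs[i], maxs[j]) + pad * hp
      }
    }
  }

  if (engine == "cpp") {
    mat <- cpp_kls_matrix(sm, h, lo, hi, as.integer(grid_n), eps)
  } else {
    mat <- matrix(0, r, r)
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        g <- seq(lo[i, j], hi[i, j], length.out = grid_n)
        pi_ <- estimate_pdf(sm[[i]], g, bw = h[i])
        pj_ <- estimate_pdf(sm[[j]], g, bw = h[j])
        mat[i, j] <- mat[j, i] <- kls(symmetric_kld(pi_, pj_, eps))
      }
    }
  }
  dimnames(mat) <- rep(list(sprintf("r%03d", subject$region_ids)), 2)
  structure(list(subject_id = subject$subject_id,
                 region_ids = subject$region_ids,
                 matrix = mat),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  w <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("<similarity_network> subject %s: %d regions, KLS %.3f-%.3f\n",
              x$subject_id, length(x$region_ids), min(w), max(w)))
  invisible(x)
}

#' Build iSCNs for a whole cohort
#'
#' @param samples Named list of [regional_samples()].
#' @param ... Passed to [build_network()].
#' @return Named list of `similarity_network` objects.
#' @export
build_cohort_networks <- function(samples, ...) {
  t0 <- Sys.time()
  nets <- lapply(samples, build_network, ...)
  log_stage("built %d iSCNs (%d regions) in %.1fs", length(nets),
            length(nets[[1]]$region_ids),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  nets
}

#' Rebuild similarity networks from an edge feature matrix
#'
#' Inverse of [connectivity_features()]: restores each subject's symmetric
#' KLS matrix (zero diagonal) from the linearised upper triangle.
#'
#' @param edges Numeric matrix, `R(R-1)/2` edge features x subjects.
#' @param region_ids Integer region labels (length R).
#' @return Named list of `similarity_network` objects.
#' @export
networks_from_features <- function(edges, region_ids) {
  r <- length(region_ids)
  stopifnot(nrow(edges) == r * (r - 1) / 2)
  ids <- colnames(edges) %||% sprintf("S%04d", seq_len(ncol(edges)))
  out <- lapply(seq_len(ncol(edges)), function(s) {
    m <- matrix(0, r, r, dimnames = rep(list(sprintf("r%03d", region_ids)), 2))
    m[upper.tri(m)] <- edges[, s]
    m <- m + t(m)
    structure(list(subject_id = ids[s], region_ids = region_ids, matrix = m),
              class = "similarity_network")
  })
  names(out) <- ids
  out
}

#' Edge feature matrix of a cohort of iSCNs
#'
#' Linearises each subject's upper triangle into the features x subjects
#' matrix consumed by [combat_harmonize()], [nbs()] and
#' [clinical_association()]. Feature order is column-major upper-triangle;
#' names are `edge_r<i>_r<j>`.
#'
#' @param networks Named list of `similarity_network`.
#' @return Numeric matrix, `R(R-1)/2` rows (edges) x subjects.
#' @export
connectivity_features <- function(networks) {
  region_ids <- networks[[1]]$region_ids
  out <- vapply(networks, function(nw) {
    stopifnot(identical(nw$region_ids, region_ids))
    nw$matrix[upper.tri(nw$matrix)]
  }, numeric(length(region_ids) * (length(region_ids) - 1) / 2))
  rownames(out) <- edge_feature_names(region_ids)
  colnames(out) <- vapply(networks, function(nw) nw$subject_id, character(1))
  out
}
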