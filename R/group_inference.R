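## Build the GLM design [intercept, group(patient=1), covariates] from a
## phenotype table, with rank checks.
group_design <- function(phenotype, covariates) {
  validate_phenotype(phenotype)
  g <- as.numeric(phenotype$group == "patient")
  if (length(unique(g)) < 2) stop("both groups must be present")
  covdf <- phenotype[, covariates, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, group = g,
             if (ncol(covdf) > 0)
               model.matrix(~ ., data = covdf)[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("collinear covariates in the design matrix")
  X
}

## Group-contrast t statistics for every row of a features-x-subjects
## matrix, via one multiresponse least-squares fit.
group_t_stats <- function(features, X) {
  n <- ncol(features)
  k <- ncol(X)
  fit <- lm.fit(X, t(features))
  cf <- fit$coefficients
  res <- fit$residuals
  sigma2 <- colSums(res^2) / (n - k)
  gpos <- which(colnames(X) == "group")
  xtxi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * xtxi[gpos, gpos])
  est <- cf["group", ]
  list(estimate = est, se = se, t = est / se, df = n - k,
       resid_sd = sqrt(sigma2))
}

#' Case-control GLM comparison of harmonised features
#'
#' Per feature, an ordinary-least-squares fit of
#' `feature ~ group + covariates`; the group contrast (patient minus
#' control, covariate-adjusted) is tested with a two-tailed t test and
#' Bonferroni-corrected over the declared family. Cohen's d is the adjusted
#' contrast divided by the residual SD.
#'
#' @param features Numeric matrix, features x subjects (harmonised).
#' @param phenotype Phenotype data.frame aligned with the columns.
#' @param covariates Nuisance covariate columns (default age, gender).
#' @param family Bonferroni family size; default the number of features.
#'   The five global metrics form one family; nodal centralities use a
#'   family of R per centrality type.
#' @param alpha Familywise significance level.
#' @return Data frame: feature, estimate, t, p, cohens_d, p_bonferroni,
#'   significant. Zero-variance features get NA statistics.
#' @export
glm_compare <- function(features, phenotype, covariates = c("age", "gender"),
                        family = NULL, alpha = 0.05) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == nrow(phenotype))
  family <- family %||% nrow(features)
  X <- group_design(phenotype, covariates)
  degenerate <- apply(features, 1, function(y) var(y) == 0)
  st <- group_t_stats(features, X)
  p <- 2 * pt(abs(st$t), df = st$df, lower.tail = FALSE)
  d <- st$estimate / st$resid_sd
  out <- data.frame(feature = rownames(features) %||%
                      sprintf("feature%03d", seq_len(nrow(features))),
                    estimate = unname(st$estimate),
                    t = unname(st$t),
                    p = unname(p),
                    cohens_d = unname(d),
                    stringsAsFactors = FALSE)
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s); statistics set to NA")
    out[degenerate, c("estimate", "t", "p", "cohens_d")] <- NA_real_
  }
  out$p_bonferroni <- pmin(out$p * family, 1)
  out$significant <- !is.na(out$p) & out$p < alpha / family
  out
}

## Residualise the columns of M (n x m) against the column space of Z.
residualize <- function(M, qz) {
  M - qr.fitted(qz, M)
}

## Max component edge count of the graph formed by the given edges.
max_component_edges <- function(pairs, n_nodes) {
  if (nrow(pairs) == 0) return(0L)
  g <- igraph::graph_from_edgelist(as.matrix(pairs), directed = FALSE)
  comp <- igraph::components(g)$membership
  ## count edges per component
  ce <- table(comp[pairs[, 1]])
  as.integer(max(ce))
}

extract_components <- function(pairs, region_ids) {
  if (nrow(pairs) == 0) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(pairs), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_ids <- sort(unique(memb[pairs[, 1]]))
  lapply(comp_ids, function(cid) {
    sel <- memb[pairs[, 1]] == cid
    e <- pairs[sel, , drop = FALSE]
    nodes <- sort(unique(c(e)))
    list(edges = data.frame(i = region_ids[e[, 1]], j = region_ids[e[, 2]]),
         edge_index = e,
         nodes = region_ids[nodes],
         size = nrow(e))
  })
}

#' Network-based statistics (NBS) on harmonised edge features
#'
#' Identifies connected subnetwork components with group differences while
#' controlling the familywise error by permutation of the maximal component
#' size. Steps: (1) edge-wise GLM t statistics for the group contrast with
#' covariates; (2) suprathreshold edges taken separately for positive and
#' negative t exceeding the two-tailed critical value at `edge_p`; (3)
#' connected components of each suprathreshold graph (breadth-first search);
#' (4) for each of `n_perm` group-label permutations (covariates stay
#' attached to subjects; the identity permutation is always the first) the
#' same steps are rerun and the maximal component edge count recorded, per
#' direction; (5) a component is significant when the fraction of
#' permutation maxima at or above its size is below `alpha`. Component size
#' is the edge count; node counts are descriptive.
#'
#' @param edges Numeric matrix, `R(R-1)/2` edge features x subjects (rows in
#'   the column-major upper-triangle order of [connectivity_features()]).
#' @param phenotype Aligned phenotype data.frame.
#' @param covariates Nuisance covariates kept in the model.
#' @param edge_p Edge-level two-tailed p threshold (default 0.001).
#' @param n_perm Number of permutations including the identity (default
#'   10000; < 100 draws a warning).
#' @param alpha Familywise alpha on the component p value.
#' @param seed Permutation seed.
#' @param region_ids Region labels (length R); default `1:R` inferred from
#'   the edge count.
#' @return List with one element per direction (`increased`, `decreased`),
#'   each holding `components` (edges, nodes, size, corrected p,
#'   significant), `max_null` (permutation max-size distribution) and
#'   `t_crit`; plus `observed_t` and `df`.
#' @export
nbs <- function(edges, phenotype, covariates = c("age", "gender"),
                edge_p = 0.001, n_perm = 10000L, alpha = 0.05, seed = 0,
                region_ids = NULL) {
  edges <- as.matrix(edges)
  n <- ncol(edges)
  stopifnot(n == nrow(phenotype))
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  n_edges <- nrow(edges)
  r <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (r != round(r)) stop("edge count ", n_edges, " is not R(R-1)/2")
  r <- as.integer(r)
  region_ids <- region_ids %||% seq_len(r)
  pairs <- as.matrix(edge_index_pairs(r))

  X <- group_design(phenotype, covariates)
  Z <- X[, setdiff(colnames(X), "group"), drop = FALSE]
  qz <- qr(Z)
  df <- n - ncol(X)
  t_crit <- qt(1 - edge_p / 2, df)

  ## Frisch-Waugh: t for the group term of the full GLM equals the t of the
  ## regression of covariate-residualised edges on the covariate-residualised
  ## group indicator. Residualising the edges once makes the permutation loop
  ## a single matrix product.
  Yres <- residualize(t(edges), qz)             # n x edges
  g <- X[, "group"]
  perms <- withr::with_seed(seed, {
    cbind(seq_len(n),
          replicate(n_perm - 1, sample.int(n)))
  })
  G <- matrix(g[perms], nrow = n)               # n x n_perm permuted labels
  Gres <- residualize(G, qz)
  gnorm <- sqrt(colSums(Gres^2))
  ynorm <- sqrt(colSums(Yres^2))
  num <- crossprod(Yres, Gres)                  # edges x n_perm
  rmat <- num / outer(ynorm, gnorm)
  tmat <- rmat * sqrt(df) / sqrt(pmax(1 - rmat^2, .Machine$double.eps))

  t_obs <- tmat[, 1]
  directions <- list(increased = +1, decreased = -1)
  out <- lapply(directions, function(sgn) {
    max_null <- vapply(seq_len(n_perm), function(p) {
      sel <- sgn * tmat[, p] > t_crit
      max_component_edges(pairs[sel, , drop = FALSE], r)
    }, integer(1))
    comps <- extract_components(pairs[sgn * t_obs > t_crit, , drop = FALSE],
                                region_ids)
    comps <- lapply(comps, function(cp) {
      cp$p <- mean(max_null >= cp$size)
      cp$significant <- cp$p < alpha
      cp
    })
    list(components = comps, max_null = max_null, t_crit = t_crit)
  })
  out$observed_t <- t_obs
  out$df <- df
  out$region_ids <- region_ids
  out
}

#' Functional-network connection-weight summary of an NBS component
#'
#' Groups a significant component's nodes into the seven Yeo intrinsic
#' functional networks plus a subcortical bucket and computes, for every
#' network pair, the connection weight = number of component edges joining
#' the pair divided by the maximum possible number of edges between (or
#' within) the two networks, given the full parcellation's network sizes.
#'
#' @param component One component from [nbs()] (list with `edges`).
#' @param assignment Region-to-network lookup (`region_id`, `network`)
#'   covering every region of the parcellation.
#' @return List with `weights` (symmetric network x network matrix in
#'   \[0, 1\]) and `sums` (per-network row sums, the histogram totals).
#' @export
summarize_networks <- function(component, assignment) {
  edges <- component$edges
  nets <- sort(unique(assignment$network))
  lookup <- setNames(assignment$network, assignment$region_id)
  miss <- setdiff(unique(c(edges$i, edges$j)), assignment$region_id)
  if (length(miss) > 0) {
    stop("component node(s) without a network assignment: ",
         paste(miss, collapse = ", "))
  }
  sizes <- table(factor(assignment$network, levels = nets))
  W <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  na_ <- lookup[as.character(edges$i)]
  nb_ <- lookup[as.character(edges$j)]
  for (k in seq_len(nrow(edges))) {
    W[na_[k], nb_[k]] <- W[na_[k], nb_[k]] + 1
    if (na_[k] != nb_[k]) W[nb_[k], na_[k]] <- W[nb_[k], na_[k]] + 1
  }
  denom <- outer(as.numeric(sizes), as.numeric(sizes))
  diag(denom) <- as.numeric(sizes) * (as.numeric(sizes) - 1) / 2
  denom[denom == 0] <- NA
  W <- W / denom
  list(weights = W, sums = rowSums(W, na.rm = TRUE))
}

#' Partial correlation of features with a clinical score
#'
#' Partial Pearson correlation between each feature and the score,
#' controlling for the covariates by residualising both sides; two-tailed p
#' from the t distribution with `n - k - 2` degrees of freedom (k =
#' number of covariate columns), Bonferroni-corrected over the declared
#' family. Only subjects with a non-missing score (typically patients) are
#' used.
#'
#' @param features Numeric matrix, features x subjects.
#' @param phenotype Aligned phenotype data.frame.
#' @param score Phenotype column holding the clinical rating (default
#'   `hamd17`).
#' @param covariates Covariates to control (default age, gender).
#' @param family Bonferroni family size; default number of features.
#' @param alpha Familywise alpha.
#' @return Data frame: feature, n, partial_r, p, p_bonferroni, significant.
#' @export
clinical_association <- function(features, phenotype, score = "hamd17",
                                 covariates = c("age", "gender"),
                                 family = NULL, alpha = 0.05) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == nrow(phenotype), score %in% names(phenotype))
  keep <- !is.na(phenotype[[score]])
  y <- phenotype[[score]][keep]
  n <- length(y)
  if (n <= length(covariates) + 2) {
    stop("too few scored subjects (", n, ") for ", length(covariates),
         " covariates")
  }
  covdf <- phenotype[keep, covariates, drop = FALSE]
  Z <- model.matrix(~ ., data = covdf)
  k <- ncol(Z) - 1
  if (n <= k + 2) stop("too few scored subjects (", n, ") for ", k,
                       " covariate columns")
  family <- family %||% nrow(features)
  qz <- qr(Z)
  yres <- residualize(cbind(y), qz)
  Fres <- residualize(t(features[, keep, drop = FALSE]), qz)
  num <- crossprod(Fres, yres)[, 1]
  den <- sqrt(colSums(Fres^2) * sum(yres^2))
  r <- num / den
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - k - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), df = n - k - 2, lower.tail = FALSE)
  data.frame(feature = rownames(features) %||%
               sprintf("feature%03d", seq_len(nrow(features))),
             n = n,
             partial_r = unname(r),
             p = unname(p),
             p_bonferroni = pmin(unname(p) * family, 1),
             significant = unname(p) < alpha / family,
             stringsAsFactors = FALSE)
}
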