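#' Run the full iSCN analysis pipeline on a synthetic cohort
#'
#' End-to-end driver used by the analysis scripts and by the determinism
#' tests: simulate (or accept) a cohort, build the iSCNs, select the density
#' threshold range, compute AUC topology profiles, harmonise topology and
#' edge features by site, run the group GLM, NBS with Yeo-network
#' summarisation, topology- and connectivity-based SVM classification, and
#' the clinical partial-correlation association. Every stochastic step is
#' seeded from `config$seed`, so two runs with the same spec and config are
#' bit-identical.
#'
#' @param spec A [simulation_spec()], or a pre-simulated cohort list (the
#'   output of [simulate_cohort()]).
#' @param config An [iscn_config()].
#' @return List of result tables: `phenotype`, `threshold_range`,
#'   `topology_glm`, `nbs_components`, `network_weights`,
#'   `classification`, `clinical_topology`, `clinical_edges`,
#'   `region_contributions`.
#' @export
run_pipeline <- function(spec, config = iscn_config()) {
  cohort <- if (inherits(spec, "simulation_spec")) {
    log_stage("simulating cohort (seed %d)", spec$seed)
    simulate_cohort(spec)
  } else {
    spec
  }
  phen <- cohort$phenotype
  nets <- build_cohort_networks(cohort$samples, grid_n = config$kde_points)

  if (identical(config$density_range, "auto")) {
    rng <- select_threshold_range(nets, step = config$density_step,
                                  floor = config$small_world_floor,
                                  window = config$density_window,
                                  n_random = config$n_random,
                                  seed = config$seed)
  } else {
    kg <- seq(config$density_range[1], config$density_range[2],
              by = config$density_step)
    rng <- list(k_min = kg[1], k_max = kg[length(kg)], k_grid = kg,
                sigma_min = rep(NA_real_, length(kg)))
  }
  log_stage("density threshold range: %g-%g%%", rng$k_min, rng$k_max)

  profiles <- compute_topology_profiles(nets, rng$k_grid,
                                        n_random = config$n_random,
                                        seed = config$seed)
  topo <- topology_features(profiles)
  edges <- connectivity_features(nets)

  biol <- phen[, c("group", config$covariates), drop = FALSE]
  log_stage("ComBat harmonisation (%d + %d features, %d sites)",
            nrow(topo), nrow(edges), length(unique(phen$site)))
  topo_h <- combat_harmonize(topo, phen$site, model = biol)
  edges_h <- combat_harmonize(edges, phen$site, model = biol)

  global_names <- c("global_efficiency", "clustering_coefficient",
                    "small_worldness", "modularity", "assortativity")
  n_regions <- length(nets[[1]]$region_ids)
  glm_global <- glm_compare(topo_h[global_names, , drop = FALSE], phen,
                            covariates = config$covariates, family = 5)
  nodal <- topo_h[!rownames(topo_h) %in% global_names, , drop = FALSE]
  glm_nodal <- glm_compare(nodal, phen, covariates = config$covariates,
                           family = n_regions)
  topology_glm <- rbind(cbind(family = "global", glm_global),
                        cbind(family = "nodal", glm_nodal))

  log_stage("NBS (%d permutations)", config$nbs_permutations)
  nbs_res <- nbs(edges_h, phen, covariates = config$covariates,
                 edge_p = config$nbs_edge_p,
                 n_perm = config$nbs_permutations,
                 alpha = config$nbs_alpha, seed = config$seed,
                 region_ids = nets[[1]]$region_ids)
  nbs_components <- do.call(rbind, lapply(c("increased", "decreased"),
    function(dir) {
      comps <- nbs_res[[dir]]$components
      if (length(comps) == 0) return(NULL)
      do.call(rbind, lapply(seq_along(comps), function(k) {
        cp <- comps[[k]]
        data.frame(direction = dir, component = k, n_edges = cp$size,
                   n_nodes = length(cp$nodes), p = cp$p,
                   significant = cp$significant)
      }))
    }))
  if (is.null(nbs_components)) {
    nbs_components <- data.frame(direction = character(), component = integer(),
                                 n_edges = integer(), n_nodes = integer(),
                                 p = numeric(), significant = logical())
  }
  network_weights <- lapply(c("increased", "decreased"), function(dir) {
    comps <- Filter(function(cp) cp$significant, nbs_res[[dir]]$components)
    lapply(comps, summarize_networks, assignment = cohort$assignment)
  })
  names(network_weights) <- c("increased", "decreased")

  log_stage("SVM classification (%d-fold)", config$cv_folds)
  labels <- phen$group
  rep_topo <- svm_classify(t(topo_h), labels, folds = config$cv_folds,
                           cost = config$svm_cost, seed = config$seed)
  rep_conn <- svm_classify(t(edges_h), labels, folds = config$cv_folds,
                           cost = config$svm_cost, seed = config$seed)
  classification <- rbind(
    data.frame(feature_set = "topology", t(rep_topo$metrics)),
    data.frame(feature_set = "connectivity", t(rep_conn$metrics)))
  region_contributions <- list(
    topology = map_region_contributions(rep_topo, "topology"),
    connectivity = map_region_contributions(rep_conn, "connectivity"))

  clinical_topology <- clinical_association(topo_h, phen,
                                            covariates = config$covariates)
  clinical_edges <- clinical_association(edges_h, phen,
                                         covariates = config$covariates)

  list(phenotype = phen,
       threshold_range = data.frame(k_min = rng$k_min, k_max = rng$k_max),
       k_grid = rng$k_grid,
       profiles = profiles,
       topology_glm = topology_glm,
       nbs = nbs_res,
       nbs_components = nbs_components,
       network_weights = network_weights,
       classification = classification,
       region_contributions = region_contributions,
       clinical_topology = clinical_topology,
       clinical_edges = clinical_edges)
}
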