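#' Pipeline run configuration
#'
#' Collects every tunable parameter of the iSCN pipeline with the defaults
#' used throughout the package. All downstream functions accept the relevant
#' scalar arguments directly; the config object exists so that a whole run
#' (and the analysis drivers) can be parameterised from one place or from a
#' JSON file.
#'
#' @param kde_points Number of kernel-density evaluation points per region
#'   pair (default 512).
#' @param density_range Either `"auto"` (select the threshold range from the
#'   data via [select_threshold_range()]) or a length-2 numeric vector
#'   `c(k_min, k_max)` in percent fixing the range, e.g. `c(12, 39)`.
#' @param density_step Step of the density-threshold grid in percent.
#' @param density_window Scan window `c(lo, hi)` in percent for automatic
#'   range selection. Densities above 50% are outside the sparse regime in
#'   which binary brain-network topology is normally studied.
#' @param small_world_floor Minimum small-worldness sigma required of every
#'   subject at every retained threshold (default 1.1).
#' @param n_random Number of degree-preserving rewired surrogate networks
#'   used to normalise small-worldness.
#' @param nbs_edge_p Edge-level two-tailed p threshold for NBS.
#' @param nbs_permutations Number of NBS label permutations (the identity
#'   permutation is always included as the first).
#' @param nbs_alpha Familywise alpha for NBS component significance.
#' @param covariates Character vector of phenotype columns used as nuisance
#'   covariates in group statistics and partial correlations.
#' @param cv_folds Number of stratified cross-validation folds for the SVM.
#' @param svm_cost Linear-SVM cost parameter C.
#' @param seed Base seed for every stochastic step of a run.
#' @return A list with class `iscn_config`.
#' @export
iscn_config <- function(kde_points = 512L,
                        density_range = "auto",
                        density_step = 1,
                        density_window = c(1, 50),
                        small_world_floor = 1.1,
                        n_random = 20L,
                        nbs_edge_p = 0.001,
                        nbs_permutations = 10000L,
                        nbs_alpha = 0.05,
                        covariates = c("age", "gender"),
                        cv_folds = 10L,
                        svm_cost = 1,
                        seed = 0L) {
  stopifnot(kde_points >= 16, density_step > 0,
            small_world_floor > 0, n_random >= 1,
            nbs_edge_p > 0, nbs_edge_p < 1,
            nbs_permutations >= 1,
            nbs_alpha > 0, nbs_alpha < 1,
            cv_folds >= 2, svm_cost > 0)
  if (!identical(density_range, "auto")) {
    stopifnot(is.numeric(density_range), length(density_range) == 2,
              density_range[1] > 0, density_range[2] < 100,
              density_range[1] <= density_range[2])
  }
  stopifnot(length(density_window) == 2, density_window[1] > 0,
            density_window[2] < 100)
  structure(list(kde_points = as.integer(kde_points),
                 density_range = density_range,
                 density_step = density_step,
                 density_window = density_window,
                 small_world_floor = small_world_floor,
                 n_random = as.integer(n_random),
                 nbs_edge_p = nbs_edge_p,
                 nbs_permutations = as.integer(nbs_permutations),
                 nbs_alpha = nbs_alpha,
                 covariates = covariates,
                 cv_folds = as.integer(cv_folds),
                 svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "iscn_config")
}

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a JSON file whose keys are [iscn_config()] arguments.
#' @return An `iscn_config` object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(iscn_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(iscn_config, raw)
}
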