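#' Specification of a synthetic multi-site cohort
#'
#' Defines the ground truth of a simulated case-control study: Gaussian
#' voxel-value distributions per region, additive/multiplicative site
#' effects, group effects on designated regions and edges, linear age and
#' gender effects on voxel means, and a HAMD-17 symptom score coupled to one
#' designated edge's realised KLS. The Gaussian voxel model is chosen because
#' the Kullback-Leibler divergence between Gaussians has a closed form,
#' giving analytic oracles for the network-construction stage.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_sites Number of acquisition sites; subjects are assigned to sites
#'   in a balanced randomised fashion.
#' @param n_regions Number of atlas regions (desk-scale default 60; the
#'   pipeline equally supports 246).
#' @param voxels_per_region Voxels per parcel (scalar or per-region vector).
#' @param base_mean Per-region voxel-mean in control subjects. Default:
#'   evenly spaced over \[0.35, 0.85\], covering the plausible modulated-GMV
#'   range and guaranteeing region-to-region distributional diversity.
#' @param base_sd Per-region voxel SD (recycled; default 0.08).
#' @param site_shift Additive offset on voxel means per site. Default: evenly
#'   spaced over \[-0.03, 0.03\] (a few percent of typical GMV), emulating
#'   scanner/protocol offsets. Length `n_sites`.
#' @param site_scale Multiplicative factor on voxel SDs per site. Default:
#'   evenly spaced over \[0.85, 1.15\]. Length `n_sites`.
#' @param effect_regions List of `list(region =, delta =)`: patients' voxel
#'   mean in `region` is shifted by `delta`.
#' @param effect_edges List of `list(i =, j =, delta =)`: patients' region
#'   `i` mean is pulled toward (`delta` in (0, 1\]; 1 makes the means equal)
#'   or pushed away from (`delta < 0`) region `j`'s mean by the fraction
#'   `delta` of their separation.
#' @param age_slope Linear effect of age (years, centred at 40) on every
#'   region's voxel mean; default -0.001/year, mimicking grey-matter decline.
#' @param gender_offset Added to male subjects' voxel means (default 0.01).
#' @param age_range Uniform age range, default 18-65 (the study inclusion
#'   window).
#' @param hamd_edge `NULL` or `list(i =, j =, r =, mean =, sd =)`: patients'
#'   HAMD-17 is generated with true partial correlation `r` (controlling age
#'   and gender) with edge (i, j)'s realised KLS, scaled to `mean`/`sd`,
#'   clipped to \[18, 52\] (inclusion required HAMD-17 >= 18) and rounded to
#'   integers.
#' @param seed RNG seed; two calls with the same spec are bit-identical.
#' @return A list with class `simulation_spec`.
#' @export
simulation_spec <- function(n_patients = 60L, n_controls = 60L,
                            n_sites = 3L, n_regions = 60L,
                            voxels_per_region = 200L,
                            base_mean = NULL, base_sd = 0.08,
                            site_shift = NULL, site_scale = NULL,
                            effect_regions = list(), effect_edges = list(),
                            age_slope = -0.001, gender_offset = 0.01,
                            age_range = c(18, 65),
                            hamd_edge = NULL, seed = 0L) {
  n_regions <- as.integer(n_regions)
  base_mean <- base_mean %||% seq(0.35, 0.85, length.out = n_regions)
  base_sd <- rep_len(base_sd, n_regions)
  site_shift <- site_shift %||%
    (if (n_sites == 1) 0 else seq(-0.03, 0.03, length.out = n_sites))
  site_scale <- site_scale %||%
    (if (n_sites == 1) 1 else seq(0.85, 1.15, length.out = n_sites))
  stopifnot(n_patients >= 1, n_controls >= 1, n_sites >= 1,
            n_regions >= 2, all(voxels_per_region >= 2),
            length(base_mean) == n_regions,
            all(base_sd > 0),
            length(site_shift) == n_sites, length(site_scale) == n_sites,
            all(site_scale > 0))
  check_region <- function(r, what) {
    if (!all(r >= 1 & r <= n_regions)) {
      stop(what, " index outside 1..", n_regions, ": ",
           paste(r[!(r >= 1 & r <= n_regions)], collapse = ", "))
    }
  }
  for (e in effect_regions) check_region(e$region, "effect region")
  for (e in effect_edges) check_region(c(e$i, e$j), "effect edge")
  if (!is.null(hamd_edge)) {
    check_region(c(hamd_edge$i, hamd_edge$j), "hamd edge")
    hamd_edge$r <- hamd_edge$r %||% 0.3
    hamd_edge$mean <- hamd_edge$mean %||% 30
    hamd_edge$sd <- hamd_edge$sd %||% 6
    stopifnot(abs(hamd_edge$r) < 1)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_sites = as.integer(n_sites),
                 n_regions = n_regions,
                 voxels_per_region = rep_len(as.integer(voxels_per_region), n_regions),
                 base_mean = base_mean, base_sd = base_sd,
                 site_shift = site_shift, site_scale = site_scale,
                 effect_regions = effect_regions, effect_edges = effect_edges,
                 age_slope = age_slope, gender_offset = gender_offset,
                 age_range = age_range, hamd_edge = hamd_edge,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a multi-site grey-matter cohort with known ground truth
#'
#' Voxel values for subject s in region r are drawn from
#' `Normal(base_mean_r + group/edge effects + age/gender terms + site_shift,
#' (base_sd_r * site_scale)^2)`. Patients' HAMD-17 (when `hamd_edge` is set)
#' is coupled to the realised KLS of the designated edge: the edge KLS is
#' residualised against age and gender across patients, standardised, and
#' the score is `mean + sd * (r * z + sqrt(1 - r^2) * noise)`, clipped to
#' \[18, 52\] and rounded — so the population partial correlation between
#' score and edge KLS given age and gender equals `r` up to the (small)
#' clipping/rounding attenuation.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `samples` (named list of
#'   [regional_samples()]), `phenotype` (data.frame), `assignment` (synthetic
#'   region-to-network lookup, regions dealt cyclically across the 7 Yeo
#'   networks plus a subcortical bucket), and `truth` (every injected effect,
#'   for recovery tests).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_patients + spec$n_controls
  ids <- sprintf("S%04d", seq_len(n))
  group <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  ## balanced randomised site assignment within each group
  site_of <- function(m) sample(rep_len(seq_len(spec$n_sites), m))
  site <- c(site_of(spec$n_patients), site_of(spec$n_controls))
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  gender <- sample(c("male", "female"), n, replace = TRUE)
  episode <- ifelse(group == "control", "control",
                    sample(c("first_episode_drug_naive", "recurrent", "other"),
                           n, replace = TRUE, prob = c(0.3, 0.25, 0.45)))

  ## per-subject, per-region means
  mu <- matrix(rep(spec$base_mean, each = n), nrow = n)
  for (e in spec$effect_regions) {
    mu[group == "patient", e$region] <- mu[group == "patient", e$region] + e$delta
  }
  for (e in spec$effect_edges) {
    pull <- e$delta * (spec$base_mean[e$j] - spec$base_mean[e$i])
    mu[group == "patient", e$i] <- mu[group == "patient", e$i] + pull
  }
  mu <- mu + spec$age_slope * (age - 40) +
    spec$gender_offset * (gender == "male") +
    spec$site_shift[site]
  sdmat <- matrix(rep(spec$base_sd, each = n), nrow = n) * spec$site_scale[site]

  region_ids <- seq_len(spec$n_regions)
  samples <- vector("list", n)
  for (s in seq_len(n)) {
    vox <- lapply(region_ids, function(r) {
      rnorm(spec$voxels_per_region[r], mu[s, r], sdmat[s, r])
    })
    samples[[s]] <- regional_samples(ids[s], region_ids, vox)
  }
  names(samples) <- ids

  hamd <- rep(NA_integer_, n)
  truth_hamd <- NULL
  if (!is.null(spec$hamd_edge)) {
    he <- spec$hamd_edge
    pat <- which(group == "patient")
    k <- vapply(pat, function(s) {
      kls_pair(samples[[s]]$samples[[he$i]], samples[[s]]$samples[[he$j]])
    }, numeric(1))
    ## impose the target partial correlation exactly in-sample: couple the
    ## score to the covariate-residualised edge KLS and orthogonalise the
    ## noise against both the covariates and the signal (up to the small
    ## attenuation from clipping to [18, 52] and integer rounding)
    cov_p <- cbind(age[pat], gender[pat] == "male")
    z <- resid(lm(k ~ cov_p))
    z <- if (sd(z) > 0) z / sd(z) else z
    e <- rnorm(length(pat))
    if (length(pat) >= 8 && sd(z) > 0) {
      e <- resid(lm(e ~ cov_p + z))
      e <- e / sd(e)
    }
    raw <- he$mean + he$sd * (he$r * z + sqrt(1 - he$r^2) * e)
    hamd[pat] <- as.integer(round(pmin(pmax(raw, 18), 52)))
    truth_hamd <- list(i = he$i, j = he$j, partial_r = he$r,
                      mean = he$mean, sd = he$sd, realized_kls = k)
  }

  phenotype <- data.frame(subject_id = ids, group = group,
                          site = sprintf("site%02d", site),
                          age = age, gender = gender,
                          hamd17 = hamd, episode = episode,
                          stringsAsFactors = FALSE)

  networks <- c("DMN", "VAN", "VN", "DAN", "SMN", "FPN", "LN", "subcortical")
  assignment <- data.frame(
    region_id = region_ids,
    network = networks[((region_ids - 1) %% length(networks)) + 1],
    stringsAsFactors = FALSE)

  list(samples = samples, phenotype = phenotype, assignment = assignment,
       truth = list(spec = spec,
                    effect_regions = spec$effect_regions,
                    effect_edges = spec$effect_edges,
                    site_shift = spec$site_shift,
                    site_scale = spec$site_scale,
                    age_slope = spec$age_slope,
                    gender_offset = spec$gender_offset,
                    hamd = truth_hamd))
}
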