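#' Regional voxel samples for one subject
#'
#' The raw material of an iSCN: for each atlas region, the vector of
#' modulated grey-matter-volume (GMV) values of the voxels inside the parcel.
#'
#' @param subject_id Subject identifier.
#' @param region_ids Integer parcel labels, ascending, one per region.
#' @param samples List of numeric vectors, one per region, aligned with
#'   `region_ids`. Every region needs at least 2 voxels and no NaN/NA.
#' @return An object of class `regional_samples`.
#' @export
regional_samples <- function(subject_id, region_ids, samples) {
  region_ids <- as.integer(region_ids)
  stopifnot(length(region_ids) == length(samples),
            !is.unsorted(region_ids, strictly = TRUE))
  for (k in seq_along(samples)) {
    v <- samples[[k]]
    if (!is.numeric(v) || length(v) < 2) {
      stop("region ", region_ids[k], " has fewer than 2 voxels")
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("region ", region_ids[k], " contains non-finite voxel values")
    }
    samples[[k]] <- as.numeric(v)
  }
  names(samples) <- sprintf("r%03d", region_ids)
  structure(list(subject_id = as.character(subject_id),
                 region_ids = region_ids,
                 samples = samples),
            class = "regional_samples")
}

#' @export
print.regional_samples <- function(x, ...) {
  nv <- lengths(x$samples)
  cat(sprintf("<regional_samples> subject %s: %d regions, %d-%d voxels/region\n",
              x$subject_id, length(x$region_ids), min(nv), max(nv)))
  invisible(x)
}

#' Extract regional voxel samples from a GMV map and a parcellation atlas
#'
#' Pulls, for every nonzero atlas label, the GMV values of the voxels carrying
#' that label. Label 0 is background. The two images must live on the same
#' voxel grid; resampling belongs to preprocessing and is deliberately not
#' performed here.
#'
#' @param gmv 3D numeric array of modulated GMV values, or the path to a
#'   NIfTI file.
#' @param atlas 3D integer-labelled array on the same grid, or a NIfTI path.
#' @param subject_id Identifier recorded in the result.
#' @param drop_zero If `TRUE`, voxels with GMV exactly 0 are excluded from a
#'   parcel's distribution; by default all in-parcel voxels are kept.
#' @param expected_labels Optional integer vector of parcel labels the atlas
#'   must contain; a listed label covering no voxels is a hard error (by
#'   default the label set is taken from the atlas itself).
#' @return A [regional_samples()] object with regions in ascending label
#'   order.
#' @export
extract_regional_samples <- function(gmv, atlas, subject_id = "subject",
                                     drop_zero = FALSE,
                                     expected_labels = NULL) {
  if (is.character(gmv)) gmv <- as.array(RNifti::readNifti(gmv))
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  gmv <- as.array(gmv)
  atlas <- as.array(atlas)
  if (!identical(dim(gmv), dim(atlas))) {
    stop(sprintf("image/atlas grid mismatch: GMV is %s, atlas is %s",
                 paste(dim(gmv), collapse = "x"),
                 paste(dim(atlas), collapse = "x")))
  }
  lab <- as.integer(atlas)
  if (any(lab < 0, na.rm = TRUE)) stop("atlas labels must be non-negative integers")
  labels <- sort(unique(lab[lab > 0]))
  if (!is.null(expected_labels)) {
    absent <- setdiff(as.integer(expected_labels), labels)
    if (length(absent) > 0) {
      stop("atlas label ", paste(absent, collapse = ", "),
           " covers fewer than 2 usable voxels")
    }
    labels <- sort(as.integer(expected_labels))
  }
  if (length(labels) == 0) stop("atlas contains no nonzero labels")
  vals <- as.numeric(gmv)
  samples <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    v <- vals[lab == labels[k]]
    if (drop_zero) v <- v[v != 0]
    if (length(v) < 2) {
      stop("atlas label ", labels[k], " covers fewer than 2 usable voxels")
    }
    if (anyNA(v)) stop("NaN GMV values inside atlas label ", labels[k])
    samples[[k]] <- v
  }
  regional_samples(subject_id, labels, samples)
}

#' Write a cohort of regional voxel samples to a plain-text archive
#'
#' One TSV of (subject, region, voxel_value) triples for the whole cohort,
#' plus a JSON sidecar recording subject order and the shared region
#' ordering. Values are serialised with 17 significant digits so the
#' round-trip is bit-exact.
#'
#' @param cohort Named list of [regional_samples()] (names = subject ids) or
#'   an unnamed list (subject ids taken from the objects).
#' @param path Basename for the archive; writes `<path>.tsv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_samples_archive <- function(cohort, path) {
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  stopifnot(!anyDuplicated(ids))
  region_ids <- cohort[[1]]$region_ids
  for (s in cohort) {
    if (!identical(s$region_ids, region_ids)) {
      stop("subject ", s$subject_id, " has a different region ordering")
    }
  }
  tabs <- lapply(cohort, function(s) {
    data.table::data.table(
      subject = s$subject_id,
      region = rep(s$region_ids, lengths(s$samples)),
      voxel_value = sprintf("%.17g", unlist(s$samples, use.names = FALSE)))
  })
  data.table::fwrite(data.table::rbindlist(tabs), paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(list(subjects = ids, region_ids = region_ids),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read a cohort archive written by [write_samples_archive()]
#'
#' @param path Archive basename (without extension).
#' @return Named list of [regional_samples()], in sidecar subject order.
#' @export
read_samples_archive <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- data.table::fread(paste0(path, ".tsv"), sep = "\t",
                           colClasses = list(character = "voxel_value"))
  region_ids <- as.integer(side$region_ids)
  out <- lapply(side$subjects, function(id) {
    sub <- tab[tab$subject == id, ]
    samples <- lapply(region_ids, function(r) {
      as.numeric(sub$voxel_value[sub$region == r])
    })
    regional_samples(id, region_ids, samples)
  })
  names(out) <- side$subjects
  out
}

#' Read and validate a phenotype table
#'
#' Requires columns `subject_id`, `group`, `site`, `age`, `gender`; any
#' further columns (e.g. `hamd17`, `episode`, `TIV`) are preserved and can be
#' selected as additional covariates downstream.
#'
#' @param path TSV or CSV file (separator inferred from content).
#' @return A `data.frame`, one row per subject.
#' @export
read_phenotype <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  required <- c("subject_id", "group", "site", "age", "gender")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("phenotype table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicate subject_id in phenotype table: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  }
  validate_phenotype(tab)
  tab$subject_id <- as.character(tab$subject_id)
  tab$site <- as.character(tab$site)
  tab
}

validate_phenotype <- function(tab) {
  if (!all(tab$group %in% c("patient", "control"))) {
    stop("phenotype 'group' must be 'patient' or 'control'")
  }
  if (!all(tab$gender %in% c("male", "female"))) {
    stop("phenotype 'gender' must be 'male' or 'female'")
  }
  if (!is.numeric(tab$age)) stop("phenotype 'age' must be numeric")
  invisible(tab)
}

#' Read a region-to-functional-network lookup table
#'
#' Maps every parcel to one of the seven canonical Yeo intrinsic functional
#' networks (DMN, VAN, VN, DAN, SMN, FPN, LN) or the subcortical bucket.
#'
#' @param path TSV with columns `region_id` and `network`.
#' @param region_ids If given, every listed region must be assigned exactly
#'   once.
#' @return A `data.frame` with integer `region_id` and character `network`.
#' @export
read_network_assignment <- function(path, region_ids = NULL) {
  tab <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("region_id", "network") %in% names(tab)))
  tab$region_id <- as.integer(tab$region_id)
  tab$network <- as.character(tab$network)
  if (anyDuplicated(tab$region_id)) {
    stop("region assigned to more than one network: ",
         paste(tab$region_id[duplicated(tab$region_id)], collapse = ", "))
  }
  if (!is.null(region_ids)) {
    missing <- setdiff(as.integer(region_ids), tab$region_id)
    if (length(missing) > 0) {
      stop("regions without a network assignment: ",
           paste(missing, collapse = ", "))
    }
  }
  tab
}
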