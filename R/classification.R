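## Stratified fold assignment: within each class, subjects are shuffled and
## dealt round-robin across folds.
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Linear-SVM classification with stratified cross-validation
#'
#' Trains a linear support vector machine (C-classification, cost `cost`)
#' under seeded stratified k-fold cross-validation. Features are
#' standardised with training-fold statistics only (no leakage into the test
#' fold). Test-fold predictions are pooled for accuracy, sensitivity and
#' specificity; ROC AUC is computed from the pooled decision scores. The
#' mean absolute weight of each feature across folds is retained for region
#' mapping.
#'
#' @param features Numeric matrix, subjects x features (named columns).
#' @param labels Factor or character with levels `patient`/`control`
#'   (`patient` is the positive class).
#' @param folds Number of stratified folds (default 10); each class needs at
#'   least `folds` members.
#' @param cost SVM cost parameter C (default 1).
#' @param seed Seed for the fold assignment.
#' @return Object of class `classification_report`: list with `metrics`
#'   (accuracy/sensitivity/specificity in percent, `auc`, 95% CI of
#'   accuracy across folds), `confusion`, `fold_accuracy`,
#'   `mean_abs_weight` (named per feature), `predictions` and `fold`.
#' @export
svm_classify <- function(features, labels, folds = 10, cost = 1, seed = 0) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("control", "patient"))
  if (anyNA(labels)) stop("labels must be 'patient' or 'control'")
  if (nlevels(droplevels(labels)) < 2) stop("need two classes to classify")
  if (any(table(labels) < folds)) {
    stop("every class needs >= ", folds, " members for ", folds, "-fold CV")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("feature%03d", seq_len(ncol(features)))
  }
  fold <- stratified_folds(labels, folds, seed)

  pred <- factor(rep(NA_character_, length(labels)),
                 levels = levels(labels))
  score <- numeric(length(labels))
  absw <- matrix(0, folds, ncol(features),
                 dimnames = list(NULL, colnames(features)))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    xt <- sweep(sweep(features, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xt[tr, , drop = FALSE], labels[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    absw[f, ] <- abs(w)
    pr <- predict(fit, xt[!tr, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    ## orient decision values so larger = more patient-like
    pos_first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
    if (pos_first != "patient") dv <- -dv
    pred[!tr] <- pr
    score[!tr] <- dv
    fold_acc[f] <- mean(pr == labels[!tr])
  }

  confusion <- table(predicted = pred, truth = labels)
  tp <- confusion["patient", "patient"]
  tn <- confusion["control", "control"]
  fp <- confusion["patient", "control"]
  fn <- confusion["control", "patient"]
  roc <- pROC::roc(response = labels, predictor = score,
                   levels = c("control", "patient"), direction = "<",
                   quiet = TRUE)
  ci <- mean(fold_acc) + c(-1, 1) * 1.96 * sd(fold_acc) / sqrt(folds)
  structure(list(
    metrics = c(accuracy = 100 * (tp + tn) / length(labels),
                sensitivity = 100 * tp / (tp + fn),
                specificity = 100 * tn / (tn + fp),
                auc = as.numeric(pROC::auc(roc)),
                accuracy_ci_low = 100 * ci[1],
                accuracy_ci_high = 100 * ci[2]),
    confusion = confusion,
    fold_accuracy = fold_acc,
    mean_abs_weight = colMeans(absw),
    predictions = pred,
    decision_scores = score,
    fold = fold,
    folds = folds, cost = cost, seed = seed),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<classification_report> accuracy %.1f%% ",
                     "(95%% CI %.1f-%.1f%%), sensitivity %.1f%%, ",
                     "specificity %.1f%%, AUC %.3f\n"),
              m["accuracy"], m["accuracy_ci_low"], m["accuracy_ci_high"],
              m["sensitivity"], m["specificity"], m["auc"]))
  invisible(x)
}

#' Map SVM feature weights to the top contributing regions
#'
#' Aggregates the mean absolute SVM weights to the region level. In
#' `topology` mode a region's score is the mean of the mean-|w| of its three
#' centrality features (`deg_`, `btw_`, `eig_`); global-metric features are
#' excluded from region mapping. In `connectivity` mode the score is the
#' mean of mean-|w| over the `R - 1` edges incident to the region. Ties are
#' broken by ascending region id.
#'
#' @param report A `classification_report` (or a named mean-|w| vector).
#' @param mode `"topology"` or `"connectivity"`; feature names must follow
#'   the package conventions (`deg_r001` / `edge_r001_r002`).
#' @param n_top Number of regions returned (default 10).
#' @return Data frame: rank, region_id, score.
#' @export
map_region_contributions <- function(report, mode = c("topology", "connectivity"),
                                     n_top = 10) {
  mode <- match.arg(mode)
  w <- if (inherits(report, "classification_report")) {
    report$mean_abs_weight
  } else {
    report
  }
  nm <- names(w)
  if (mode == "topology") {
    sel <- grepl("^(deg|btw|eig)_r\\d+$", nm)
    global <- c("global_efficiency", "clustering_coefficient",
                "small_worldness", "modularity", "assortativity")
    bad <- nm[!sel & !nm %in% global]
    if (length(bad) > 0) {
      stop("unparseable topology feature name(s): ",
           paste(head(bad, 5), collapse = ", "))
    }
    region <- as.integer(sub("^(deg|btw|eig)_r", "", nm[sel]))
    score <- tapply(w[sel], region, mean)
  } else {
    sel <- grepl("^edge_r\\d+_r\\d+$", nm)
    if (!all(sel)) {
      stop("unparseable connectivity feature name(s): ",
           paste(head(nm[!sel], 5), collapse = ", "))
    }
    i <- as.integer(sub("^edge_r(\\d+)_r\\d+$", "\\1", nm))
    j <- as.integer(sub("^edge_r\\d+_r(\\d+)$", "\\1", nm))
    score <- tapply(c(w, w), c(i, j), mean)
  }
  region_id <- as.integer(names(score))
  ord <- order(-score, region_id)
  top <- head(ord, n_top)
  data.frame(rank = seq_along(top),
             region_id = region_id[top],
             score = unname(score[top]))
}
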