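# Tumor/normal classification on a gene panel. Tumor samples are split into
# normal-sized subgroups to balance classes, each subgroup (plus all normals)
# gets stratified k-fold cross-validation with a Gaussian-kernel SVM, and the
# held-out decision scores are pooled into one ROC/AUC (per-subgroup AUCs are
# also reported).

#' Partition tumors into class-balanced subgroups
#'
#' Random partition of the tumor samples into `ceiling(n_tumor / n_normal)`
#' subgroups whose sizes differ by at most 1, so each subgroup is about the
#' size of the normal cohort. Deterministic under `seed`.
#'
#' @param tumor_ids character vector of tumor sample ids.
#' @param n_normal size of the normal cohort (>= 2).
#' @param seed integer seed.
#' @return Named integer vector: tumor id -> subgroup index.
#' @export
make_balanced_subgroups <- function(tumor_ids, n_normal, seed = 1L) {
  if (n_normal < 2) ssnet_error("n_normal must be >= 2", "ssnet_config_error")
  m <- length(tumor_ids)
  n_sub <- max(1L, ceiling(m / n_normal))
  with_sim_seed(seed, {
    shuffled <- tumor_ids[sample.int(m)]
    base <- m %/% n_sub
    extra <- m %% n_sub
    sizes <- rep(base, n_sub) + c(rep(1L, extra), rep(0L, n_sub - extra))
    assignment <- rep(seq_len(n_sub), times = sizes)
    stats::setNames(assignment, shuffled)[tumor_ids]
  })
}

auc_from_scores <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, positive) {
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) mean(scores[positive] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!positive] >= t), numeric(1))
  data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      ssnet_error(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                          cl, length(idx), k), "ssnet_stratification_error")
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated tumor/normal classification with ROC/AUC
#'
#' Splits the tumors into class-balanced subgroups
#' ([make_balanced_subgroups()]), then for each subgroup plus all normal
#' samples runs stratified `folds`-fold cross-validation with a
#' Gaussian-kernel SVM ([kernlab::ksvm()] with the default bandwidth
#' heuristic and unit cost). Held-out decision scores are pooled across
#' subgroups; the ROC is traced by sweeping the score threshold and the AUC
#' computed by the trapezoid rule (rank form). Score orientation is fixed per
#' fold from the training data only.
#'
#' @param expr_subset an [expression_matrix()] restricted to the gene panel
#'   (e.g. core functional genes).
#' @param labels optional named class vector (default: the matrix's
#'   `sample_class`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the subgroup partition and fold assignment.
#' @return A `classification_result`: list with `scores` (data.frame
#'   `sample_id`, `subgroup`, `fold`, `score`, `label`), `roc` (pooled ROC
#'   points), `auc` (pooled), `auc_by_subgroup`, `subgroups`, `seed`.
#' @export
crossval_auc <- function(expr_subset, labels = NULL, folds = 5, seed = 1L) {
  stopifnot(inherits(expr_subset, "expression_matrix"))
  labels <- labels %||% expr_subset$sample_class
  labels <- labels[expr_subset$sample_ids]
  if (!all(labels %in% c("tumor", "normal"))) {
    ssnet_error("labels must be tumor/normal", "ssnet_labeling_error")
  }
  tumor_ids <- names(labels)[labels == "tumor"]
  normal_ids <- names(labels)[labels == "normal"]
  if (!length(tumor_ids) || !length(normal_ids)) {
    ssnet_error("both classes required", "ssnet_labeling_error")
  }
  subgroups <- make_balanced_subgroups(tumor_ids, length(normal_ids), seed)
  xt <- t(expr_subset$values)  # samples x genes

  results <- list()
  with_sim_seed(seed + 1L, {
    for (sg in sort(unique(subgroups))) {
      ids <- c(names(subgroups)[subgroups == sg], normal_ids)
      y <- factor(labels[ids], levels = c("normal", "tumor"))
      fold <- stratified_folds(as.character(y), folds)
      score <- numeric(length(ids))
      for (f in seq_len(folds)) {
        train <- fold != f
        fit <- kernlab::ksvm(xt[ids[train], , drop = FALSE], y[train],
                             kernel = "rbfdot", C = 1, scaled = TRUE)
        dec_train <- kernlab::predict(fit, xt[ids[train], , drop = FALSE],
                                      type = "decision")[, 1]
        flip <- mean(dec_train[y[train] == "tumor"]) <
          mean(dec_train[y[train] == "normal"])
        dec <- kernlab::predict(fit, xt[ids[!train], , drop = FALSE],
                                type = "decision")[, 1]
        score[!train] <- if (flip) -dec else dec
      }
      results[[as.character(sg)]] <- data.frame(
        sample_id = ids, subgroup = sg, fold = fold, score = score,
        label = as.character(y), stringsAsFactors = FALSE)
    }
  })
  pooled <- do.call(rbind, results)
  rownames(pooled) <- NULL
  pos <- pooled$label == "tumor"
  auc_by_sg <- vapply(results, function(r) {
    auc_from_scores(r$score, r$label == "tumor")
  }, numeric(1))
  structure(list(scores = pooled,
                 roc = roc_points(pooled$score, pos),
                 auc = auc_from_scores(pooled$score, pos),
                 auc_by_subgroup = auc_by_sg,
                 subgroups = subgroups, seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification_result: pooled AUC = %.5f over %d subgroups (%s)\n",
              x$auc, length(x$auc_by_subgroup),
              paste(sprintf("%.3f", x$auc_by_subgroup), collapse = ", ")))
  invisible(x)
}

#' Hierarchical clustering of samples on a gene panel
#'
#' Agglomerative clustering of samples with distance `1 - Pearson
#' correlation` between sample expression profiles and average linkage;
#' returns the merge tree and leaf order for heat-map export.
#'
#' @param expr_subset an [expression_matrix()] with >= 2 samples.
#' @param method linkage method passed to [stats::hclust()].
#' @return An object of class `hclust` (merge heights in `$height`, leaf
#'   order in `$order`, sample ids in `$labels`).
#' @export
hierarchical_cluster <- function(expr_subset, method = "average") {
  stopifnot(inherits(expr_subset, "expression_matrix"))
  if (length(expr_subset$sample_ids) < 2) {
    ssnet_error("need >= 2 samples to cluster", "ssnet_config_error")
  }
  sds <- apply(expr_subset$values, 2, stats::sd)
  if (any(sds == 0)) {
    ssnet_error("constant sample vector: correlation distance undefined",
                "ssnet_degenerate_edge_error")
  }
  d <- stats::as.dist(1 - stats::cor(expr_subset$values))
  stats::hclust(d, method = method)
}
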