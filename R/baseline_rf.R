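#' Random-forest baseline configuration
#'
#' Defaults mirror the study's forest: 500 trees, mtry 200,
#' impurity-corrected importance, 100 permutations both for the Altmann
#' feature p-values and for the prAUC significance.
#'
#' @param n_trees number of trees.
#' @param mtry variables tried at each split (must not exceed the number of
#'   features).
#' @param importance_mode passed to ranger (default "impurity_corrected",
#'   required by the Altmann method).
#' @param n_perm_importance label permutations for the Altmann p-values.
#' @param n_perm_prauc label permutations for the prAUC significance.
#' @param seed seed.
#' @return an `rf_config`.
#' @export
rf_config <- function(n_trees = 500L, mtry = 200L,
                      importance_mode = "impurity_corrected",
                      n_perm_importance = 100L, n_perm_prauc = 100L,
                      seed = 1L) {
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 importance_mode = importance_mode,
                 n_perm_importance = as.integer(n_perm_importance),
                 n_perm_prauc = as.integer(n_perm_prauc),
                 seed = as.integer(seed)), class = "rf_config")
}

#' Build the TFBS count feature table
#'
#' Counts putative binding sites of each library motif in the 1000 bp
#' upstream window of every gene (both strands by default) and appends a
#' total-count column, one feature per motif plus the total (413 features for
#' the canonical 412-motif library).
#'
#' @param windows named character vector: gene id -> 1000 bp upstream window.
#' @param tfbs_library named character vector of consensus sequences, or list
#'   of objects with `id` and `consensus`.
#' @param both_strands count matches on both strands (default TRUE).
#' @return integer matrix, genes x (motifs + total).
#' @export
build_feature_table <- function(windows, tfbs_library, both_strands = TRUE) {
  if (is.list(tfbs_library)) {
    ids <- vapply(tfbs_library, `[[`, "", "id")
    cons <- vapply(tfbs_library, `[[`, "", "consensus")
  } else {
    cons <- as.character(tfbs_library)
    ids <- names(tfbs_library)
    if (is.null(ids)) ids <- sprintf("tf%03d", seq_along(cons))
  }
  ss <- DNAStringSet(windows)
  counts <- matrix(0L, length(windows), length(cons),
                   dimnames = list(names(windows), ids))
  for (j in seq_along(cons)) {
    cnt <- vcountPattern(cons[j], ss)
    rc <- .revcomp(cons[j])
    if (both_strands && rc != cons[j]) cnt <- cnt + vcountPattern(rc, ss)
    counts[, j] <- cnt
  }
  cbind(counts, total = rowSums(counts))
}

.rf_fit <- function(df, config, seed) {
  ranger::ranger(label ~ ., data = df, num.trees = config$n_trees,
                 mtry = min(config$mtry, ncol(df) - 1L),
                 importance = config$importance_mode,
                 probability = TRUE, seed = seed)
}

.rf_oob_prauc <- function(rf, labels, positive) {
  score <- rf$predictions[, positive]
  ok <- !is.na(score)
  pr_auc(score[ok], labels[ok] == positive)
}

#' Fit the random-forest baseline and assess its significance
#'
#' Fits a probability forest on the feature table, reports the out-of-bag
#' misclassification error, per-feature Altmann permutation p-values (the
#' fraction of label-permuted importances at least as large as the observed
#' one), the prAUC of the out-of-bag scores with the DEG class as positive,
#' and a permutation p-value for that prAUC obtained by refitting under
#' shuffled labels.
#'
#' @param table feature matrix or data.frame (genes x features).
#' @param labels binary factor; the first level is treated as the DEG
#'   (positive) class unless `positive` says otherwise.
#' @param config an [rf_config()].
#' @param positive the positive class label (default `levels(labels)[1]`).
#' @return an `rf_eval` list: oob_error, importance (matrix with importance
#'   and pvalue columns), prauc, prauc_perm (null prAUCs), prauc_perm_p.
#' @export
fit_and_evaluate <- function(table, labels, config = rf_config(),
                             positive = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two classes, got ", nlevels(labels))
  if (is.null(positive)) positive <- levels(labels)[1L]
  if (config$mtry > ncol(table))
    stop("mtry (", config$mtry, ") exceeds the number of features (",
         ncol(table), ")")
  df <- data.frame(label = labels, as.data.frame(table),
                   check.names = TRUE)
  rf <- .rf_fit(df, config, config$seed)

  imp <- ranger::importance_pvalues(
    rf, method = "altmann", formula = label ~ ., data = df,
    num.permutations = config$n_perm_importance, seed = config$seed)

  pred_class <- colnames(rf$predictions)[max.col(rf$predictions,
                                                 ties.method = "first")]
  ok <- !is.na(rf$predictions[, 1L])
  oob_error <- mean(pred_class[ok] != as.character(labels[ok]))

  prauc <- .rf_oob_prauc(rf, labels, positive)
  perm <- numeric(config$n_perm_prauc)
  set.seed(config$seed + 1L)
  perm_seeds <- sample.int(.Machine$integer.max %/% 2L, config$n_perm_prauc)
  for (i in seq_len(config$n_perm_prauc)) {
    dfi <- df
    set.seed(perm_seeds[i])
    dfi$label <- sample(dfi$label)
    rfi <- .rf_fit(dfi, config, perm_seeds[i])
    perm[i] <- .rf_oob_prauc(rfi, dfi$label, positive)
  }
  structure(list(oob_error = oob_error, importance = imp, prauc = prauc,
                 prauc_perm = perm,
                 prauc_perm_p = mean(perm >= prauc),
                 positive = positive, config = config),
            class = "rf_eval")
}

#' @export
print.rf_eval <- function(x, ...) {
  cat("<rf_eval> OOB error:", round(x$oob_error, 4),
      "| prAUC (", x$positive, "positive ):", round(x$prauc, 4),
      "| permutation p:", x$prauc_perm_p, "\n")
  invisible(x)
}
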