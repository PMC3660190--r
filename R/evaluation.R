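#' Cross-validated SVM decision values for a gene panel
#'
#' Stratified k-fold cross-validation: every sample is scored exactly once
#' by a linear SVM that never saw it; features are standardized per training
#' fold.  When the smaller class has fewer samples than `k_folds`, the split
#' falls back to leave-one-out.
#'
#' @param ds A labeled `expression_dataset`.
#' @param panel Character vector of gene ids to use (default: all genes).
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM soft-margin cost (shared convention with the selection
#'   stage).
#' @return Numeric vector of decision values (larger = case), one per
#'   sample, with attribute `folds` (per-sample fold ids).
#' @export
cross_val_scores <- function(ds, panel = NULL, k_folds = 5L, seed = 1L,
                             cost = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(unique(ds$labels)) < 2L) stop("both classes required")
  if (is.null(panel)) panel <- ds$gene_ids
  sub <- subset_dataset(ds, genes = panel)
  y <- sub$labels
  n <- length(y)
  if (min(table(y)) < k_folds) k_folds <- n      # leave-one-out fallback
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- integer(n)
  if (k_folds >= n) {
    folds <- seq_len(n)
  } else {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  }
  X <- t(sub$values)
  scores <- numeric(n)
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    Xs <- .standardize_by_train(X, train)
    fit <- fit_svm(Xs[train, , drop = FALSE], y[train], cost = cost)
    scores[test] <- svm_decision_values(fit, Xs[test, , drop = FALSE])
  }
  structure(scores, folds = folds, names = sub$sample_ids)
}

#' ROC curve and AUC from decision values
#'
#' The AUC is the Mann-Whitney pair-counting probability that a random case
#' outscores a random control, ties counting one half.  The curve enumerates
#' all distinct thresholds (tied scores grouped), starts at (0, 0) and ends
#' at (1, 1); its trapezoidal area equals the pair-counting AUC exactly.
#'
#' @param scores Numeric decision values (larger = case).
#' @param labels Binary 0/1 labels.
#' @return A `roc_result` with fields `auc`, `curve` (data frame `fpr`,
#'   `tpr`, `threshold`), `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required")
  # pair counting via midranks (ties -> 1/2)
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # curve over distinct thresholds, descending
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  curve <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
                      threshold = c(Inf, thr))
  structure(list(auc = auc, curve = curve, n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.5f (%d case vs %d control, %d curve points)\n",
              x$auc, x$n_case, x$n_control, nrow(x$curve)))
  invisible(x)
}

#' Cross-validated ROC/AUC of a panel
#'
#' Convenience wrapper: pools the cross-validated decision values from
#' [cross_val_scores()] into one ROC and also reports per-fold AUCs (folds
#' lacking a class are skipped in the per-fold list).
#'
#' @inheritParams cross_val_scores
#' @return A `roc_result` with extra fields `fold_assignments` and
#'   `fold_aucs`.
#' @export
evaluate_panel <- function(ds, panel = NULL, k_folds = 5L, seed = 1L,
                           cost = 1) {
  scores <- cross_val_scores(ds, panel, k_folds, seed, cost)
  folds <- attr(scores, "folds")
  roc <- roc_auc(as.numeric(scores), ds$labels)
  fold_aucs <- vapply(sort(unique(folds)), function(f) {
    sel <- folds == f
    if (length(unique(ds$labels[sel])) < 2L) return(NA_real_)
    roc_auc(as.numeric(scores)[sel], ds$labels[sel])$auc
  }, numeric(1))
  roc$fold_assignments <- folds
  roc$fold_aucs <- fold_aucs[!is.na(fold_aucs)]
  roc
}
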