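#' Confusion counts and classification metrics
#'
#' `confusion_counts()` tallies TP/TN/FP/FN from predicted and true labels
#' (responder is the positive class); `confusion_metrics()` evaluates
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/N`.  A zero denominator yields `NaN` with the corresponding
#' `undefined_*` flag set rather than an error, so degenerate folds are
#' reported, not lost.
#'
#' @param predicted,actual Character vectors of `responder` /
#'   `non_responder` calls for the same samples.
#' @return `confusion_counts`: list with `TP`, `TN`, `FP`, `FN`, `N`.
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("`predicted` and `actual` must have equal length", call. = FALSE)
  pos_p <- predicted == "responder"; pos_a <- actual == "responder"
  list(TP = sum(pos_p & pos_a), TN = sum(!pos_p & !pos_a),
       FP = sum(pos_p & !pos_a), FN = sum(!pos_p & pos_a),
       N = length(actual))
}

#' @rdname confusion_counts
#' @param counts List with elements `TP`, `TN`, `FP`, `FN`, `N`.
#' @return `confusion_metrics`: list with `sensitivity`, `specificity`,
#'   `accuracy`, `undefined_sensitivity`, `undefined_specificity`.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    if (N == 0) stop("empty evaluation: no predicted samples", call. = FALSE)
    if (TP + TN + FP + FN != N)
      stop("confusion counts do not sum to N", call. = FALSE)
    sens <- if (TP + FN == 0) NaN else TP / (TP + FN)
    spec <- if (TN + FP == 0) NaN else TN / (TN + FP)
    list(sensitivity = sens, specificity = spec,
         accuracy = (TP + TN) / N,
         undefined_sensitivity = TP + FN == 0,
         undefined_specificity = TN + FP == 0)
  })
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a cutoff (ties grouped), accumulating
#' (false-positive-rate, true-positive-rate) points from (0,0) to (1,1),
#' and integrates the curve by the trapezoidal rule — equivalent to the
#' Mann-Whitney U statistic divided by `n1 * n2` with ties counted half.
#'
#' @param scores Numeric scores (higher = more responder-like).
#' @param labels Aligned `responder` / `non_responder` labels; both classes
#'   required.
#' @return List of class `roc_curve`: `fpr`, `tpr` (ordered points) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "responder"
  if (all(pos) || !any(pos))
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores so the curve cuts diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(tapply(p, grp, sum)))
  fp <- c(0, cumsum(tapply(!p, grp, sum)))
  tpr <- tp / sum(pos); fpr <- fp / sum(!pos)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = unname(fpr), tpr = unname(tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

# Stratified fold assignment: shuffles each class and deals it round-robin
# into k folds, so every fold keeps the class balance as even as n allows.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the signature model
#'
#' For each repeat, samples are dealt into k stratified folds; for each
#' fold the PLS model and its ROC threshold are fitted on the training
#' folds only (per-gene centring and scaling included, so no test-fold
#' statistics leak), the held-out fold is scored, and
#' accuracy / sensitivity / specificity / AUC are recorded.  AUC is `NA`
#' for a fold whose test set lacks a class.
#'
#' @param expr An `expr_matrix` of the discovery cohort.
#' @param genes Candidate signature genes.
#' @param k Folds (default 5); reduced with a warning when the smaller
#'   class has fewer members than `k`.
#' @param repeats Independent repetitions of the fold split (default 5).
#' @param seed Integer seed governing all fold assignments.
#' @param n_components PLS components per fold model.
#' @return List of class `cv_report`: `folds` (per-fold metric table),
#'   `per_repeat` (means by repeat), `overall` (means over folds),
#'   `assignments` (sample-by-repeat fold matrix), `k`, `repeats`, `seed`.
#' @export
kfold_cv <- function(expr, genes = NULL, k = 5L, repeats = 5L, seed = 1L,
                     n_components = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  labels <- expr$labels
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("smaller class has ", min_class, " samples; reducing k from ",
            k, " to ", min_class)
    k <- min_class
  }
  set.seed(seed)
  n <- length(labels)
  assignments <- matrix(NA_integer_, n, repeats,
                        dimnames = list(names(labels), NULL))
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, k)
    assignments[, r] <- fold
    for (f in seq_len(k)) {
      test <- fold == f
      train_expr <- expression_matrix(expr$values[, !test, drop = FALSE],
                                      labels[!test])
      model <- train_classifier(train_expr, genes, n_components)
      test_expr <- expr$values[, test, drop = FALSE]
      sc <- score_samples(model, structure(
        list(values = test_expr,
             labels = labels[test]), class = "expr_matrix"))
      met <- confusion_metrics(confusion_counts(sc$predicted, labels[test]))
      auc <- if (length(unique(labels[test])) == 2)
        roc_auc(sc$score, labels[test])$auc else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(repeat_id = r, fold = f, n_test = sum(test),
                   accuracy = met$accuracy, sensitivity = met$sensitivity,
                   specificity = met$specificity, auc = auc)
    }
  }
  folds <- do.call(rbind, rows)
  mean_cols <- c("accuracy", "sensitivity", "specificity", "auc")
  per_repeat <- do.call(rbind, lapply(split(folds, folds$repeat_id), function(d)
    data.frame(repeat_id = d$repeat_id[1],
               t(colMeans(d[mean_cols], na.rm = TRUE)))))
  rownames(per_repeat) <- NULL
  structure(list(folds = folds, per_repeat = per_repeat,
                 overall = colMeans(folds[mean_cols], na.rm = TRUE),
                 assignments = assignments,
                 k = k, repeats = repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold stratified CV (seed %d)\n", x$repeats, x$k, x$seed))
  cat(sprintf("  mean accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              x$overall["accuracy"], x$overall["sensitivity"],
              x$overall["specificity"], x$overall["auc"]))
  invisible(x)
}

#' DeLong comparison of two correlated AUCs
#'
#' Two score vectors over the same samples are compared with DeLong's test
#' for paired ROC curves (two-sided).  Identical score vectors have zero
#' AUC difference and return p = 1.
#'
#' @param scores_a,scores_b Numeric scores over identical samples.
#' @param labels Aligned `responder` / `non_responder` labels.
#' @return List with `auc_a`, `auc_b`, `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("score vectors and labels must cover the same samples",
         call. = FALSE)
  resp <- as.integer(labels == "responder")
  roc_a <- pROC::roc(resp, scores_a, quiet = TRUE, direction = "<",
                     levels = c(0, 1))
  roc_b <- pROC::roc(resp, scores_b, quiet = TRUE, direction = "<",
                     levels = c(0, 1))
  auc_a <- as.numeric(pROC::auc(roc_a))
  auc_b <- as.numeric(pROC::auc(roc_b))
  p <- tryCatch(
    suppressWarnings(
      pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)$p.value),
    error = function(e) NA_real_)
  if (!is.finite(p) && isTRUE(all.equal(auc_a, auc_b))) p <- 1
  list(auc_a = auc_a, auc_b = auc_b, p_value = p)
}

#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way analysis of variance (equal-variance
#' F-test), as used to compare candidate-gene expression between responder
#' and non-responder groups.  With two groups the F statistic equals the
#' squared pooled-variance t statistic.
#'
#' @param values Numeric measurements.
#' @param groups Group membership aligned with `values`; at least 2 groups
#'   of at least 2 values each.
#' @return List with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
compare_groups_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  f <- unname(fit$statistic)
  p <- if (is.nan(f)) 1 else unname(fit$p.value)  # zero within+between variance
  if (f == 0) p <- 1
  list(f_statistic = f, p_value = p,
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}
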