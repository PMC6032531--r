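#' Run the discovery workflow end to end
#'
#' Executes the full biomarker-discovery chain on one cohort: RVM moderated
#' t-test, DEG screen, median edge filter, DEG subgraph construction,
#' centrality computation, major-gene and candidate selection, PLS model
#' fitting with ROC threshold selection, and repeated stratified k-fold
#' cross-validation.  Per-stage gene counts are collected in an attrition
#' table; if fewer than two candidates survive, the run halts with a
#' diagnostic listing that attrition.
#'
#' @param expr An `expr_matrix` (discovery cohort).
#' @param edges Scored edge table (`gene_a`, `gene_b`, `combined_score`).
#' @param log2fc_threshold,p_threshold DEG screen thresholds
#'   (defaults 0.5 / 0.05).
#' @param fold_threshold Candidate fold-change threshold (default 1.5).
#' @param k,repeats,cv_seed Cross-validation settings (defaults 5 / 5).
#' @param n_components PLS components (default 1).
#' @param weighted_degree Use score-weighted degree in topology.
#' @param outdir Optional directory; when given, every intermediate
#'   artifact (DEG table, topology, candidate list, model JSON, manifest)
#'   is written there.
#' @return List of class `discovery_run`: `deg_table`, `degs`, `topology`,
#'   `major_genes`, `candidates`, `model`, `cv`, `attrition`, `manifest`.
#' @export
run_discovery <- function(expr, edges,
                          log2fc_threshold = 0.5, p_threshold = 0.05,
                          fold_threshold = 1.5,
                          k = 5L, repeats = 5L, cv_seed = 1L,
                          n_components = 1L, weighted_degree = FALSE,
                          outdir = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  deg_table <- rvm_ttest(expr)
  degs <- screen_degs(deg_table, log2fc_threshold, p_threshold)
  filtered <- filter_edges_by_median(edges)
  net <- build_network(degs$gene_id, filtered)
  topo <- compute_topology(net, weighted_degree = weighted_degree)
  major <- select_major_genes(topo)
  candidates <- if (length(major))
    select_candidates(major, deg_table, fold_threshold, p_threshold)
  else character(0)

  attrition <- data.frame(
    stage = c("input_genes", "degs", "network_nodes", "major_genes",
              "candidates"),
    n = c(nrow(expr$values), nrow(degs), nrow(topo), length(major),
          length(candidates)))
  if (length(candidates) < 2) {
    stop("fewer than 2 candidate genes survive the filters; attrition: ",
         paste(sprintf("%s=%d", attrition$stage, attrition$n),
               collapse = ", "), call. = FALSE)
  }

  model <- train_classifier(expr, candidates, n_components)
  cv <- kfold_cv(expr, candidates, k = k, repeats = repeats, seed = cv_seed,
                 n_components = n_components)

  manifest <- list(
    package = "tgpredict",
    version = as.character(utils::packageVersion("tgpredict")),
    thresholds = list(log2fc = log2fc_threshold, p = p_threshold,
                      fold = fold_threshold),
    cv = list(k = cv$k, repeats = cv$repeats, seed = cv_seed),
    n_components = n_components,
    weighted_degree = weighted_degree,
    attrition = stats::setNames(as.list(attrition$n), attrition$stage),
    candidates = candidates)

  run <- structure(list(deg_table = deg_table, degs = degs, topology = topo,
                        major_genes = major, candidates = candidates,
                        model = model, cv = cv, attrition = attrition,
                        manifest = manifest),
                   class = "discovery_run")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_deg_tsv(degs, file.path(outdir, "degs.tsv"))
    utils::write.table(topo, file.path(outdir, "topology.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(candidates, file.path(outdir, "candidates.txt"))
    write_pls_model(model, file.path(outdir, "model.json"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("discovery run\n")
  cat(sprintf("  %s\n", paste(sprintf("%s=%d", x$attrition$stage,
                                      x$attrition$n), collapse = " -> ")))
  cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  cat(sprintf("  CV mean accuracy %.3f, AUC %.3f\n",
              x$cv$overall["accuracy"], x$cv$overall["auc"]))
  invisible(x)
}

#' Evaluate a trained model on an independent validation cohort
#'
#' Scores the validation samples with the trained signature model, computes
#' confusion metrics and the ROC/AUC, and — mirroring the single-marker
#' comparison — contrasts the combined score's AUC with each signature
#' gene's own discrimination.  Per-gene AUCs are orientation-free
#' (`max(auc, 1 - auc)`), since a down-regulated marker discriminates in
#' the opposite direction; the DeLong p-value compares the model score with
#' the gene oriented the same way.
#'
#' @param model A `pls_model` with its threshold set.
#' @param expr Validation `expr_matrix` containing every model gene (for
#'   qPCR cohorts, build it with [qpcr_to_expression()]).
#' @param restandardize Re-centre and re-scale each model gene on the
#'   validation cohort before applying the weights.  Needed when the
#'   validation platform differs from the training platform (microarray
#'   log2 intensities vs qPCR log2 relative quantities), whose location
#'   scales are incommensurable; the weights and threshold are kept as
#'   trained.  Default `FALSE` (use the model's stored constants).
#' @return List of class `evaluation_report`: `scores`, `counts`,
#'   `metrics`, `roc`, `auc`, `per_gene` (gene, auc, delong_p vs the model
#'   score).
#' @export
run_validation <- function(model, expr, restandardize = FALSE) {
  stopifnot(inherits(model, "pls_model"), inherits(expr, "expr_matrix"))
  if (ncol(expr$values) == 0)
    stop("empty evaluation: validation cohort has no samples", call. = FALSE)
  if (is.na(model$threshold))
    stop("model threshold is unset; run choose_threshold() first",
         call. = FALSE)
  if (restandardize) {
    X <- expr$values[model$gene_ids, , drop = FALSE]
    model$center <- stats::setNames(rowMeans(X), model$gene_ids)
    model$scale <- stats::setNames(apply(X, 1, stats::sd), model$gene_ids)
    if (any(model$scale == 0))
      stop("gene(s) with zero variance in the validation cohort; cannot restandardize",
           call. = FALSE)
  }
  sc <- score_samples(model, expr)
  actual <- expr$labels[sc$sample_id]
  counts <- confusion_counts(sc$predicted, actual)
  metrics <- confusion_metrics(counts)
  roc <- roc_auc(sc$score, actual)

  per_gene <- do.call(rbind, lapply(model$gene_ids, function(g) {
    v <- expr$values[g, sc$sample_id]
    a <- roc_auc(v, actual)$auc
    oriented <- if (a >= 0.5) v else -v
    cmp <- compare_auc(sc$score, oriented, actual)
    data.frame(gene_id = g, auc = max(a, 1 - a), delong_p = cmp$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(scores = sc, counts = counts, metrics = metrics,
                 roc = roc, auc = roc$auc, per_gene = per_gene),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("validation: n = %d, accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              x$counts$N, x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity, x$auc))
  invisible(x)
}
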