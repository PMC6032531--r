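#' Fit the partial-least-squares signature model
#'
#' Candidate-gene expression is standardised per gene (training mean 0,
#' SD 1) and the response coded +1 responder / -1 non-responder and centred.
#' The first PLS component maximises the squared covariance between the
#' linear combination of predictors and the response; its weight vector is
#' `X'y` normalised to unit length — the closed form of that maximisation.
#' With `n_components > 1` further components follow standard NIPALS
#' deflation and the stored weights are the aggregated per-gene regression
#' coefficients.  With six candidate genes and a dozen training samples one
#' component is the sensible default.
#'
#' @param expr An `expr_matrix` holding the training cohort.
#' @param genes Candidate genes (default: all genes of `expr`); each must
#'   have positive training variance.
#' @param n_components Number of PLS components (default 1).
#' @return A list of class `pls_model` with fields `gene_ids`, `center`,
#'   `scale`, `weights`, `threshold` (NA until [choose_threshold()] sets
#'   it) and `n_components`.
#' @export
fit_pls <- function(expr, genes = NULL, n_components = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(genes)) genes <- rownames(expr$values)
  expr <- subset_genes(expr, genes)
  grp <- group_samples(expr)
  if (length(grp$responder) < 2 || length(grp$non_responder) < 2)
    stop("need at least 2 samples per group to fit the model", call. = FALSE)
  X <- t(expr$values)                       # samples x genes
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  degenerate <- genes[scl == 0]
  if (length(degenerate))
    stop("candidate gene(s) with zero training variance: ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y <- ifelse(expr$labels == "responder", 1, -1)
  y <- y - mean(y)

  k <- length(genes)
  H <- min(as.integer(n_components), k)
  Wmat <- Pmat <- matrix(0, k, H)
  qvec <- numeric(H)
  E <- Xs; f <- y
  for (h in seq_len(H)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw == 0) { H <- h - 1L; break }
    w <- w / nw
    t_h <- drop(E %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(E, t_h)) / tt
    q_h <- sum(f * t_h) / tt
    E <- E - tcrossprod(t_h, p_h)
    f <- f - t_h * q_h
    Wmat[, h] <- w; Pmat[, h] <- p_h; qvec[h] <- q_h
  }
  if (H < 1) stop("response has no covariance with any candidate gene",
                  call. = FALSE)
  weights <- if (H == 1) {
    Wmat[, 1]                               # unit-norm first-component weights
  } else {
    Wm <- Wmat[, seq_len(H), drop = FALSE]
    Pm <- Pmat[, seq_len(H), drop = FALSE]
    drop(Wm %*% solve(crossprod(Pm, Wm), qvec[seq_len(H)]))
  }
  structure(list(gene_ids = genes,
                 center = stats::setNames(unname(ctr), genes),
                 scale = stats::setNames(unname(scl), genes),
                 weights = stats::setNames(unname(weights), genes),
                 threshold = NA_real_,
                 n_components = H),
            class = "pls_model")
}

#' Construct a PLS model from known constants
#'
#' Assembles a `pls_model` directly from gene order, standardisation
#' constants, weights and threshold — used to apply a published signature
#' to new samples.
#'
#' @param gene_ids,weights,center,scale Aligned per-gene constants;
#'   `center`/`scale` default to 0/1 (expression already standardised).
#' @param threshold Classification threshold `T`.
#' @return A `pls_model`.
#' @export
pls_model <- function(gene_ids, weights, center = NULL, scale = NULL,
                      threshold = NA_real_) {
  k <- length(gene_ids)
  if (is.null(center)) center <- rep(0, k)
  if (is.null(scale)) scale <- rep(1, k)
  if (length(weights) != k || length(center) != k || length(scale) != k)
    stop("gene_ids, weights, center and scale must have equal length",
         call. = FALSE)
  if (any(scale <= 0)) stop("all scale entries must be positive", call. = FALSE)
  structure(list(gene_ids = gene_ids,
                 center = stats::setNames(as.numeric(center), gene_ids),
                 scale = stats::setNames(as.numeric(scale), gene_ids),
                 weights = stats::setNames(as.numeric(weights), gene_ids),
                 threshold = threshold, n_components = 1L),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS signature model: %d genes, %d component(s), threshold %s\n",
              length(x$gene_ids), x$n_components,
              ifelse(is.na(x$threshold), "unset", format(x$threshold))))
  print(round(x$weights, 4))
  invisible(x)
}

#' Score samples with a PLS signature model
#'
#' Each sample's score is the weighted sum over the signature genes of its
#' standardised expression, `Score = sum_i L_i * W_i`, where `L_i` uses the
#' model's stored centring and scaling constants.  When the model carries a
#' threshold `T`, samples with `Score > T` are called responders.
#'
#' @param model A `pls_model`.
#' @param expr An `expr_matrix` containing every model gene.
#' @return Data frame with columns `sample_id`, `score` and — when the
#'   threshold is set — `predicted`.
#' @export
score_samples <- function(model, expr) {
  stopifnot(inherits(model, "pls_model"), inherits(expr, "expr_matrix"))
  missing <- setdiff(model$gene_ids, rownames(expr$values))
  if (length(missing))
    stop("model gene(s) missing from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- t(expr$values[model$gene_ids, , drop = FALSE])
  L <- sweep(sweep(X, 2, model$center[model$gene_ids]),
             2, model$scale[model$gene_ids], "/")
  score <- drop(L %*% model$weights[model$gene_ids])
  out <- data.frame(sample_id = colnames(expr$values), score = unname(score),
                    stringsAsFactors = FALSE)
  if (!is.na(model$threshold))
    out$predicted <- ifelse(out$score > model$threshold,
                            "responder", "non_responder")
  out
}

#' Choose the classification threshold from training scores
#'
#' Candidate cutoffs are the n + 1 positions around the sorted distinct
#' scores (one below the minimum, the midpoints between adjacent distinct
#' scores, one above the maximum).  The cutoff maximising Youden's J
#' (sensitivity + specificity - 1) is selected; ties are broken towards the
#' higher accuracy and then towards the lower cutoff, so the choice is
#' deterministic.  When no cutoff separates the classes at all
#' (J = 0 everywhere) the lowest candidate is returned and flagged.
#'
#' @param scores Numeric sample scores (or the data frame returned by
#'   [score_samples()]).
#' @param labels Sample labels aligned with `scores`
#'   (`responder` / `non_responder`); both classes must be present.
#' @return A list of class `threshold_choice`: `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`, `accuracy`, `degenerate`.
#' @export
choose_threshold <- function(scores, labels) {
  if (is.data.frame(scores)) {
    if (is.null(names(labels))) names(labels) <- scores$sample_id
    labels <- labels[scores$sample_id]
    scores <- scores$score
  }
  pos <- labels == "responder"
  if (all(pos) || !any(pos))
    stop("both classes must be present to choose a threshold", call. = FALSE)
  d <- sort(unique(scores))
  cuts <- if (length(d) == 1) c(d - 1, d + 1)
  else c(d[1] - 1, (d[-1] + d[-length(d)]) / 2, d[length(d)] + 1)

  n_pos <- sum(pos); n_neg <- sum(!pos)
  stats_at <- function(cut) {
    pred <- scores > cut
    sens <- sum(pred & pos) / n_pos
    spec <- sum(!pred & !pos) / n_neg
    c(j = sens + spec - 1, acc = (sum(pred & pos) + sum(!pred & !pos)) /
        length(scores), sens = sens, spec = spec)
  }
  tab <- vapply(cuts, stats_at, numeric(4))
  best <- which(tab["j", ] == max(tab["j", ]))
  best <- best[tab["acc", best] == max(tab["acc", best])]
  pick <- best[1]                           # lowest cutoff on remaining ties
  structure(list(threshold = cuts[pick],
                 youden_j = unname(tab["j", pick]),
                 sensitivity = unname(tab["sens", pick]),
                 specificity = unname(tab["spec", pick]),
                 accuracy = unname(tab["acc", pick]),
                 degenerate = max(tab["j", ]) <= 0),
            class = "threshold_choice")
}

#' Fit the signature model and its threshold in one step
#'
#' Convenience wrapper: [fit_pls()] on the training cohort, score the
#' training samples, then [choose_threshold()] on those scores.
#'
#' @inheritParams fit_pls
#' @return A `pls_model` with `threshold` set; the `threshold_choice` is
#'   attached as attribute `"training"`.
#' @export
train_classifier <- function(expr, genes = NULL, n_components = 1L) {
  model <- fit_pls(expr, genes, n_components)
  sc <- score_samples(model, if (is.null(genes)) expr else subset_genes(expr, genes))
  choice <- choose_threshold(sc$score, expr$labels[sc$sample_id])
  model$threshold <- choice$threshold
  attr(model, "training") <- choice
  model
}

#' Serialize / deserialize a PLS model as JSON
#'
#' Round-trips gene order, centring/scaling constants, weights and threshold
#' at full double precision.
#'
#' @param model A `pls_model`.
#' @param path JSON file path.
#' @return `write_pls_model` returns `path` invisibly; `read_pls_model`
#'   the reconstructed `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  jsonlite::write_json(
    list(gene_ids = model$gene_ids,
         center = unname(model$center),
         scale = unname(model$scale),
         weights = unname(model$weights),
         threshold = model$threshold,
         n_components = model$n_components,
         format = "tgpredict-pls-1"),
    path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- pls_model(obj$gene_ids, obj$weights, obj$center, obj$scale,
                 threshold = ifelse(is.null(obj$threshold), NA_real_,
                                    obj$threshold))
  m$n_components <- as.integer(obj$n_components)
  m
}

#' The published six-gene TG-response signature
#'
#' The discovery-cohort weight values reported for MX1, OASL, SPINK1, CRK,
#' GRAPL and RNF2 together with the published classification threshold of
#' -0.03, assembled as a ready-to-score `pls_model` over standardised
#' expression (centre 0, scale 1).  The down-regulated interferon-inducible
#' genes carry negative weights and the up-regulated adaptor/ligase genes
#' positive ones.
#'
#' @return A `pls_model` with the published weights and threshold.
#' @export
tg_signature_model <- function() {
  pls_model(
    gene_ids = c("MX1", "OASL", "SPINK1", "CRK", "GRAPL", "RNF2"),
    weights = c(-0.4694, -0.2494, -0.5592, 0.3429, 0.4054, 0.3504),
    threshold = -0.03)
}
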