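#' Configuration of the synthetic-cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a small two-group microarray cohort whose gene-wise variances
#' follow an inverse-gamma-type prior (precision gamma-distributed with
#' shape `prior_shape_a` and scale `prior_scale_b`, the random-variance-model
#' assumption), a planted fraction of differentially expressed genes with a
#' fixed |log2 fold change| and balanced up/down signs, and a STRING-style
#' scored interaction network in which a subset of the planted genes are
#' wired as hubs.
#'
#' @param n_genes Number of genes.
#' @param n_responders,n_nonresponders Samples per group; at least 2 each so
#'   gene-wise variances are estimable.
#' @param de_fraction Fraction of genes planted as differentially expressed,
#'   in \[0, 1). When positive, `de_fraction * n_genes` must be at least 6 so
#'   candidate selection has something to find.
#' @param log2_effect Magnitude of the planted log2 fold change
#'   (responder minus non-responder group mean); sign is drawn per gene with
#'   a balanced up/down split.
#' @param prior_shape_a,prior_scale_b Gamma shape and scale of the gene-wise
#'   precision prior.
#' @param hub_fraction Fraction of planted genes additionally wired as
#'   network hubs.
#' @param edge_score_range Integer vector `c(min, max)` of combined
#'   interaction scores (STRING dialect, default 150-999).
#' @param bg_mean_degree Mean degree of the Erdos-Renyi background graph.
#' @param hub_spokes Number of extra high-score edges attached to each
#'   planted hub.
#' @param ct_noise_sd Replicate-level Gaussian noise (cycles) of simulated
#'   qPCR Ct values.
#' @param reference_genes Names of the two group-independent reference genes
#'   emitted by [simulate_qpcr()].
#' @param seed Integer seed; every simulation function is deterministic
#'   given the configuration.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_responders = 6,
                       n_nonresponders = 6,
                       de_fraction = 0.05,
                       log2_effect = 2,
                       prior_shape_a = 3,
                       prior_scale_b = 1,
                       hub_fraction = 0.06,
                       edge_score_range = c(150L, 999L),
                       bg_mean_degree = 2,
                       hub_spokes = 20,
                       ct_noise_sd = 0.2,
                       reference_genes = c("GAPDH", "RPS18"),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              de_fraction = de_fraction,
              log2_effect = log2_effect,
              prior_shape_a = prior_shape_a,
              prior_scale_b = prior_scale_b,
              hub_fraction = hub_fraction,
              edge_score_range = as.integer(edge_score_range),
              bg_mean_degree = bg_mean_degree,
              hub_spokes = as.integer(hub_spokes),
              ct_noise_sd = ct_noise_sd,
              reference_genes = reference_genes,
              seed = as.integer(seed))
  check_positive <- function(field) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 1 ||
        !is.finite(cfg[[field]]) || cfg[[field]] <= 0)
      stop("invalid configuration: `", field, "` must be a positive number",
           call. = FALSE)
  }
  for (f in c("n_genes", "log2_effect", "prior_shape_a", "prior_scale_b"))
    check_positive(f)
  if (cfg$n_responders < 2 || cfg$n_nonresponders < 2)
    stop("invalid configuration: `n_responders` and `n_nonresponders` must both be >= 2",
         call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction >= 1)
    stop("invalid configuration: `de_fraction` must lie in [0, 1)", call. = FALSE)
  if (cfg$de_fraction > 0 && cfg$de_fraction * cfg$n_genes < 6)
    stop("invalid configuration: `de_fraction` * `n_genes` must be >= 6",
         call. = FALSE)
  if (cfg$hub_fraction < 0 || cfg$hub_fraction > 1)
    stop("invalid configuration: `hub_fraction` must lie in [0, 1]", call. = FALSE)
  if (length(cfg$edge_score_range) != 2 ||
      cfg$edge_score_range[1] >= cfg$edge_score_range[2])
    stop("invalid configuration: `edge_score_range` must be c(min, max) with min < max",
         call. = FALSE)
  if (cfg$ct_noise_sd < 0)
    stop("invalid configuration: `ct_noise_sd` must be >= 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-group expression cohort with planted signal
#'
#' Gene-wise variances are drawn from the configured precision prior
#' (`1/sigma^2 ~ Gamma(a, scale = b)`); each gene gets its own baseline
#' log2 mean; planted genes differ between responder and non-responder
#' groups by `log2_effect` with a balanced random sign.  All randomness is
#' governed by `config$seed`, so identical configurations reproduce
#' bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `expression`
#'   (an `expr_matrix`), `truth` (data frame of planted genes and their true
#'   log2 effects), `truth_hubs` (character vector, subset of `truth$gene_id`)
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_g))
  sample_ids <- c(sprintf("R%02d", seq_len(config$n_responders)),
                  sprintf("N%02d", seq_len(config$n_nonresponders)))
  labels <- stats::setNames(
    rep(c("responder", "non_responder"),
        c(config$n_responders, config$n_nonresponders)),
    sample_ids)

  sigma2 <- 1 / stats::rgamma(n_g, shape = config$prior_shape_a,
                              scale = config$prior_scale_b)
  baseline <- stats::rnorm(n_g, mean = 7, sd = 2)

  n_de <- round(config$de_fraction * n_g)
  de_idx <- if (n_de > 0) sort(sample.int(n_g, n_de)) else integer(0)
  # balanced up/down split, order shuffled
  signs <- if (n_de > 0) sample(rep(c(1, -1), length.out = n_de)) else numeric(0)
  effect <- numeric(n_g)
  effect[de_idx] <- signs * config$log2_effect

  n_tot <- length(sample_ids)
  is_resp <- labels == "responder"
  mu <- matrix(baseline, n_g, n_tot)
  mu[, is_resp] <- mu[, is_resp] + effect
  values <- mu + matrix(stats::rnorm(n_g * n_tot, sd = sqrt(sigma2)),
                        n_g, n_tot)
  dimnames(values) <- list(gene_ids, sample_ids)

  truth <- data.frame(gene_id = gene_ids[de_idx],
                      log2_effect = effect[de_idx],
                      stringsAsFactors = FALSE)
  n_hub <- round(config$hub_fraction * n_de)
  truth_hubs <- if (n_hub > 0) sort(sample(truth$gene_id, n_hub)) else character(0)

  structure(list(expression = expression_matrix(values, labels),
                 truth = truth, truth_hubs = truth_hubs, config = config),
            class = "sim_cohort")
}

#' Simulate a STRING-style scored interaction network
#'
#' A sparse Erdos-Renyi background graph is drawn over all genes; each
#' planted hub then receives `hub_spokes` extra edges towards other planted
#' genes, so that after differential-expression screening the hub dominates
#' the degree, closeness and betweenness medians of the candidate subgraph.
#' Background edges carry integer combined scores uniform over
#' `edge_score_range`; hub edges are sampled from the upper half of the
#' range so they survive the median edge filter.
#'
#' @param cohort A `sim_cohort`.
#' @param config The same [sim_config()] used for the cohort.
#' @return Data frame with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
simulate_network <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- rownames(cohort$expression$values)
  n_g <- length(genes)
  n_bg <- round(config$bg_mean_degree * n_g / 2)

  a <- sample.int(n_g, 2L * n_bg, replace = TRUE)
  b <- sample.int(n_g, 2L * n_bg, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(cbind(lo, hi))
  lo <- lo[!dup][seq_len(min(n_bg, sum(!dup)))]
  hi <- hi[!dup][seq_len(length(lo))]
  rng <- config$edge_score_range
  edges <- data.frame(gene_a = genes[lo], gene_b = genes[hi],
                      combined_score = sample(rng[1]:rng[2], length(lo),
                                              replace = TRUE),
                      stringsAsFactors = FALSE)

  hubs <- cohort$truth_hubs
  if (length(hubs)) {
    upper <- ceiling((rng[1] + rng[2]) / 2):rng[2]
    hub_edges <- do.call(rbind, lapply(hubs, function(h) {
      partners <- setdiff(cohort$truth$gene_id, h)
      partners <- sample(partners, min(config$hub_spokes, length(partners)))
      data.frame(gene_a = pmin(h, partners), gene_b = pmax(h, partners),
                 combined_score = sample(upper, length(partners),
                                         replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    edges <- rbind(edges, hub_edges)
    edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), ]
  }
  rownames(edges) <- NULL
  edges
}

#' Simulate triplicate qPCR Ct tables for candidate genes
#'
#' Emulates a comparative-CT validation experiment: two reference genes with
#' group-independent mean Ct, candidate genes whose responder-group Ct is
#' shifted by `-log2(fold change)`, a per-sample offset shared by all genes
#' of that sample (RNA input amount, cancelled by delta-Ct normalisation),
#' and Gaussian replicate noise.
#'
#' @param candidates Character vector of candidate gene identifiers.
#' @param labels Named character vector of sample labels
#'   (`responder` / `non_responder`).
#' @param config A [sim_config()]; `ct_noise_sd`, `reference_genes` and
#'   `seed` are used.
#' @param log2_effects Optional named numeric vector of planted log2 fold
#'   changes (responder vs non-responder) per candidate; defaults to
#'   `config$log2_effect` with alternating signs.
#' @param n_replicates Technical replicates per sample and gene.
#' @return Data frame of class `ct_table` with columns
#'   `sample_id`, `gene_id`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(candidates, labels, config,
                          log2_effects = NULL, n_replicates = 3L) {
  if (!length(candidates)) stop("`candidates` must be non-empty", call. = FALSE)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(log2_effects)) {
    log2_effects <- stats::setNames(
      rep(c(1, -1), length.out = length(candidates)) * config$log2_effect,
      candidates)
  }
  missing <- setdiff(candidates, names(log2_effects))
  if (length(missing))
    stop("no planted effect for: ", paste(missing, collapse = ", "),
         call. = FALSE)

  refs <- config$reference_genes
  genes <- c(candidates, refs)
  base_ct <- c(stats::setNames(stats::rnorm(length(candidates), 26, 1.5),
                               candidates),
               stats::setNames(c(18, 22)[seq_along(refs)], refs))
  sample_offset <- stats::setNames(stats::rnorm(length(labels), 0, 0.5),
                                   names(labels))

  grid <- expand.grid(replicate = seq_len(n_replicates), gene_id = genes,
                      sample_id = names(labels), stringsAsFactors = FALSE)
  shift <- ifelse(grid$gene_id %in% candidates &
                    labels[grid$sample_id] == "responder",
                  -log2_effects[grid$gene_id], 0)
  ct <- base_ct[grid$gene_id] + sample_offset[grid$sample_id] + shift +
    stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  out <- data.frame(sample_id = grid$sample_id, gene_id = grid$gene_id,
                    replicate = grid$replicate, ct = unname(ct),
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the pipeline's file dialects: expression TSV, labels TSV, edge TSV
#' and a JSON file recording the planted truth.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if absent).
#' @param edges Optional pre-simulated edge table; defaults to
#'   [simulate_network()] on the cohort.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, edges = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(edges)) edges <- simulate_network(cohort)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             edges = file.path(dir, "edges.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(cohort$expression, paths["expression"])
  write_labels_tsv(cohort$expression$labels, paths["labels"])
  utils::write.table(edges, paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(truth = cohort$truth, truth_hubs = cohort$truth_hubs),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
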