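#' Read a qPCR Ct table
#'
#' Comma-separated with a required header: `sample_id`, `gene_id`,
#' `replicate`, `ct` (legacy column names `sample` / `gene` are accepted).
#'
#' @param path CSV file path.
#' @return Data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "sample"] <- "sample_id"
  names(tab)[names(tab) == "gene"] <- "gene_id"
  req <- c("sample_id", "gene_id", "replicate", "ct")
  if (!all(req %in% names(tab)))
    stop("Ct table must have columns sample, gene, replicate, ct",
         call. = FALSE)
  if (any(!is.finite(tab$ct)))
    stop("Ct values must all be finite", call. = FALSE)
  tab <- tab[, req]
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' Comparative-CT relative quantification
#'
#' Implements the 2^-ddCt method: replicate Ct values are averaged per
#' sample and gene, delta-Ct is the target's mean Ct minus the reference
#' gene's mean Ct in the same sample, delta-delta-Ct subtracts the
#' calibrator delta-Ct (by default the mean delta-Ct of the non-responder
#' group, so reported quantities are fold changes relative to that group),
#' and the relative quantity is `2^-ddCt`.  Replicate scatter is propagated
#' as `sqrt(sd_target^2/r_t + sd_reference^2/r_r)`, the standard error of
#' the delta-Ct.
#'
#' The default aggregation averages Ct before differencing; pairing
#' replicates by index and differencing first (`aggregate =
#' "per_replicate"`) is also available — with equal replicate counts both
#' orders give identical mean delta-Ct.
#'
#' @param ct A `ct_table` (see [read_ct_table()] / [simulate_qpcr()]).
#' @param reference_gene Reference gene measured in every sample.
#' @param labels Named sample labels; required when `calibrator` is a group.
#' @param calibrator Either a group name (`"non_responder"`, the default, or
#'   `"responder"`) whose mean delta-Ct calibrates each gene, or the
#'   identifier of a single calibrator sample.
#' @param aggregate Replicate aggregation order (see above).
#' @return Data frame with columns `sample_id`, `gene_id`,
#'   `reference_gene`, `delta_ct`, `ddct`, `rq`, `replicate_sd`.
#' @export
relative_quantify <- function(ct, reference_gene, labels = NULL,
                              calibrator = "non_responder",
                              aggregate = c("mean_ct", "per_replicate")) {
  aggregate <- match.arg(aggregate)
  if (!reference_gene %in% ct$gene_id)
    stop("reference gene ", reference_gene, " absent from Ct table",
         call. = FALSE)
  samples <- unique(ct$sample_id)
  ref <- ct[ct$gene_id == reference_gene, ]
  no_ref <- setdiff(samples, ref$sample_id)
  if (length(no_ref))
    stop("missing reference measurements for sample(s): ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  targets <- setdiff(unique(ct$gene_id), reference_gene)

  per_cell <- function(d) c(mean = mean(d$ct), sd = stats::sd(d$ct),
                            n = nrow(d))
  cell_stats <- function(gene) {
    d <- ct[ct$gene_id == gene, ]
    t(vapply(split(d, d$sample_id), per_cell, numeric(3)))
  }
  refstat <- cell_stats(reference_gene)

  rows <- lapply(targets, function(g) {
    gs <- cell_stats(g)
    smp <- rownames(gs)
    if (aggregate == "mean_ct") {
      dct <- gs[, "mean"] - refstat[smp, "mean"]
    } else {
      dct <- vapply(smp, function(s) {
        dg <- ct[ct$gene_id == g & ct$sample_id == s, ]
        dr <- ct[ct$gene_id == reference_gene & ct$sample_id == s, ]
        r <- min(nrow(dg), nrow(dr))
        mean(dg$ct[order(dg$replicate)][seq_len(r)] -
               dr$ct[order(dr$replicate)][seq_len(r)])
      }, numeric(1))
    }
    sd_prop <- sqrt(gs[, "sd"]^2 / gs[, "n"] +
                      refstat[smp, "sd"]^2 / refstat[smp, "n"])
    data.frame(sample_id = smp, gene_id = g, reference_gene = reference_gene,
               delta_ct = unname(dct), replicate_sd = unname(sd_prop),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  if (length(calibrator) == 1 && calibrator %in% out$sample_id) {
    cal <- stats::setNames(out$delta_ct[out$sample_id == calibrator],
                           out$gene_id[out$sample_id == calibrator])
  } else {
    if (is.null(labels))
      stop("`labels` required when the calibrator is a group mean",
           call. = FALSE)
    if (!calibrator %in% labels)
      stop("calibrator group '", calibrator, "' not present in labels",
           call. = FALSE)
    in_cal <- labels[out$sample_id] == calibrator
    cal <- tapply(out$delta_ct[in_cal], out$gene_id[in_cal], mean)
  }
  out$ddct <- out$delta_ct - as.numeric(cal[out$gene_id])
  out$rq <- 2^(-out$ddct)
  rownames(out) <- NULL
  out[, c("sample_id", "gene_id", "reference_gene", "delta_ct", "ddct",
          "rq", "replicate_sd")]
}

#' Assemble relative quantities into an expression matrix
#'
#' Converts `2^-ddCt` relative quantities back to log2 scale
#' (`log2(rq) = -ddCt`) and shapes them as a genes-by-samples
#' `expr_matrix`, ready for [score_samples()] — the route by which
#' qPCR-validated candidate genes feed the signature classifier.
#'
#' @param rel Output of [relative_quantify()] for a single reference gene.
#' @param labels Named sample labels covering every sample in `rel`.
#' @return An `expr_matrix` of log2 relative expression.
#' @export
qpcr_to_expression <- function(rel, labels) {
  if (length(unique(rel$reference_gene)) != 1)
    stop("`rel` must come from a single reference gene; got: ",
         paste(unique(rel$reference_gene), collapse = ", "), call. = FALSE)
  if (anyDuplicated(rel[, c("sample_id", "gene_id")]))
    stop("duplicate (sample, gene) pairs after aggregation", call. = FALSE)
  genes <- unique(rel$gene_id)
  samples <- unique(rel$sample_id)
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(rel$gene_id, genes), match(rel$sample_id, samples))] <-
    log2(rel$rq)
  if (anyNA(mat))
    stop("incomplete (sample, gene) grid in relative-expression table",
         call. = FALSE)
  expression_matrix(mat, labels)
}
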