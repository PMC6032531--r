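#' Gene-set collection for over-representation analysis
#'
#' @param sets Named list of character vectors (set name -> member genes);
#'   every set must be non-empty.  Members outside the background are
#'   dropped by intersection.
#' @param background Character vector, the gene universe.
#' @return A list of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, background) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a non-empty named list", call. = FALSE)
  background <- unique(background)
  sets <- lapply(sets, function(s) intersect(unique(s), background))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    stop("gene sets empty after background intersection: ",
         paste(empty, collapse = ", "), call. = FALSE)
  structure(list(sets = sets, background = background),
            class = "geneset_collection")
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.  Delegates to
#' `fgsea::gmtPathways()` when fgsea is installed, otherwise parses the
#' format directly.
#'
#' @param path GMT file path.
#' @param background Gene universe for the returned collection.
#' @return A `geneset_collection`.
#' @export
read_gmt <- function(path, background) {
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t")
    stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                    vapply(lines, `[`, character(1), 1))
  }
  geneset_collection(sets, background)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set the one-sided hypergeometric upper-tail probability of
#' seeing at least the observed overlap between the query list and the set,
#' given the background universe, is computed, then corrected two ways:
#' Bonferroni (p times the number of sets, capped at 1) and
#' Benjamini-Hochberg across all tested sets.  A set is called significant
#' when both corrected values fall below `alpha` — the dual-correction rule
#' used with DAVID-style annotation screens.
#'
#' @param query Character vector of genes; members outside the background
#'   are dropped with a warning.
#' @param collection A `geneset_collection`.
#' @param alpha Significance level applied to both corrected p-values.
#' @return Data frame sorted by `p_raw` with columns `set_name`,
#'   `set_size`, `overlap_count`, `p_raw`, `p_bonferroni`, `p_bh`,
#'   `significant`.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  query <- unique(query)
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the background")
    query <- setdiff(query, outside)
  }
  if (!length(query))
    stop("query is empty after background intersection", call. = FALSE)

  n_bg <- length(collection$background)
  n_q <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), n_bg - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(set), overlap_count = k,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_bonferroni < alpha & out$p_bh < alpha
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  out
}
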