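#' Median filter on scored interaction edges
#'
#' Keeps only edges whose combined evidence score is strictly greater than
#' the median of all input scores.  When every score is identical nothing
#' exceeds the median and the result is empty — degenerate but well-defined.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`,
#'   `combined_score`; self-loops are rejected.
#' @return The retained subset of `edges`.
#' @export
filter_edges_by_median <- function(edges) {
  edges <- validate_edges(edges)
  if (!nrow(edges)) stop("empty edge table", call. = FALSE)
  med <- stats::median(edges$combined_score)
  out <- edges[edges$combined_score > med, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_edges <- function(edges) {
  req <- c("gene_a", "gene_b", "combined_score")
  if (!all(req %in% names(edges)))
    stop("edge table must have columns gene_a, gene_b, combined_score",
         call. = FALSE)
  if (any(edges$gene_a == edges$gene_b))
    stop("self-loop edges are not allowed", call. = FALSE)
  if (any(edges$combined_score <= 0))
    stop("combined scores must be positive", call. = FALSE)
  edges
}

#' Build the gene signal-transduction network
#'
#' Restricts a (typically median-filtered) edge table to pairs whose both
#' endpoints are differentially expressed, canonicalises the undirected
#' edges, removes duplicates, and drops isolated genes from the node set.
#'
#' @param deg_genes Character vector of differentially expressed gene ids.
#' @param edges Edge data frame (`gene_a`, `gene_b`, `combined_score`).
#' @return A list of class `gene_network` with elements `graph` (an
#'   [igraph][igraph::igraph-package] undirected graph whose edges carry
#'   `combined_score`) and `edges` (the retained edge table).
#' @export
build_network <- function(deg_genes, edges) {
  edges <- validate_edges(edges)
  keep <- edges$gene_a %in% deg_genes & edges$gene_b %in% deg_genes
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges)) {
    lo <- pmin(edges$gene_a, edges$gene_b)
    hi <- pmax(edges$gene_a, edges$gene_b)
    edges$gene_a <- lo; edges$gene_b <- hi
    edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  if (nrow(edges))
    igraph::E(g)$combined_score <- edges$combined_score
  structure(list(graph = g, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node centralities of the gene network
#'
#' Degree is the incident-edge count (or the sum of combined scores when
#' `weighted_degree = TRUE`); betweenness is unnormalised shortest-path
#' betweenness on the unweighted graph; closeness is computed per connected
#' component as `(nc - 1) / sum(shortest-path distances within the
#' component)`, with `nc` the component size, so disconnected networks —
#' routine for STRING subgraphs — stay well-defined.  Isolated components of
#' size 1 get closeness 0.
#'
#' @param net A `gene_network`.
#' @param weighted_degree Sum combined scores instead of counting edges.
#' @return Data frame with columns `gene_id`, `degree`, `closeness`,
#'   `betweenness`.
#' @export
compute_topology <- function(net, weighted_degree = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("network has no nodes", call. = FALSE)
  deg <- if (weighted_degree)
    igraph::strength(g, weights = igraph::E(g)$combined_score)
  else igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)

  d <- igraph::distances(g, weights = NA)
  comp <- igraph::components(g)$membership
  clo <- vapply(seq_len(igraph::vcount(g)), function(i) {
    same <- comp == comp[i]
    nc <- sum(same)
    if (nc < 2) return(0)
    (nc - 1) / sum(d[i, same])
  }, numeric(1))

  data.frame(gene_id = igraph::V(g)$name,
             degree = unname(deg), closeness = unname(clo),
             betweenness = unname(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Major genes: nodes above the median of all three centralities
#'
#' A gene qualifies only when its degree, closeness and betweenness are each
#' strictly greater than the median of that feature across all nodes;
#' genes sitting exactly at a median are excluded.
#'
#' @param topology Data frame from [compute_topology()].
#' @return Character vector of major-gene identifiers (input order).
#' @export
select_major_genes <- function(topology) {
  if (nrow(topology) < 2)
    stop("need at least 2 topology records", call. = FALSE)
  keep <- topology$degree > stats::median(topology$degree) &
    topology$closeness > stats::median(topology$closeness) &
    topology$betweenness > stats::median(topology$betweenness)
  topology$gene_id[keep]
}

#' Candidate biomarkers: major genes with strong dysregulation
#'
#' Among the major genes, keeps those whose differential-expression record
#' shows `p_value < p_threshold` together with a fold change above
#' `fold_threshold` or below its reciprocal (both strict), i.e. at least a
#' `fold_threshold`-fold change in either direction.  Output is sorted
#' alphabetically.
#'
#' @param major_genes Character vector from [select_major_genes()].
#' @param deg_records Data frame with `gene_id`, `fc`, `p_value` covering
#'   every major gene.
#' @param fold_threshold Linear fold-change cut (> 1), default 1.5.
#' @param p_threshold P-value cut, default 0.05.
#' @return Sorted character vector of candidate gene identifiers.
#' @export
select_candidates <- function(major_genes, deg_records,
                              fold_threshold = 1.5, p_threshold = 0.05) {
  if (fold_threshold <= 1)
    stop("`fold_threshold` must exceed 1", call. = FALSE)
  missing <- setdiff(major_genes, deg_records$gene_id)
  if (length(missing))
    stop("no differential-expression record for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rec <- deg_records[match(major_genes, deg_records$gene_id), ]
  keep <- rec$p_value < p_threshold &
    (rec$fc > fold_threshold | rec$fc < 1 / fold_threshold)
  sort(major_genes[keep])
}

#' Read a scored edge table
#'
#' Accepts the package's tab-separated dialect (`gene_a`, `gene_b`,
#' `combined_score`, header optional) as well as the STRING protein-links
#' dialect (space-separated with a `combined_score` column).
#'
#' @param path Path to the edge file.
#' @return Data frame with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
read_edge_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ""
  has_header <- grepl("combined_score|gene", first)
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < 3) stop("edge table needs 3 columns", call. = FALSE)
    names(tab)[1:3] <- c("gene_a", "gene_b", "combined_score")
  } else {
    sc <- grep("combined_score", names(tab))
    idc <- setdiff(seq_along(tab), sc)[1:2]
    tab <- stats::setNames(tab[, c(idc, sc[1])],
                           c("gene_a", "gene_b", "combined_score"))
  }
  validate_edges(tab[, c("gene_a", "gene_b", "combined_score")])
}

#' The published 16-gene topology table of the TG-response network
#'
#' Network centralities and differential-expression summaries of the 16
#' major genes reported for the TG-tablet response network in rheumatoid
#' arthritis, shipped as a plain-text fixture.  Feeding this table to
#' [select_candidates()] reproduces the six-gene signature
#' MX1, OASL, SPINK1, CRK, GRAPL, RNF2.
#'
#' @return Data frame with columns `gene_id`, `degree`, `closeness`,
#'   `betweenness`, `p_value`, `fc`, `direction`.
#' @export
tg_major_genes <- function() {
  path <- system.file("extdata", "tg_major_genes.tsv", package = "tgpredict")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
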