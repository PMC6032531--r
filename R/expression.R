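#' Two-group expression matrix
#'
#' Container for a genes-by-samples matrix of log2-scale expression values
#' together with the responder / non-responder label of every sample.  This
#' is the object every screening, modelling and evaluation function in the
#' package consumes.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.  Values are log2 expression units unless
#'   `linear_input = TRUE`.
#' @param labels Named character vector mapping each sample identifier to
#'   `"responder"` or `"non_responder"`.  Every column of `values` must be
#'   labelled and both groups must be non-empty.
#' @param linear_input If `TRUE` the matrix is on linear scale and is log2
#'   transformed on construction; non-positive values are rejected because
#'   they have no log2 image.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the numeric matrix) and `labels` (character vector aligned to the
#'   columns of `values`).
#' @export
expression_matrix <- function(values, labels, linear_input = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  if (linear_input) {
    if (any(values <= 0))
      stop("linear-scale input contains non-positive values; cannot log2 transform",
           call. = FALSE)
    values <- log2(values)
  }
  labels <- validate_labels(labels, colnames(values))
  structure(list(values = values, labels = labels[colnames(values)]),
            class = "expr_matrix")
}

validate_labels <- function(labels, sample_ids) {
  if (is.null(names(labels)))
    stop("`labels` must be named by sample identifier", call. = FALSE)
  labels <- vapply(labels, as.character, character(1))
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("samples without a label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(unname(labels)), c("responder", "non_responder"))
  if (length(bad))
    stop("labels must be 'responder' or 'non_responder'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  lab <- labels[sample_ids]
  if (!all(c("responder", "non_responder") %in% lab))
    stop("both responder and non_responder groups must be non-empty",
         call. = FALSE)
  lab
}

#' @export
print.expr_matrix <- function(x, ...) {
  n_r <- sum(x$labels == "responder")
  n_n <- sum(x$labels == "non_responder")
  cat(sprintf("expr_matrix: %d genes x %d samples (%d responders, %d non-responders)\n",
              nrow(x$values), ncol(x$values), n_r, n_n))
  invisible(x)
}

# Sample identifiers of each group, in matrix column order.
group_samples <- function(expr) {
  list(responder     = names(expr$labels)[expr$labels == "responder"],
       non_responder = names(expr$labels)[expr$labels == "non_responder"])
}

#' Restrict an expression matrix to a gene subset
#'
#' @param expr An `expr_matrix`.
#' @param genes Character vector of gene identifiers; all must be present.
#' @return An `expr_matrix` containing only `genes`, in the given order.
#' @export
subset_genes <- function(expr, genes) {
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  expression_matrix(expr$values[genes, , drop = FALSE], expr$labels)
}

#' Read / write the expression TSV dialect
#'
#' The on-disk format is a tab-separated table whose first column (`gene_id`)
#' holds gene identifiers and whose remaining columns are samples; labels
#' live in a two-column TSV (`sample_id`, `label`).
#'
#' @param path File path.
#' @param labels_path Path to the labels TSV.
#' @return `read_expression_tsv` returns an `expr_matrix`;
#'   `read_labels_tsv` a named character vector.
#' @export
read_expression_tsv <- function(path, labels_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  expression_matrix(mat, read_labels_tsv(labels_path))
}

#' @rdname read_expression_tsv
#' @export
read_labels_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}

#' @rdname read_expression_tsv
#' @param expr An `expr_matrix` to serialize.
#' @export
write_expression_tsv <- function(expr, path) {
  tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression_tsv
#' @param labels Named character label vector to serialize.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
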