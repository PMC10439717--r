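#' Construct a cells-by-genes expression matrix
#'
#' The package-wide container for expression data: a dense numeric matrix
#' with cells in rows and genes in columns, carrying unique cell and gene
#' identifiers as dimnames and a flag recording whether the values have
#' been z-score standardized.
#'
#' @param values Numeric matrix, `n` cells by `d` genes. All values must be
#'   finite.
#' @param gene_ids Character vector of `d` unique gene identifiers. Defaults
#'   to the column names of `values`.
#' @param cell_ids Character vector of `n` unique cell identifiers. Defaults
#'   to the row names of `values`.
#' @param standardized Logical; `TRUE` when `values` are already z-scored.
#'
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   `cell_ids` as rownames, `gene_ids` as colnames, and a `standardized`
#'   attribute.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values),
                              standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values))
    stop("length of gene_ids (", length(gene_ids),
         ") does not match gene dimension (", ncol(values), ")", call. = FALSE)
  if (length(cell_ids) != nrow(values))
    stop("length of cell_ids (", length(cell_ids),
         ") does not match cell dimension (", nrow(values), ")", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("cell_ids must be unique", call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(values, standardized = isTRUE(standardized),
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes (%s)\n",
              nrow(x), ncol(x),
              if (is_standardized(x)) "standardized" else "raw scale"))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An object to test or query.
#' @export
is_standardized <- function(x) isTRUE(attr(x, "standardized"))

#' Gene and cell identifier accessors
#'
#' @param x An `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) colnames(x)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) rownames(x)

# internal: strip class and flags, keep plain numeric matrix with dimnames
as_plain_matrix <- function(x) {
  attr(x, "standardized") <- NULL
  class(x) <- NULL
  x
}

#' Construct a per-cell label set
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param labels Character vector of cell type labels, same length; labels
#'   are stripped of surrounding whitespace and must be non-empty.
#'
#' @return An object of class `label_set` with elements `cell_ids` and
#'   `labels`, preserving input order.
#' @export
label_set <- function(cell_ids, labels) {
  cell_ids <- as.character(cell_ids)
  labels <- trimws(as.character(labels))
  if (length(cell_ids) != length(labels))
    stop("cell_ids and labels must have equal length", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_id in label set: ",
         cell_ids[anyDuplicated(cell_ids)], call. = FALSE)
  if (any(is.na(labels)) || any(labels == ""))
    stop("labels must be non-empty", call. = FALSE)
  structure(list(cell_ids = cell_ids, labels = labels), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d cells, %d distinct types\n",
              length(x$cell_ids), length(unique(x$labels))))
  invisible(x)
}

#' @export
length.label_set <- function(x) length(x$cell_ids)
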