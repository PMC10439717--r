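#' Read an expression matrix from disk
#'
#' Reads dense delimited matrices or Matrix Market triplets into the
#' package's internal cells-by-genes orientation. Dense files carry one
#' header row and one identifier column; when the file stores genes in rows
#' (`orientation = "genes_by_cells"`, the common public layout) the matrix
#' is transposed on load. Matrix Market input follows the 10x-style triplet
#' layout: an `.mtx` coordinate file with `genes.tsv` and `barcodes.tsv`
#' sidecars in the same directory, genes in rows. Sparse input is densified.
#'
#' @param path Path to the matrix file.
#' @param format One of `"dense_tsv"`, `"dense_csv"`, `"mtx_triplet"`. The
#'   default infers `dense_tsv`/`dense_csv` from the `.tsv`/`.csv` extension
#'   and `mtx_triplet` from `.mtx`.
#' @param orientation `"cells_by_genes"` or `"genes_by_cells"`, describing
#'   the on-disk layout. Default `"cells_by_genes"` for dense files; `.mtx`
#'   triplets default to `"genes_by_cells"` per the 10x convention.
#'
#' @return An [expression_matrix], cells in rows.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "dense_tsv",
                                              "dense_csv", "mtx_triplet"),
                                   orientation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     tsv = "dense_tsv", txt = "dense_tsv",
                     csv = "dense_csv", mtx = "mtx_triplet",
                     stop("cannot infer format from extension '", ext,
                          "'; pass `format`", call. = FALSE))
  }
  if (format == "mtx_triplet") {
    if (is.null(orientation)) orientation <- "genes_by_cells"
    return(read_mtx_triplet(path, orientation))
  }
  if (is.null(orientation)) orientation <- "cells_by_genes"
  orientation <- match.arg(orientation, c("cells_by_genes", "genes_by_cells"))
  sep <- if (format == "dense_tsv") "\t" else ","
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
    error = function(e) stop("malformed header or body in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) < 2)
    stop("malformed header: expected an id column plus at least one data ",
         "column in ", path, call. = FALSE)
  row_ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num)) {
    j <- which(non_num)[1]
    i <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
    stop("non-numeric value at row ", if (is.na(i)) "?" else i,
         ", column '", colnames(body)[j], "' of ", path, call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- row_ids
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m)
}

read_mtx_triplet <- function(path, orientation) {
  orientation <- match.arg(orientation, c("genes_by_cells", "cells_by_genes"))
  dir <- dirname(path)
  gene_file <- file.path(dir, "genes.tsv")
  barcode_file <- file.path(dir, "barcodes.tsv")
  if (!file.exists(gene_file) || !file.exists(barcode_file))
    stop("mtx_triplet requires genes.tsv and barcodes.tsv alongside ",
         path, call. = FALSE)
  sm <- tryCatch(Matrix::readMM(path),
                 error = function(e) stop("malformed Matrix Market file ",
                                          path, ": ", conditionMessage(e),
                                          call. = FALSE))
  genes <- data.table::fread(gene_file, header = FALSE,
                             data.table = FALSE)[[1]]
  barcodes <- data.table::fread(barcode_file, header = FALSE,
                                data.table = FALSE)[[1]]
  n_row_ids <- if (orientation == "genes_by_cells") length(genes) else length(barcodes)
  n_col_ids <- if (orientation == "genes_by_cells") length(barcodes) else length(genes)
  if (nrow(sm) != n_row_ids || ncol(sm) != n_col_ids)
    stop("sidecar lengths (", length(genes), " genes, ", length(barcodes),
         " barcodes) do not match matrix dimensions ", nrow(sm), " x ",
         ncol(sm), call. = FALSE)
  m <- as.matrix(sm)
  if (orientation == "genes_by_cells") {
    dimnames(m) <- list(genes, barcodes)
    m <- t(m)
  } else {
    dimnames(m) <- list(barcodes, genes)
  }
  expression_matrix(m)
}

#' Write an expression matrix as a dense delimited file
#'
#' Writes cells in rows with a `cell_id` identifier column and gene ids as
#' the header, the layout [read_expression_matrix] reads back with
#' `orientation = "cells_by_genes"`.
#'
#' @param x An [expression_matrix].
#' @param path Output path; `.tsv` or `.csv` extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  dt <- data.table::data.table(cell_id = cell_ids(x))
  dt <- cbind(dt, data.table::as.data.table(as_plain_matrix(x)))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read per-cell type labels
#'
#' Expects a two-column delimited file (`cell_id`, `label`) with a header
#' row; tab or comma delimited. Labels are stripped of surrounding
#' whitespace; file order is preserved.
#'
#' @param path Path to the label file.
#' @return A [label_set].
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2)
    stop("label file must have cell_id and label columns: ", path,
         call. = FALSE)
  if (any(is.na(dt[[2]])) || any(trimws(dt[[2]]) == ""))
    stop("missing label value in ", path, call. = FALSE)
  label_set(dt[[1]], dt[[2]])
}

#' Write per-cell type labels
#'
#' @param labels A [label_set].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_cell_labels <- function(labels, path) {
  data.table::fwrite(data.table::data.table(cell_id = labels$cell_ids,
                                            label = labels$labels),
                     path, sep = "\t")
  invisible(path)
}

#' Align an expression matrix onto a reference gene space
#'
#' Reorders the columns of `target` to match `reference_genes` exactly.
#' Genes absent from the target are filled with `fill_value`; genes present
#' in the target but not in the reference are dropped. Matching is by exact
#' string identity. This is the step that places a test dataset from one
#' sequencing platform into the gene space a model was trained on.
#'
#' @param reference_genes Character vector of unique gene identifiers
#'   defining the output column order.
#' @param target An [expression_matrix] to realign.
#' @param fill_value Value for unmeasured genes; default 0, the per-gene
#'   mean on the z-scored scale.
#'
#' @return An [expression_matrix] with columns exactly `reference_genes`;
#'   the number of genes found in the target is attached as attribute
#'   `matched_genes`.
#' @export
align_genes <- function(reference_genes, target, fill_value = 0) {
  reference_genes <- as.character(reference_genes)
  if (anyDuplicated(reference_genes))
    stop("reference_genes must be unique", call. = FALSE)
  matched <- intersect(reference_genes, gene_ids(target))
  if (length(matched) == 0)
    stop("no overlapping genes between reference and target; ",
         "datasets appear incompatible", call. = FALSE)
  out <- matrix(fill_value, nrow = nrow(target),
                ncol = length(reference_genes),
                dimnames = list(cell_ids(target), reference_genes))
  out[, matched] <- as_plain_matrix(target)[, matched, drop = FALSE]
  res <- expression_matrix(out, standardized = is_standardized(target))
  attr(res, "matched_genes") <- length(matched)
  res
}

#' Write per-cell predictions with class probabilities
#'
#' @param cell_ids Character vector of cell identifiers.
#' @param predicted_labels Character vector of predicted types, same length.
#' @param probabilities Numeric matrix, cells by classes, with class names
#'   as colnames; each row must sum to 1 within 1e-6.
#' @param path Output path (TSV): columns `cell_id`, `predicted_label`,
#'   then one probability column per class.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(cell_ids, predicted_labels, probabilities,
                              path) {
  n <- length(cell_ids)
  if (length(predicted_labels) != n || nrow(probabilities) != n)
    stop("cell_ids, predicted_labels and probabilities disagree in length",
         call. = FALSE)
  if (is.null(colnames(probabilities)))
    stop("probabilities must carry class names as colnames", call. = FALSE)
  rs <- rowSums(probabilities)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1 (worst deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  dt <- data.table::data.table(cell_id = as.character(cell_ids),
                               predicted_label = as.character(predicted_labels))
  dt <- cbind(dt, data.table::as.data.table(probabilities))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read back a predictions file written by [write_predictions]
#'
#' @param path Path to the predictions TSV.
#' @return A list with `cell_ids`, `predicted_labels` and the probability
#'   matrix.
#' @export
read_predictions <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  probs <- as.matrix(dt[, -(1:2), drop = FALSE])
  rownames(probs) <- dt[[1]]
  list(cell_ids = as.character(dt[[1]]),
       predicted_labels = as.character(dt[[2]]),
       probabilities = probs)
}

#' Write a cell embedding matrix as dense TSV
#'
#' @param embedding Numeric matrix, cells by embedding dimensions, with cell
#'   identifiers as rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embedding, path) {
  dt <- data.table::data.table(cell_id = rownames(embedding))
  m <- embedding
  colnames(m) <- paste0("E", seq_len(ncol(m)))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
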