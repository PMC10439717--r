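#' Z-score standardization of expression values
#'
#' Transforms each gene to mean 0 and standard deviation 1 across cells,
#' `(f - E(f)) / Std(f)`, which makes expression levels comparable across
#' genes before embedding. The standard deviation is the population form
#' (divide by n). Genes that are constant across cells map to 0 rather than
#' being dropped, so the gene dimension `d` is preserved.
#'
#' When `params` is supplied the stored means and deviations are applied
#' as-is (reference-based standardization, used to place a test dataset on
#' the scale of a training dataset); otherwise the moments are computed
#' from `x` itself.
#'
#' @param x An [expression_matrix] (not already standardized) or plain
#'   numeric matrix, cells by genes.
#' @param params Optional standardization parameters from a previous call.
#'
#' @return A list with `matrix` (the standardized [expression_matrix]) and
#'   `params`, a `standardization_params` object holding `gene_means`,
#'   `gene_stds` and `constant_gene_mask`.
#' @export
zscore_transform <- function(x, params = NULL) {
  if (inherits(x, "expression_matrix") && is_standardized(x))
    stop("matrix is already standardized", call. = FALSE)
  m <- if (inherits(x, "expression_matrix")) as_plain_matrix(x) else x
  if (anyNA(m)) stop("input contains NA values", call. = FALSE)
  d <- ncol(m)
  n <- nrow(m)
  if (is.null(params)) {
    mu <- colMeans(m)
    # population std: divide by n
    sd_pop <- sqrt(colMeans(m^2) - mu^2)
    sd_pop[sd_pop < 0] <- 0  # guard tiny negative from roundoff
    params <- standardization_params(mu, sd_pop)
  } else {
    if (!inherits(params, "standardization_params"))
      stop("`params` must be a standardization_params object", call. = FALSE)
    if (length(params$gene_means) != d)
      stop("params length (", length(params$gene_means),
           ") does not match gene dimension (", d, ")", call. = FALSE)
  }
  denom <- ifelse(params$constant_gene_mask, 1, params$gene_stds)
  z <- sweep(m, 2, params$gene_means, "-")
  z <- sweep(z, 2, denom, "/")
  z[, params$constant_gene_mask] <- 0
  out <- expression_matrix(z,
                           gene_ids = colnames(m),
                           cell_ids = rownames(m),
                           standardized = TRUE)
  list(matrix = out, params = params)
}

#' @rdname zscore_transform
#' @param gene_means,gene_stds Numeric vectors of per-gene moments.
#' @export
standardization_params <- function(gene_means, gene_stds) {
  if (length(gene_means) != length(gene_stds))
    stop("gene_means and gene_stds must have equal length", call. = FALSE)
  if (any(gene_stds < 0))
    stop("gene_stds must be non-negative", call. = FALSE)
  structure(list(gene_means = gene_means, gene_stds = gene_stds,
                 constant_gene_mask = gene_stds == 0),
            class = "standardization_params")
}

#' Encode cell type labels for classification
#'
#' Classes are the sorted unique labels, making the integer coding
#' deterministic across runs. Indices are 1-based (R convention); the
#' one-hot matrix has exactly one 1 per row.
#'
#' @param labels A [label_set] or character vector of labels.
#' @return An `encoded_labels` object with `class_names` (sorted unique
#'   labels), `indices` (per-cell integers in `1..J`), `one_hot` (n x J
#'   binary matrix) and `n_classes`. A single distinct label is allowed but
#'   flagged `trainable = FALSE`.
#' @export
encode_labels <- function(labels) {
  lab <- if (inherits(labels, "label_set")) labels$labels else
    trimws(as.character(labels))
  if (length(lab) == 0) stop("no labels to encode", call. = FALSE)
  class_names <- sort(unique(lab))
  J <- length(class_names)
  idx <- match(lab, class_names)
  one_hot <- matrix(0L, nrow = length(lab), ncol = J,
                    dimnames = list(NULL, class_names))
  one_hot[cbind(seq_along(idx), idx)] <- 1L
  structure(list(class_names = class_names, indices = idx,
                 one_hot = one_hot, n_classes = J, trainable = J >= 2),
            class = "encoded_labels")
}

#' @export
print.encoded_labels <- function(x, ...) {
  cat(sprintf("encoded_labels: %d cells, J = %d classes\n",
              length(x$indices), x$n_classes))
  invisible(x)
}

#' Split cells into training and test sets
#'
#' The default protocol is an unstratified random split with
#' `|test| = round(test_fraction * n)` and the remainder in training.
#' The stratified variant preserves each class's proportion within one
#' cell; classes with fewer than 2 members go entirely to training with a
#' warning.
#'
#' @param n Number of cells.
#' @param labels Optional `encoded_labels`, required when `stratified`.
#' @param test_fraction Fraction of cells held out; default 0.2.
#' @param seed Integer seed making the split reproducible.
#' @param stratified Logical; preserve class proportions.
#'
#' @return A `data_split` object with integer vectors `train_indices` and
#'   `test_indices` (1-based, disjoint, covering `1..n`), plus the `seed`,
#'   `test_fraction` and `stratified` flag.
#' @export
split_train_test <- function(n, labels = NULL, test_fraction = 0.2,
                             seed = 1L, stratified = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (stratified && is.null(labels))
    stop("stratified split requires labels", call. = FALSE)
  rng <- local_rng(seed)
  if (!stratified) {
    n_test <- round(test_fraction * n)
    test_idx <- sort(sample.int(n, n_test))
  } else {
    idx_by_class <- split(seq_len(n), labels$indices)
    test_idx <- integer(0)
    for (cls in idx_by_class) {
      if (length(cls) < 2) {
        warning("class with fewer than 2 cells kept entirely in training",
                call. = FALSE)
        next
      }
      k <- round(test_fraction * length(cls))
      if (k > 0) test_idx <- c(test_idx, sample(cls, k))
    }
    test_idx <- sort(test_idx)
  }
  structure(list(train_indices = setdiff(seq_len(n), test_idx),
                 test_indices = test_idx,
                 seed = seed, test_fraction = test_fraction,
                 stratified = stratified),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data_split: %d train / %d test (%s, seed %d)\n",
              length(x$train_indices), length(x$test_indices),
              if (x$stratified) "stratified" else "random", x$seed))
  invisible(x)
}

# internal: scoped RNG so package functions are deterministic under their
# seed argument and do not disturb the caller's random stream
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
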