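#' Classification accuracy
#'
#' Fraction of cells whose predicted type equals the true type:
#' `accuracy = (1/n) sum_i delta(pred_i, true_i)`.
#'
#' @param predicted,true Character vectors of equal, positive length.
#' @return A value in `[0, 1]`.
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) == 0)
    stop("predicted and true must have equal positive length",
         call. = FALSE)
  mean(predicted == true)
}

#' Confusion matrix and per-cell misclassification report
#'
#' @param predicted,true Character label vectors over `class_names`.
#' @param class_names Ordered class vocabulary; defaults to the sorted
#'   union of observed labels.
#' @param cell_ids Optional cell identifiers for the misclassification
#'   listing.
#' @return An `evaluation_report`: `accuracy`; `confusion` (J x J integer
#'   matrix, rows true, columns predicted, entries summing to n);
#'   `misclassified`, a data.frame of `(cell_id, true_label,
#'   predicted_label)` for every off-diagonal cell; and `n`.
#' @export
confusion_and_misclassified <- function(predicted, true,
                                        class_names = NULL,
                                        cell_ids = NULL) {
  if (length(predicted) != length(true))
    stop("predicted and true must have equal length", call. = FALSE)
  n <- length(true)
  if (is.null(class_names))
    class_names <- sort(unique(c(predicted, true)))
  if (!all(predicted %in% class_names) || !all(true %in% class_names))
    stop("labels outside the class vocabulary", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  conf <- table(factor(true, levels = class_names),
                factor(predicted, levels = class_names))
  conf <- matrix(as.integer(conf), nrow = length(class_names),
                 dimnames = list(true = class_names,
                                 predicted = class_names))
  wrong <- which(predicted != true)
  mis <- data.frame(cell_id = cell_ids[wrong], true_label = true[wrong],
                    predicted_label = predicted[wrong],
                    stringsAsFactors = FALSE)
  structure(list(accuracy = sum(diag(conf)) / n, confusion = conf,
                 misclassified = mis, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: accuracy %.4f on %d cells (%d wrong)\n",
              x$accuracy, x$n, nrow(x$misclassified)))
  if (!is.null(x$per_method)) {
    cat("per-method accuracies:\n")
    for (m in names(x$per_method))
      cat(sprintf("  %-8s %.4f\n", m, x$per_method[[m]]))
  }
  invisible(x)
}

#' Write an evaluation report to a run directory
#'
#' Emits `confusion.tsv` (the confusion matrix), `misclassified.tsv`
#' (per-cell mispredictions) and `summary.tsv` (key-value run summary).
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- data.table::data.table(true = rownames(report$confusion))
  conf <- cbind(conf, data.table::as.data.table(report$confusion + 0L))
  data.table::fwrite(conf, file.path(dir, "confusion.tsv"), sep = "\t")
  data.table::fwrite(report$misclassified,
                     file.path(dir, "misclassified.tsv"), sep = "\t")
  keys <- data.frame(key = c("n_cells", "accuracy", "n_misclassified"),
                     value = c(report$n,
                               format(report$accuracy, digits = 15),
                               nrow(report$misclassified)))
  if (!is.null(report$per_method))
    keys <- rbind(keys,
                  data.frame(key = paste0("accuracy_",
                                          names(report$per_method)),
                             value = vapply(report$per_method, format,
                                            character(1), digits = 15)))
  data.table::fwrite(keys, file.path(dir, "summary.tsv"), sep = "\t")
  invisible(dir)
}

#' Cross-platform (batch-robustness) evaluation
#'
#' Trains the full embedding + classifier pipeline on one dataset and
#' evaluates it on a second dataset from another platform: test genes are
#' aligned onto the training gene order, the test matrix is standardized
#' either with its own statistics (`"per_dataset"`, the default: each
#' dataset is z-scored on its own) or with the training statistics
#' (`"reference"`), and the trained model predicts every test cell. Test
#' cells whose true type never occurs in training are counted, flagged in
#' the report, and excluded from the accuracy.
#'
#' @param train,test Lists with elements `expression` (an
#'   [expression_matrix], raw scale) and `labels` (a [label_set]).
#' @param config A [pipeline_config].
#' @param standardize_test `"per_dataset"` or `"reference"`.
#' @return An `evaluation_report` with extra fields `matched_genes`,
#'   `unseen_label_cells` (count excluded) and `train_accuracy_selftest`.
#' @export
cross_platform_evaluate <- function(train, test,
                                    config = pipeline_config(),
                                    standardize_test = c("per_dataset",
                                                         "reference")) {
  standardize_test <- match.arg(standardize_test)
  if (length(intersect(unique(train$labels$labels),
                       unique(test$labels$labels))) == 0)
    stop("train and test label vocabularies do not overlap", call. = FALSE)
  model <- fit_pipeline(train$expression, train$labels, config)
  aligned <- align_genes(model$gene_ids, test$expression)
  matched <- attr(aligned, "matched_genes")
  Xz <- if (standardize_test == "per_dataset")
    zscore_transform(aligned)$matrix
  else zscore_transform(aligned, model$standardization)$matrix
  pred <- predict_cells(model, Xz, standardize = "none")
  seen <- test$labels$labels %in% model$classifier$class_names
  rep <- confusion_and_misclassified(
    pred$labels[seen], test$labels$labels[seen],
    class_names = sort(unique(c(model$classifier$class_names,
                                test$labels$labels[seen]))),
    cell_ids = test$labels$cell_ids[seen])
  rep$matched_genes <- matched
  rep$unseen_label_cells <- sum(!seen)
  rep
}

#' Run several classification methods on one shared split
#'
#' Standardizes the full matrix once, applies the identical train/test
#' split to every method, and reports each method's test accuracy so the
#' comparison is well-defined. Methods: `"sdae_nn"` (the embedding
#' pipeline), `"pca_nn"`, `"raw_nn"`, `"lr"`.
#'
#' @param X An [expression_matrix] (raw scale).
#' @param labels A [label_set].
#' @param split A `data_split` from [split_train_test]; default 80/20
#'   random under `config$seed`.
#' @param methods Subset of the four method names.
#' @param config A [pipeline_config]; also supplies the PCA width
#'   (`config$pca_components`, default the embedding width) and the LR
#'   penalty (`config$lr_l2`).
#' @return An `evaluation_report` for the first method listed, with
#'   `per_method` (named accuracies) and `input_digest` (checksum of the
#'   standardized matrix and split, proving shared inputs).
#' @export
compare_methods <- function(X, labels,
                            split = NULL,
                            methods = c("sdae_nn", "pca_nn", "raw_nn",
                                        "lr"),
                            config = pipeline_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  Xz <- zscore_transform(X)$matrix
  if (is.null(split))
    split <- split_train_test(nrow(Xz), test_fraction = 0.2,
                              seed = config$seed)
  tr <- split$train_indices
  te <- split$test_indices
  y_tr <- labels$labels[tr]
  y_te <- labels$labels[te]
  Xtr <- as_plain_matrix(Xz)[tr, , drop = FALSE]
  Xte <- as_plain_matrix(Xz)[te, , drop = FALSE]
  digest <- input_digest(Xz, split)
  per_method <- list()
  first_report <- NULL
  for (m in methods) {
    pred_labels <- switch(
      m,
      sdae_nn = {
        model <- fit_pipeline(
          expression_matrix(Xtr, standardized = TRUE),
          label_set(labels$cell_ids[tr], y_tr), config)
        predict_cells(model, Xte, standardize = "none")$labels
      },
      pca_nn = pca_nn_classify(Xtr, y_tr, Xte,
                               k = config$pca_components,
                               nn_cfg = config$classifier,
                               adam = config$adam)$labels,
      raw_nn = raw_nn_classify(Xtr, y_tr, Xte,
                               nn_cfg = config$classifier,
                               adam = config$adam)$labels,
      lr = logistic_predict(logistic_train(Xtr, y_tr,
                                           l2_strength = config$lr_l2),
                            Xte)$labels)
    per_method[[m]] <- accuracy(pred_labels, y_te)
    if (is.null(first_report))
      first_report <- confusion_and_misclassified(
        pred_labels, y_te,
        class_names = sort(unique(c(pred_labels, y_te))),
        cell_ids = labels$cell_ids[te])
  }
  first_report$per_method <- per_method
  first_report$input_digest <- digest
  first_report
}

# internal: cheap deterministic checksum binding a comparison to its
# standardized inputs and split
input_digest <- function(Xz, split) {
  v <- c(dim(Xz), sum(Xz) %% 1e6, sum(abs(Xz)) %% 1e6,
         sum(split$train_indices), sum(split$test_indices))
  paste(format(v, digits = 12), collapse = ":")
}
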