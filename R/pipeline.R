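#' Configuration for the full embedding + classification pipeline
#'
#' Bundles every tunable of the two training stages. The shipped defaults
#' are the full-scale recipe: encoder `d-500-500-2000-1000`, 200
#' pretraining epochs per layer, 400 fine-tuning epochs with the 0.1 /
#' divide-by-10-every-80 schedule, and a `1000-528-256-J` classifier
#' trained 1200 epochs by Adam at 1e-3. `fast = TRUE` switches to the
#' desk-scale profile (20 / 40 / 200 epochs, same everything else) for
#' quick experiments; it is not the full-scale recipe.
#'
#' @param hidden_widths Encoder widths after the input layer; the last
#'   entry is the embedding width. Default `c(500, 500, 2000, 1000)`.
#' @param classifier_hidden Hidden widths of the classifier; default
#'   `c(528, 256)`.
#' @param pretrain A [pretrain_config].
#' @param finetune A [finetune_config].
#' @param classifier A [classifier_train_config].
#' @param adam An [adam_config].
#' @param pca_components PCA width for the `pca_nn` comparison; default
#'   equals the embedding width (capped at `min(n, d)` when used).
#' @param lr_l2 L2 strength for the logistic-regression comparison;
#'   default 1.
#' @param seed Master seed; all stage seeds are derived from it by fixed
#'   offsets, so one integer controls end-to-end reproducibility.
#' @param fast Logical; use the reduced-epoch profile.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(hidden_widths = c(500, 500, 2000, 1000),
                            classifier_hidden = c(528, 256),
                            pretrain = NULL, finetune = NULL,
                            classifier = NULL, adam = adam_config(),
                            pca_components = NULL, lr_l2 = 1,
                            seed = 1L, fast = FALSE) {
  if (is.null(pretrain))
    pretrain <- pretrain_config(epochs = if (fast) 20 else 200)
  if (is.null(finetune))
    finetune <- finetune_config(epochs = if (fast) 40 else 400)
  if (is.null(classifier))
    classifier <- classifier_train_config(epochs = if (fast) 200 else 1200)
  if (is.null(pca_components))
    pca_components <- hidden_widths[length(hidden_widths)]
  classifier$seed <- as.integer(seed) + 3L
  structure(list(hidden_widths = as.integer(hidden_widths),
                 classifier_hidden = as.integer(classifier_hidden),
                 pretrain = pretrain, finetune = finetune,
                 classifier = classifier, adam = adam,
                 pca_components = pca_components, lr_l2 = lr_l2,
                 seed = as.integer(seed), fast = isTRUE(fast)),
            class = "pipeline_config")
}

#' Train the full cell-type identification pipeline
#'
#' The three stages in order: (i) z-score standardization of the
#' expression matrix (skipped when the input is already standardized);
#' (ii) greedy layer-wise pretraining of the stacked denoising
#' autoencoder followed by joint fine-tuning of the unrolled stack;
#' (iii) training of the deep softmax classifier by Adam on the
#' bottleneck cell embeddings, which are treated as frozen features.
#'
#' @param X An [expression_matrix], cells by genes.
#' @param labels A [label_set] (or character vector) of per-cell types,
#'   in the row order of `X`.
#' @param config A [pipeline_config].
#' @return A `cell_type_model` holding the fine-tuned `sdae`, the trained
#'   `classifier`, the `standardization` parameters, the training
#'   `gene_ids`, the `config`, and training diagnostics
#'   (`finetune_loss`, `train_accuracy`).
#' @export
fit_pipeline <- function(X, labels, config = pipeline_config()) {
  lab_vec <- if (inherits(labels, "label_set")) labels$labels else labels
  if (length(lab_vec) != nrow(X))
    stop("labels (", length(lab_vec), ") do not match cells (", nrow(X),
         ")", call. = FALSE)
  if (inherits(X, "expression_matrix") && is_standardized(X)) {
    Xz <- X
    std <- NULL
  } else {
    z <- zscore_transform(X)
    Xz <- z$matrix
    std <- z$params
  }
  topology <- c(ncol(Xz), config$hidden_widths)
  sdae <- greedy_pretrain(topology, Xz, config$pretrain,
                          seed = config$seed + 1L)
  ft <- finetune_sdae(sdae, Xz, config$finetune, seed = config$seed + 2L)
  emb <- encode_cells(ft$model, Xz)
  enc <- encode_labels(lab_vec)
  clf <- train_classifier(emb, enc, config$classifier, config$adam,
                          topology = c(ncol(emb), config$classifier_hidden,
                                       enc$n_classes))
  train_pred <- predict(clf, emb)
  structure(list(sdae = ft$model, classifier = clf,
                 standardization = std, gene_ids = gene_ids(Xz),
                 config = config,
                 finetune_loss = ft$loss_history,
                 train_accuracy = accuracy(train_pred$labels, lab_vec)),
            class = "cell_type_model")
}

#' @export
print.cell_type_model <- function(x, ...) {
  cat(sprintf(
    "cell_type_model: %d genes -> %d-dim embedding -> %d classes (training accuracy %.3f)\n",
    length(x$gene_ids), rev(x$sdae$topology)[1],
    length(x$classifier$class_names), x$train_accuracy))
  invisible(x)
}

#' Predict cell types for new cells
#'
#' Aligns the new matrix onto the training gene space when identifiers
#' are available, standardizes it per `standardize`, embeds it through
#' the encoder, and classifies.
#'
#' @param model A `cell_type_model` from [fit_pipeline].
#' @param X New cells-by-genes matrix. If its gene set differs from the
#'   training genes it is passed through [align_genes] first.
#' @param standardize How to place `X` on the z-scored scale:
#'   `"per_dataset"` (z-score with its own statistics, the default),
#'   `"reference"` (apply the training-set moments), or `"none"` (input
#'   is already standardized).
#' @return A list with `labels`, `probabilities` and the `embedding`.
#' @export
predict_cells <- function(model, X,
                          standardize = c("per_dataset", "reference",
                                          "none")) {
  standardize <- match.arg(standardize)
  if (inherits(X, "expression_matrix") &&
      !identical(gene_ids(X), model$gene_ids))
    X <- align_genes(model$gene_ids, X)
  Xz <- switch(standardize,
               per_dataset = zscore_transform(X)$matrix,
               reference = {
                 if (is.null(model$standardization))
                   stop("model carries no training standardization; it ",
                        "was fitted on pre-standardized data", call. = FALSE)
                 zscore_transform(X, model$standardization)$matrix
               },
               none = X)
  emb <- encode_cells(model$sdae, Xz)
  pred <- predict(model$classifier, emb)
  list(labels = pred$labels, probabilities = pred$probabilities,
       embedding = emb)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the autoencoder layers
#' and activation tags, classifier weights and class names, the
#' standardization parameters, the gene space, and the training
#' configuration. Loading is bit-faithful: the restored object is
#' identical to the saved one.
#'
#' @param model A `cell_type_model` (or any model object).
#' @param path Checkpoint path.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path,
         "; run the training step first", call. = FALSE)
  readRDS(path)
}
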