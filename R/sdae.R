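#' Masking corruption specification
#'
#' Describes the noise injected during denoising-autoencoder training:
#' each input entry is independently set to zero with probability `rate`,
#' emulating dropout zeros in single-cell expression data.
#'
#' @param rate Masking probability in `[0, 1]`; default 0.2.
#' @param kind Corruption type; only `"masking"` is implemented.
#' @param seed Optional integer seed; when supplied, [mask_corrupt] is
#'   deterministic for this spec.
#' @return A `corruption_spec` object.
#' @export
corruption_spec <- function(rate = 0.2, kind = "masking", seed = NULL) {
  kind <- match.arg(kind, "masking")
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1)
    stop("corruption rate must lie in [0, 1]", call. = FALSE)
  structure(list(kind = kind, rate = rate, seed = seed),
            class = "corruption_spec")
}

#' Apply masking corruption to a matrix
#'
#' Sets each entry of `H` to zero independently with probability
#' `spec$rate`, leaving the remaining entries bit-identical. The input is
#' not modified.
#'
#' @param H Numeric matrix.
#' @param spec A [corruption_spec].
#' @return The corrupted matrix, same shape as `H`.
#' @export
mask_corrupt <- function(H, spec = corruption_spec()) {
  if (!inherits(spec, "corruption_spec"))
    stop("`spec` must be a corruption_spec", call. = FALSE)
  if (!is.null(spec$seed)) local_rng(spec$seed)
  corrupt_mask(H, spec$rate)
}

# internal: masking using the current RNG stream
corrupt_mask <- function(H, rate) {
  if (rate == 0) return(H)
  keep <- stats::runif(length(H)) >= rate
  out <- H
  out[!keep] <- 0
  out
}

#' Pretraining configuration for one denoising-autoencoder layer
#'
#' Defaults follow the training recipe for single-cell embedding: 200
#' epochs of mini-batch SGD with masking corruption at rate 0.2. The SGD
#' step size and momentum are tunable (0.1 and 0.9 by default).
#'
#' @param epochs Number of passes over the data (>= 1); default 200.
#' @param corruption A [corruption_spec]; default masking at 0.2.
#' @param learning_rate SGD step size; default 0.1.
#' @param momentum Classical momentum coefficient; default 0.9.
#' @param batch_size Mini-batch size; default 256.
#' @return A `pretrain_config` object.
#' @export
pretrain_config <- function(epochs = 200, corruption = corruption_spec(0.2),
                            learning_rate = 0.1, momentum = 0.9,
                            batch_size = 256) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), corruption = corruption,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size)),
            class = "pretrain_config")
}

#' Fine-tuning configuration for the unrolled autoencoder
#'
#' After greedy pretraining the encoder and reversed decoder layers are
#' joined into one deep autoencoder and trained jointly with SGD under a
#' step schedule: the learning rate starts at `base_learning_rate` and is
#' divided by `decay_factor` every `decay_interval` epochs.
#'
#' @param epochs Number of fine-tuning epochs; default 400.
#' @param base_learning_rate Initial step size; default 0.1.
#' @param decay_factor Division factor per decay; default 10 (> 1).
#' @param decay_interval Epochs between decays; default 80.
#' @param batch_size Mini-batch size; default 256.
#' @param momentum Momentum coefficient; default 0.9.
#' @return A `finetune_config` object.
#' @export
finetune_config <- function(epochs = 400, base_learning_rate = 0.1,
                            decay_factor = 10, decay_interval = 80,
                            batch_size = 256, momentum = 0.9) {
  if (decay_factor <= 1) stop("decay_factor must exceed 1", call. = FALSE)
  if (decay_interval < 1) stop("decay_interval must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 base_learning_rate = base_learning_rate,
                 decay_factor = decay_factor,
                 decay_interval = as.integer(decay_interval),
                 batch_size = as.integer(batch_size), momentum = momentum),
            class = "finetune_config")
}

#' Fine-tuning learning rate at a given epoch
#'
#' Evaluates the step schedule `base / factor^floor(epoch / interval)`;
#' epochs are counted from 0.
#'
#' @param cfg A [finetune_config].
#' @param epoch Zero-based epoch index.
#' @return The learning rate in effect at `epoch`.
#' @export
finetune_lr <- function(cfg, epoch) {
  cfg$base_learning_rate /
    cfg$decay_factor^floor(epoch / cfg$decay_interval)
}

#' Construct a denoising-autoencoder layer
#'
#' One encoder/decoder pair: `hidden = phi_e(H W_e + b_e)` and
#' `reconstruction = phi_d(hidden W_d + b_d)`.
#'
#' @param encoder_weights `in_dim x hidden_dim` matrix.
#' @param encoder_bias Length-`hidden_dim` vector.
#' @param decoder_weights `hidden_dim x in_dim` matrix.
#' @param decoder_bias Length-`in_dim` vector.
#' @param encoder_activation,decoder_activation One of `"relu"`, `"tanh"`,
#'   `"linear"`.
#' @return A `dae_layer` object.
#' @export
dae_layer <- function(encoder_weights, encoder_bias, decoder_weights,
                      decoder_bias, encoder_activation = "relu",
                      decoder_activation = "relu") {
  encoder_activation <- match.arg(encoder_activation,
                                  c("relu", "tanh", "linear"))
  decoder_activation <- match.arg(decoder_activation,
                                  c("relu", "tanh", "linear"))
  if (ncol(encoder_weights) != nrow(decoder_weights) ||
      nrow(encoder_weights) != ncol(decoder_weights))
    stop("encoder (", nrow(encoder_weights), " x ", ncol(encoder_weights),
         ") and decoder (", nrow(decoder_weights), " x ",
         ncol(decoder_weights), ") weight shapes are incompatible",
         call. = FALSE)
  if (length(encoder_bias) != ncol(encoder_weights) ||
      length(decoder_bias) != ncol(decoder_weights))
    stop("bias lengths do not match weight output dimensions", call. = FALSE)
  if (!all(is.finite(encoder_weights)) || !all(is.finite(decoder_weights)))
    stop("weights must be finite", call. = FALSE)
  structure(list(encoder = list(W = encoder_weights,
                                b = as.numeric(encoder_bias),
                                act = encoder_activation),
                 decoder = list(W = decoder_weights,
                                b = as.numeric(decoder_bias),
                                act = decoder_activation)),
            class = "dae_layer")
}

# internal: fresh randomly-initialized layer (draws from current stream)
new_dae_layer <- function(in_dim, hidden_dim, enc_act, dec_act) {
  enc <- init_dense_layer(in_dim, hidden_dim, enc_act)
  dec <- init_dense_layer(hidden_dim, in_dim, dec_act)
  dae_layer(enc$W, enc$b, dec$W, dec$b, enc_act, dec_act)
}

#' Apply a denoising-autoencoder layer
#'
#' Deterministic forward pass: encodes `H_in` and reconstructs it.
#'
#' @param layer A [dae_layer].
#' @param H_in Numeric matrix, cells by `in_dim`.
#' @return A list with `hidden` (cells x hidden_dim) and `reconstruction`
#'   (cells x in_dim).
#' @export
dae_apply <- function(layer, H_in) {
  if (ncol(H_in) != nrow(layer$encoder$W))
    stop("input width ", ncol(H_in), " does not match layer input dimension ",
         nrow(layer$encoder$W), call. = FALSE)
  A <- forward_stack(list(layer$encoder, layer$decoder), H_in)
  list(hidden = A[[2]], reconstruction = A[[3]])
}

#' Reconstruction loss of a denoising autoencoder
#'
#' Squared reconstruction error summed over genes and averaged over cells:
#' `L = (1/n) * sum_i sum_j (clean_ij - recon_ij)^2`.
#'
#' @param X_clean,X_recon Numeric matrices of identical shape.
#' @return A non-negative scalar, zero iff the matrices are identical.
#' @export
reconstruction_loss <- function(X_clean, X_recon) {
  if (!identical(dim(X_clean), dim(X_recon)))
    stop("clean and reconstructed matrices differ in shape", call. = FALSE)
  sum((X_clean - X_recon)^2) / nrow(X_clean)
}

#' Train a single denoising-autoencoder layer
#'
#' Minimizes the reconstruction loss between the clean input and the
#' reconstruction of its masked version by mini-batch SGD with momentum.
#' A fresh corruption mask is drawn for every mini-batch; the data order
#' is reshuffled each epoch. Fully deterministic under `seed`.
#'
#' @param layer A [dae_layer] (typically freshly initialized).
#' @param H_in Clean input matrix, cells by `in_dim`; must be finite.
#' @param cfg A [pretrain_config].
#' @param seed Optional integer seed scoping all randomness of this call.
#' @return A list with the trained `layer` and `loss_history`, the
#'   per-epoch reconstruction loss (summed over features, averaged over
#'   cells) on the corrupted batches.
#' @export
pretrain_layer <- function(layer, H_in, cfg = pretrain_config(),
                           seed = NULL) {
  if (!all(is.finite(H_in))) stop("H_in must be finite", call. = FALSE)
  if (!is.null(seed)) local_rng(seed)
  stack <- list(layer$encoder, layer$decoder)
  vel <- zero_velocity(stack)
  n <- nrow(H_in)
  d <- ncol(H_in)
  loss_history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batch_losses <- numeric(0)
    for (idx in batch_indices(n, cfg$batch_size)) {
      clean <- H_in[idx, , drop = FALSE]
      corrupted <- corrupt_mask(clean, cfg$corruption$rate)
      A <- forward_stack(stack, corrupted)
      recon <- A[[3]]
      loss <- sum((clean - recon)^2) / length(idx)
      check_finite_loss(loss, "layer pretraining")
      batch_losses <- c(batch_losses, loss)
      # optimizer gradient: elementwise mean of the squared error, which
      # rescales the per-cell loss by the constant 1/d
      delta <- 2 * (recon - clean) / (length(idx) * d) *
        act_deriv(stack[[2]]$act, recon)
      grads <- backward_stack(stack, A, delta)
      upd <- sgd_momentum_update(stack, grads, vel, cfg$learning_rate,
                                 cfg$momentum)
      stack <- upd$layers
      vel <- upd$velocity
    }
    loss_history[epoch] <- mean(batch_losses)
  }
  trained <- dae_layer(stack[[1]]$W, stack[[1]]$b, stack[[2]]$W,
                       stack[[2]]$b, layer$encoder$act, layer$decoder$act)
  list(layer = trained, loss_history = loss_history)
}

# activation assignment over the stack: relu everywhere except the
# bottleneck encoder (last) and the final decoder (the layer that outputs
# the gene dimension), which use tanh
sdae_activations <- function(topology) {
  n_layers <- length(topology) - 1L
  enc <- rep("relu", n_layers)
  enc[n_layers] <- "tanh"
  dec <- rep("relu", n_layers)
  dec[1L] <- "tanh"
  list(encoder = enc, decoder = dec)
}

#' Greedy layer-wise pretraining of a stacked denoising autoencoder
#'
#' Trains the first denoising autoencoder on the standardized expression
#' matrix, then each subsequent layer on the clean hidden representation
#' produced by the already-trained layers below it, with masking
#' corruption applied afresh to that layer's own input. Activations are
#' ReLU throughout except the bottleneck encoder layer and the final
#' decoder layer, which use tanh.
#'
#' @param topology Integer vector of layer widths starting at the gene
#'   dimension `d`, e.g. `c(d, 500, 500, 2000, 1000)` (the default
#'   architecture; the last entry is the embedding width).
#' @param X Standardized cells-by-genes matrix.
#' @param cfg A [pretrain_config] applied to every layer.
#' @param seed Integer seed controlling initialization, corruption masks
#'   and shuffling.
#' @return An `sdae_model` with the ordered trained layers, the topology,
#'   per-layer loss histories, and `finetuned = FALSE`.
#' @export
greedy_pretrain <- function(topology, X, cfg = pretrain_config(),
                            seed = 1L) {
  if (length(topology) < 2)
    stop("topology needs at least an input and one hidden width",
         call. = FALSE)
  if (ncol(X) != topology[1])
    stop("topology starts at ", topology[1], " but X has ", ncol(X),
         " genes", call. = FALSE)
  local_rng(seed)
  acts <- sdae_activations(topology)
  n_layers <- length(topology) - 1L
  layers <- vector("list", n_layers)
  losses <- vector("list", n_layers)
  H <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  for (l in seq_len(n_layers)) {
    layer <- new_dae_layer(topology[l], topology[l + 1L],
                           acts$encoder[l], acts$decoder[l])
    fit <- pretrain_layer(layer, H, cfg)
    layers[[l]] <- fit$layer
    losses[[l]] <- fit$loss_history
    # clean (uncorrupted) representation feeds the next level
    H <- dae_apply(fit$layer, H)$hidden
  }
  structure(list(layers = layers, topology = as.integer(topology),
                 pretrain_loss = losses, finetuned = FALSE),
            class = "sdae_model")
}

#' @export
print.sdae_model <- function(x, ...) {
  cat(sprintf("sdae_model: topology %s (%s)\n",
              paste(x$topology, collapse = "-"),
              if (x$finetuned) "fine-tuned" else "pretrained only"))
  invisible(x)
}

# internal: unroll encoders then reversed decoders into one deep stack
unroll_sdae <- function(model) {
  enc <- lapply(model$layers, `[[`, "encoder")
  dec <- lapply(rev(model$layers), `[[`, "decoder")
  c(enc, dec)
}

#' Widths of the unrolled autoencoder
#'
#' For the default architecture this is
#' `d, 500, 500, 2000, 1000, 2000, 500, 500, d`: the encoder followed by
#' the decoder in reverse training order.
#'
#' @param model An `sdae_model`.
#' @return Integer vector of layer widths.
#' @export
unrolled_widths <- function(model) {
  c(model$topology, rev(model$topology)[-1])
}

#' Joint fine-tuning of the stacked denoising autoencoder
#'
#' Connects all encoder layers with all decoder layers in reverse
#' training order and minimizes the reconstruction loss of the whole
#' stack on uncorrupted input, using mini-batch SGD with momentum under
#' the step schedule of [finetune_config]. Set `keep_corruption = TRUE`
#' to keep masking the input during fine-tuning.
#'
#' @param model A pretrained `sdae_model`.
#' @param X Standardized cells-by-genes matrix (the same gene space the
#'   model was pretrained on).
#' @param cfg A [finetune_config].
#' @param seed Integer seed for shuffling (and corruption if kept).
#' @param keep_corruption Logical; default `FALSE` (clean input).
#' @param corruption A [corruption_spec] used when `keep_corruption`.
#' @return A list with the fine-tuned `model` (flag set) and
#'   `loss_history`, the per-epoch reconstruction loss.
#' @export
finetune_sdae <- function(model, X, cfg = finetune_config(), seed = 1L,
                          keep_corruption = FALSE,
                          corruption = corruption_spec(0.2)) {
  if (!inherits(model, "sdae_model"))
    stop("`model` must be an sdae_model", call. = FALSE)
  Xm <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  if (ncol(Xm) != model$topology[1])
    stop("X has ", ncol(Xm), " genes but the model expects ",
         model$topology[1], call. = FALSE)
  local_rng(seed)
  stack <- unroll_sdae(model)
  vel <- zero_velocity(stack)
  n <- nrow(Xm)
  d <- ncol(Xm)
  loss_history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- finetune_lr(cfg, epoch - 1L)
    batch_losses <- numeric(0)
    for (idx in batch_indices(n, cfg$batch_size)) {
      clean <- Xm[idx, , drop = FALSE]
      input <- if (keep_corruption) corrupt_mask(clean, corruption$rate)
               else clean
      A <- forward_stack(stack, input)
      recon <- A[[length(A)]]
      loss <- sum((clean - recon)^2) / length(idx)
      check_finite_loss(loss, "fine-tuning")
      batch_losses <- c(batch_losses, loss)
      delta <- 2 * (recon - clean) / (length(idx) * d) *
        act_deriv(stack[[length(stack)]]$act, recon)
      grads <- backward_stack(stack, A, delta)
      upd <- sgd_momentum_update(stack, grads, vel, lr, cfg$momentum)
      stack <- upd$layers
      vel <- upd$velocity
    }
    loss_history[epoch] <- mean(batch_losses)
  }
  # fold the tuned weights back into per-layer encoder/decoder pairs
  n_layers <- length(model$layers)
  for (l in seq_len(n_layers)) {
    model$layers[[l]]$encoder <- stack[[l]]
    model$layers[[l]]$decoder <- stack[[2L * n_layers - l + 1L]]
  }
  model$finetuned <- TRUE
  list(model = model, loss_history = loss_history)
}

#' Extract cell embeddings from a trained autoencoder
#'
#' Deterministic forward pass through the encoder layers only, with no
#' corruption: the activations of the bottleneck (tanh) layer are the
#' cell embeddings.
#'
#' @param model An `sdae_model` (fine-tuned; set `allow_pretrained = TRUE`
#'   to embed with a merely pretrained stack).
#' @param X Standardized cells-by-genes matrix.
#' @param allow_pretrained Logical; default `FALSE`.
#' @return Numeric matrix, cells by embedding width, with cell identifiers
#'   as rownames when `X` carries them.
#' @export
encode_cells <- function(model, X, allow_pretrained = FALSE) {
  if (!model$finetuned && !allow_pretrained)
    stop("model is not fine-tuned; pass allow_pretrained = TRUE to embed ",
         "with a pretrained-only stack", call. = FALSE)
  Xm <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  if (ncol(Xm) != model$topology[1])
    stop("X has ", ncol(Xm), " genes but the model expects ",
         model$topology[1], "; use align_genes() to match gene spaces",
         call. = FALSE)
  enc <- lapply(model$layers, `[[`, "encoder")
  A <- forward_stack(enc, Xm)
  emb <- A[[length(A)]]
  rownames(emb) <- rownames(Xm)
  emb
}
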