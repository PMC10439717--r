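#' Logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, elementwise, numerically stable for
#' large `|x|` (computed through the positive branch so `exp` never
#' overflows).
#'
#' @param x Numeric vector, matrix or array.
#' @return Values in `(0, 1)`, same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Softmax over classes
#'
#' `softmax(x)_j = exp(x_j) / sum_j exp(x_j)`, computed with the max-shift
#' trick so large logits do not overflow. For a matrix the softmax is
#' taken over each row (cells in rows, classes in columns).
#'
#' @param x Numeric vector (one set of class scores) or matrix (cells by
#'   classes).
#' @return Probabilities of the same shape; each vector/row sums to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    shifted <- exp(x - apply(x, 1, max))
    shifted / rowSums(shifted)
  } else {
    shifted <- exp(x - max(x))
    shifted / sum(shifted)
  }
}

#' Multiclass cross-entropy loss
#'
#' `L = -sum_i sum_j y_ji log(p_ji)` over one-hot true labels, the
#' discrepancy between predicted class probabilities and the true types.
#' Probabilities are clipped to `[1e-12, 1]` before the logarithm.
#'
#' @param probs Numeric matrix, cells by classes; rows must sum to 1
#'   within 1e-6.
#' @param labels An `encoded_labels` object, an integer vector of 1-based
#'   class indices, or a one-hot matrix matching `probs`.
#' @param reduction `"total"` (the sum over all cells, the canonical
#'   form) or `"mean"` (per-cell average).
#' @return A non-negative scalar; 0 iff predictions are exactly one-hot
#'   on the true classes.
#' @export
cross_entropy_loss <- function(probs, labels,
                               reduction = c("total", "mean")) {
  reduction <- match.arg(reduction)
  n <- nrow(probs)
  J <- ncol(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  idx <- label_indices(labels, J, n)
  p_true <- pmin(pmax(probs[cbind(seq_len(n), idx)], 1e-12), 1)
  total <- -sum(log(p_true))
  if (reduction == "total") total else total / n
}

# internal: normalize the accepted label representations to indices
label_indices <- function(labels, J, n) {
  idx <- if (inherits(labels, "encoded_labels")) labels$indices
         else if (is.matrix(labels)) max.col(labels, ties.method = "first")
         else as.integer(labels)
  if (length(idx) != n)
    stop("labels length ", length(idx), " does not match ", n, " cells",
         call. = FALSE)
  if (any(idx < 1 | idx > J))
    stop("label index outside 1..", J, call. = FALSE)
  idx
}

#' Adam optimizer configuration
#'
#' The standard defaults for first-order stochastic optimization:
#' step size `alpha = 0.001`, moment decays `beta1 = 0.9` and
#' `beta2 = 0.999`, and stabilizer `epsilon = 1e-8`.
#'
#' @param alpha Step size (> 0).
#' @param beta1,beta2 Exponential decay rates in `[0, 1)`.
#' @param epsilon Denominator stabilizer (> 0).
#' @return An `adam_config` object.
#' @export
adam_config <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8) {
  if (alpha <= 0 || epsilon <= 0 || beta1 < 0 || beta1 >= 1 ||
      beta2 < 0 || beta2 >= 1)
    stop("require alpha > 0, epsilon > 0 and 0 <= beta < 1", call. = FALSE)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon), class = "adam_config")
}

#' Initialize Adam moment accumulators
#'
#' @param theta A numeric array or (possibly nested) list of numeric
#'   arrays: the parameters to be optimized.
#' @return An `adam_state` with zeroed first/second moments mirroring the
#'   shape of `theta` and `step_count = 0`.
#' @export
adam_init <- function(theta) {
  zeros <- rapply(list(theta), function(x) x * 0, how = "replace")[[1]]
  structure(list(first_moments = zeros, second_moments = zeros,
                 step_count = 0L), class = "adam_state")
}

#' One Adam update step
#'
#' Applies the bias-corrected moment update: `t <- t + 1`;
#' `m <- beta1 m + (1 - beta1) g`; `v <- beta2 v + (1 - beta2) g^2`;
#' `m_hat = m / (1 - beta1^t)`; `v_hat = v / (1 - beta2^t)`;
#' `theta <- theta - alpha * m_hat / (sqrt(v_hat) + epsilon)`.
#' The update direction is invariant to diagonal rescaling of the
#' gradients (up to `epsilon`).
#'
#' @param theta Parameters (numeric array or nested list of arrays).
#' @param gradients Gradients with the same structure as `theta`.
#' @param state An `adam_state` from [adam_init] or a previous step.
#' @param cfg An [adam_config].
#' @return A list with updated `theta` and `state`.
#' @export
adam_step <- function(theta, gradients, state, cfg = adam_config()) {
  if (!all(rapply(list(gradients), function(g) all(is.finite(g)),
                  how = "unlist")))
    stop("non-finite gradients; training diverged", call. = FALSE)
  t <- state$step_count + 1L
  upd <- adam_recurse(theta, gradients, state$first_moments,
                      state$second_moments, t, cfg)
  new_state <- structure(list(first_moments = upd$m, second_moments = upd$v,
                              step_count = t), class = "adam_state")
  list(theta = upd$theta, state = new_state)
}

adam_recurse <- function(theta, g, m, v, t, cfg) {
  if (is.list(theta)) {
    out <- Map(function(th, gg, mm, vv) adam_recurse(th, gg, mm, vv, t, cfg),
               theta, g, m, v)
    list(theta = lapply(out, `[[`, "theta"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    m_hat <- m / (1 - cfg$beta1^t)
    v_hat <- v / (1 - cfg$beta2^t)
    list(theta = theta - cfg$alpha * m_hat / (sqrt(v_hat) + cfg$epsilon),
         m = m, v = v)
  }
}

#' Classifier training configuration
#'
#' Defaults follow the embedding-classifier recipe: learning rate 1e-3,
#' 1200 epochs, mini-batches of 256.
#'
#' @param learning_rate Adam step size; default 1e-3.
#' @param epochs Training epochs; default 1200.
#' @param batch_size Mini-batch size; default 256.
#' @param seed Integer seed for initialization and shuffling.
#' @return A `classifier_train_config` object.
#' @export
classifier_train_config <- function(learning_rate = 1e-3, epochs = 1200,
                                    batch_size = 256, seed = 1L) {
  if (learning_rate <= 0 || epochs < 1 || batch_size < 1)
    stop("learning_rate, epochs and batch_size must be positive",
         call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "classifier_train_config")
}

#' Construct an (untrained) deep softmax classifier
#'
#' A fully connected network with sigmoid hidden layers and a softmax
#' output over `J` cell types. The default architecture takes a 1000-wide
#' embedding through two hidden layers of 528 and 256 units.
#'
#' @param topology Integer vector of widths `c(input, hidden..., J)`;
#'   default `c(1000, 528, 256, J)` where `J = length(class_names)`.
#' @param class_names Ordered class labels; the output width.
#' @param seed Integer seed for the fan-based symmetric initialization.
#' @return An `mlp_classifier`.
#' @export
mlp_classifier <- function(class_names,
                           topology = c(1000, 528, 256,
                                        length(class_names)),
                           seed = 1L) {
  J <- length(class_names)
  if (topology[length(topology)] != J)
    stop("output width ", topology[length(topology)],
         " does not equal the number of classes ", J, call. = FALSE)
  if (length(topology) < 2) stop("topology too short", call. = FALSE)
  local_rng(seed)
  n_layers <- length(topology) - 1L
  acts <- c(rep("sigmoid", n_layers - 1L), "softmax")
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers))
    layers[[l]] <- init_dense_layer(topology[l], topology[l + 1L], acts[l])
  structure(list(layers = layers, topology = as.integer(topology),
                 class_names = as.character(class_names),
                 loss_history = NULL),
            class = "mlp_classifier")
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat(sprintf("mlp_classifier: %s -> %d classes\n",
              paste(x$topology, collapse = "-"),
              length(x$class_names)))
  invisible(x)
}

#' Forward pass of the softmax classifier
#'
#' `O_1 = sigmoid(X W_1 + b_1)`, `O_m = sigmoid(O_{m-1} W_m + b_m)`,
#' probabilities `= softmax(O_M W_{M+1} + b_{M+1})`.
#'
#' @param model An `mlp_classifier`.
#' @param X Numeric matrix, cells by input width (the cell embeddings).
#' @return Probability matrix, cells by classes; rows sum to 1.
#' @export
mlp_forward <- function(model, X) {
  if (ncol(X) != model$topology[1])
    stop("input width ", ncol(X), " does not match classifier input ",
         model$topology[1], call. = FALSE)
  A <- forward_stack(model$layers, X)
  probs <- A[[length(A)]]
  colnames(probs) <- model$class_names
  rownames(probs) <- rownames(X)
  probs
}

#' Train the deep softmax classifier with Adam
#'
#' Minimizes the cross-entropy between predicted and true cell types by
#' mini-batch Adam, using the per-batch mean of the loss so the step size
#' is robust to batch size. Data order is reshuffled each epoch; the run
#' is fully deterministic under `cfg$seed`.
#'
#' @param X_embed Numeric matrix, cells by embedding width.
#' @param labels An `encoded_labels` object (or a [label_set] / character
#'   vector, encoded internally). At least two classes are required.
#' @param cfg A [classifier_train_config].
#' @param adam An [adam_config]; its `alpha` is taken from
#'   `cfg$learning_rate`.
#' @param topology Optional widths; default `c(k, 528, 256, J)` with `k`
#'   the embedding width.
#' @return A trained `mlp_classifier` with `loss_history` (per-epoch mean
#'   cross-entropy).
#' @export
train_classifier <- function(X_embed, labels,
                             cfg = classifier_train_config(),
                             adam = adam_config(), topology = NULL) {
  if (!inherits(labels, "encoded_labels")) labels <- encode_labels(labels)
  if (!labels$trainable)
    stop("training requires at least 2 classes", call. = FALSE)
  n <- nrow(X_embed)
  if (length(labels$indices) != n)
    stop("embedding rows (", n, ") and labels (", length(labels$indices),
         ") disagree", call. = FALSE)
  k <- ncol(X_embed)
  J <- labels$n_classes
  if (is.null(topology)) topology <- c(k, 528, 256, J)
  adam$alpha <- cfg$learning_rate
  model <- mlp_classifier(labels$class_names, topology, seed = cfg$seed)
  local_rng(cfg$seed + 1L)
  layers <- model$layers
  theta <- lapply(layers, function(l) list(W = l$W, b = l$b))
  state <- adam_init(theta)
  Y <- labels$one_hot
  loss_history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batch_losses <- numeric(0)
    for (idx in batch_indices(n, cfg$batch_size)) {
      Xb <- X_embed[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      A <- forward_stack(layers, Xb)
      P <- A[[length(A)]]
      loss <- cross_entropy_loss(P, max.col(Yb, ties.method = "first"),
                                 reduction = "mean")
      check_finite_loss(loss, "classifier training")
      batch_losses <- c(batch_losses, loss)
      # softmax + cross-entropy: gradient at the output preactivation
      delta <- (P - Yb) / length(idx)
      grads <- backward_stack(layers, A, delta)
      upd <- adam_step(theta, grads, state, adam)
      theta <- upd$theta
      state <- upd$state
      for (l in seq_along(layers)) {
        layers[[l]]$W <- theta[[l]]$W
        layers[[l]]$b <- theta[[l]]$b
      }
    }
    loss_history[epoch] <- mean(batch_losses)
  }
  model$layers <- layers
  model$loss_history <- loss_history
  model
}

#' Predict cell types from embeddings
#'
#' The predicted type of a cell is the class with the highest softmax
#' probability; exact ties resolve to the lowest class index.
#'
#' @param object A trained `mlp_classifier`.
#' @param newdata Numeric matrix, cells by input width.
#' @param ... Unused.
#' @return A list with `labels` (character vector) and `probabilities`
#'   (cells-by-classes matrix).
#' @export
predict.mlp_classifier <- function(object, newdata, ...) {
  probs <- mlp_forward(object, newdata)
  idx <- max.col(probs, ties.method = "first")
  list(labels = object$class_names[idx], probabilities = probs)
}
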