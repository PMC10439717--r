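# Internal dense-layer machinery shared by the autoencoder stack and the
# softmax classifier. Layers are lists of (W, b, act) with W of shape
# in_dim x out_dim, rows of the data matrix being cells; a forward step is
# A_l = act(A_{l-1} %*% W_l + b_l).

act_forward <- function(act, z) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = sigmoid(z),
         linear = z,
         softmax = softmax(z),
         stop("unknown activation: ", act, call. = FALSE))
}

# derivative of the activation wrt its preactivation, expressed through the
# activation output a (cheaper than recomputing from z)
act_deriv <- function(act, a) {
  switch(act,
         relu = (a > 0) * 1,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         linear = 1,
         stop("no elementwise derivative for activation: ", act,
              call. = FALSE))
}

# symmetric uniform fan-based initialization; draws consume the current
# RNG stream so callers control determinism via local_rng()
init_dense_layer <- function(in_dim, out_dim, act) {
  limit <- sqrt(6 / (in_dim + out_dim))
  W <- matrix(stats::runif(in_dim * out_dim, -limit, limit),
              nrow = in_dim, ncol = out_dim)
  list(W = W, b = numeric(out_dim), act = act)
}

# forward pass caching all activations; activations[[1]] is the input
forward_stack <- function(layers, X) {
  A <- vector("list", length(layers) + 1L)
  A[[1]] <- X
  for (l in seq_along(layers)) {
    z <- A[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    A[[l + 1L]] <- act_forward(layers[[l]]$act, z)
  }
  A
}

# backpropagation given the gradient of the loss wrt the final layer's
# PREACTIVATION (delta_out); returns per-layer gradients
backward_stack <- function(layers, A, delta_out) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- delta_out
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(A[[l]], delta), b = colSums(delta))
    if (l > 1L) {
      dA <- delta %*% t(layers[[l]]$W)
      delta <- dA * act_deriv(layers[[l - 1L]]$act, A[[l]])
    }
  }
  grads
}

# classic momentum SGD; velocity is carried across calls
sgd_momentum_update <- function(layers, grads, velocity, lr, momentum) {
  for (l in seq_along(layers)) {
    velocity[[l]]$W <- momentum * velocity[[l]]$W - lr * grads[[l]]$W
    velocity[[l]]$b <- momentum * velocity[[l]]$b - lr * grads[[l]]$b
    layers[[l]]$W <- layers[[l]]$W + velocity[[l]]$W
    layers[[l]]$b <- layers[[l]]$b + velocity[[l]]$b
  }
  list(layers = layers, velocity = velocity)
}

zero_velocity <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

# mini-batch index sets over a permutation; last batch may be short
batch_indices <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_len(n) / batch_size))
}

check_finite_loss <- function(loss, context) {
  if (!is.finite(loss))
    stop("training diverged (non-finite loss) during ", context,
         "; try a smaller learning rate", call. = FALSE)
  invisible(loss)
}
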