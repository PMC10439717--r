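#' Principal component analysis with a fixed sign convention
#'
#' Centers by column means and extracts the top `k` components by singular
#' value decomposition. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible
#' across runs and linear-algebra backends.
#'
#' @param X Numeric matrix, cells by genes (typically standardized).
#' @param k Number of components, `k <= min(n, d)`.
#' @return A list with `model` (a `pca_model`: `component_matrix` d x k,
#'   `center` length-d, `n_components`) and `scores` (n x k projections).
#' @export
pca_fit_transform <- function(X, k) {
  Xm <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  n <- nrow(Xm); d <- ncol(Xm)
  if (k > min(n, d))
    stop("k = ", k, " exceeds min(n, d) = ", min(n, d), call. = FALSE)
  center <- colMeans(Xm)
  Xc <- sweep(Xm, 2, center, "-")
  sv <- svd(Xc, nu = 0, nv = k)
  V <- sv$v
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  model <- structure(list(component_matrix = V, center = center,
                          n_components = as.integer(k)),
                     class = "pca_model")
  list(model = model, scores = Xc %*% V)
}

#' Project new data onto fitted principal components
#'
#' Uses the training centering vector: no information from the new data
#' leaks into the transform.
#'
#' @param model A `pca_model` from [pca_fit_transform].
#' @param X Numeric matrix with the same gene dimension.
#' @return Score matrix, cells by components.
#' @export
pca_transform <- function(model, X) {
  Xm <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  if (ncol(Xm) != length(model$center))
    stop("gene dimension mismatch with fitted PCA", call. = FALSE)
  sweep(Xm, 2, model$center, "-") %*% model$component_matrix
}

#' PCA + neural network baseline classifier
#'
#' The reference feature-selection comparison: PCA is fitted on the
#' training cells only, both sets are projected onto the training
#' components, and the same deep softmax classifier used on autoencoder
#' embeddings is trained on the scores.
#'
#' @param X_train,X_test Standardized cells-by-genes matrices sharing one
#'   gene space.
#' @param y_train Labels for the training cells.
#' @param k Number of components; default 1000 to mirror the autoencoder
#'   embedding width, capped at `min(n_train, d)`.
#' @param nn_cfg A [classifier_train_config].
#' @param adam An [adam_config].
#' @return A list with `labels` (test predictions), `probabilities`, the
#'   fitted `pca` model and the trained `classifier`.
#' @export
pca_nn_classify <- function(X_train, y_train, X_test, k = 1000,
                            nn_cfg = classifier_train_config(),
                            adam = adam_config()) {
  k <- min(k, nrow(X_train), ncol(X_train))
  fit <- pca_fit_transform(X_train, k)
  clf <- train_classifier(fit$scores, y_train, nn_cfg, adam)
  pred <- predict(clf, pca_transform(fit$model, X_test))
  list(labels = pred$labels, probabilities = pred$probabilities,
       pca = fit$model, classifier = clf)
}

#' Neural network on raw standardized expression
#'
#' Trains the same deep softmax classifier directly on the standardized
#' gene expression matrix (input width `d`), without any learned or
#' linear feature selection.
#'
#' @inheritParams pca_nn_classify
#' @return A list with `labels`, `probabilities` and the trained
#'   `classifier`.
#' @export
raw_nn_classify <- function(X_train, y_train, X_test,
                            nn_cfg = classifier_train_config(),
                            adam = adam_config()) {
  Xtr <- if (inherits(X_train, "expression_matrix"))
    as_plain_matrix(X_train) else X_train
  Xte <- if (inherits(X_test, "expression_matrix"))
    as_plain_matrix(X_test) else X_test
  clf <- train_classifier(Xtr, y_train, nn_cfg, adam)
  pred <- predict(clf, Xte)
  list(labels = pred$labels, probabilities = pred$probabilities,
       classifier = clf)
}

#' L2-regularized multinomial logistic regression
#'
#' Minimizes the mean softmax cross-entropy plus
#' `(l2_strength / 2) * ||W||^2` by full-batch gradient descent with a
#' backtracking step size, stopping when the gradient norm drops below
#' `tol`. The bias is not penalized.
#'
#' @param X Numeric matrix, cells by genes.
#' @param y Labels (any form accepted by [encode_labels]).
#' @param l2_strength Non-negative ridge penalty on the weights;
#'   default 1.
#' @param max_iter Iteration cap; default 500.
#' @param tol Gradient-norm convergence tolerance; default 1e-5.
#' @return A `logistic_model` with `weight_matrix` (d x J), `bias`
#'   (length J), `class_names`, `l2_strength`, `converged` and
#'   `final_gradient_norm`.
#' @export
logistic_train <- function(X, y, l2_strength = 1, max_iter = 500,
                           tol = 1e-5) {
  Xm <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  enc <- if (inherits(y, "encoded_labels")) y else encode_labels(y)
  if (!enc$trainable)
    stop("logistic regression requires at least 2 classes", call. = FALSE)
  n <- nrow(Xm); d <- ncol(Xm); J <- enc$n_classes
  W <- matrix(0, d, J)
  b <- numeric(J)
  Y <- enc$one_hot
  step <- 1
  obj <- function(W, b) {
    P <- softmax(sweep(Xm %*% W, 2, b, "+"))
    cross_entropy_loss(P, enc, reduction = "mean") +
      l2_strength / 2 * sum(W^2) / n
  }
  f <- obj(W, b)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    P <- softmax(sweep(Xm %*% W, 2, b, "+"))
    R <- (P - Y) / n
    gW <- crossprod(Xm, R) + l2_strength * W / n
    gb <- colSums(R)
    gnorm <- sqrt(sum(gW^2) + sum(gb^2))
    if (gnorm < tol) break
    # backtracking line search on the descent direction
    repeat {
      W_new <- W - step * gW
      b_new <- b - step * gb
      f_new <- obj(W_new, b_new)
      if (is.finite(f_new) && f_new <= f - 1e-4 * step * gnorm^2) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) break
    W <- W_new; b <- b_new; f <- f_new
    step <- min(step * 2, 1e3)
  }
  converged <- gnorm < tol
  if (!converged)
    warning("logistic regression did not converge; final gradient norm ",
            format(gnorm), call. = FALSE)
  structure(list(weight_matrix = W, bias = b,
                 class_names = enc$class_names, l2_strength = l2_strength,
                 converged = converged, final_gradient_norm = gnorm),
            class = "logistic_model")
}

#' @rdname logistic_train
#' @param model A fitted `logistic_model`.
#' @return `logistic_predict`: a list with `labels` and `probabilities`.
#' @export
logistic_predict <- function(model, X) {
  Xm <- if (inherits(X, "expression_matrix")) as_plain_matrix(X) else X
  P <- softmax(sweep(Xm %*% model$weight_matrix, 2, model$bias, "+"))
  colnames(P) <- model$class_names
  idx <- max.col(P, ties.method = "first")
  list(labels = model$class_names[idx], probabilities = P)
}
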