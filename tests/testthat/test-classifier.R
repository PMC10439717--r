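test_that("sigmoid closed forms, symmetry and overflow stability", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  x <- seq(-20, 20, length.out = 41)
  expect_true(all(abs(sigmoid(x) + sigmoid(-x) - 1) < 1e-12))
  expect_equal(sigmoid(700), 1, tolerance = 1e-12)
  expect_equal(sigmoid(-700), 0, tolerance = 1e-12)
  expect_true(all(is.finite(sigmoid(c(-700, 700)))))
})

test_that("softmax closed forms, shift invariance and overflow guard", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  p <- softmax(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  # invariance to adding a constant to all logits
  withr::with_seed(2, x <- rnorm(5))
  expect_equal(softmax(x), softmax(x + 123.4), tolerance = 1e-12)
  # matrix form: rows sum to 1 within 1e-9 for random logits
  withr::with_seed(3, M <- matrix(rnorm(200, sd = 5), 20, 10))
  expect_true(all(abs(rowSums(softmax(M)) - 1) < 1e-9))
})

test_that("mlp_forward matches brute-force per-unit evaluation", {
  clf <- mlp_classifier(c("A", "B", "C", "D"), topology = c(5, 4, 3, 4),
                        seed = 17)
  withr::with_seed(18, X <- matrix(rnorm(15), 3, 5))
  probs <- mlp_forward(clf, X)
  # oracle: explicit loops through every layer and unit
  ref <- matrix(0, 3, 4)
  for (i in 1:3) {
    a <- X[i, ]
    for (l in 1:3) {
      W <- clf$layers[[l]]$W; b <- clf$layers[[l]]$b
      z <- numeric(ncol(W))
      for (j in seq_len(ncol(W))) {
        s <- b[j]
        for (p in seq_len(nrow(W))) s <- s + a[p] * W[p, j]
        z[j] <- s
      }
      a <- if (l < 3) 1 / (1 + exp(-z)) else exp(z - max(z)) / sum(exp(z - max(z)))
    }
    ref[i, ] <- a
  }
  expect_equal(unname(probs), ref, tolerance = 1e-6)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  # zero weights give uniform probabilities
  zero <- clf
  for (l in 1:3) {
    zero$layers[[l]]$W <- zero$layers[[l]]$W * 0
    zero$layers[[l]]$b <- zero$layers[[l]]$b * 0
  }
  expect_equal(unname(mlp_forward(zero, X)),
               matrix(0.25, 3, 4), tolerance = 1e-12)
  expect_equal(dim(mlp_forward(clf, matrix(0, 7, 5))), c(7L, 4L))
  expect_error(mlp_forward(clf, matrix(0, 2, 9)), "width")
})

test_that("cross-entropy closed forms, clipping and label validation", {
  # perfect one-hot prediction
  P <- diag(3); P[P == 0] <- 0
  expect_equal(cross_entropy_loss(P + 1e-15, c(1L, 2L, 3L)), 0,
               tolerance = 1e-9)
  # single cell with true-class probability 0.5
  expect_equal(cross_entropy_loss(matrix(c(0.5, 0.5), 1), 1L), log(2))
  # uniform over J classes, n cells: total n log J, mean log J
  n <- 7; J <- 4
  U <- matrix(1 / J, n, J)
  expect_equal(cross_entropy_loss(U, rep(1L, n)), n * log(J))
  expect_equal(cross_entropy_loss(U, rep(1L, n), reduction = "mean"),
               log(J))
  expect_gte(cross_entropy_loss(U, rep(2L, n)), 0)
  expect_error(cross_entropy_loss(U, rep(9L, n)), "index")
  expect_error(cross_entropy_loss(U * 2, rep(1L, n)), "sum to 1")
})

test_that("adam_step reproduces the hand-computed first update", {
  # f(theta) = theta^2 at theta = 1: gradient 2; with defaults
  # m_hat = 2, v_hat = 4, update = 0.001 * 2 / (2 + eps) -> theta' = 0.999
  out <- adam_step(1, 2, adam_init(1), adam_config())
  expect_equal(out$theta, 0.999, tolerance = 1e-9)
  expect_equal(out$state$step_count, 1L)
  # zero gradient leaves theta unchanged but advances the step count
  out2 <- adam_step(1.5, 0, adam_init(1.5), adam_config())
  expect_equal(out2$theta, 1.5)
  expect_equal(out2$state$step_count, 1L)
  # non-finite gradients abort
  expect_error(adam_step(1, NaN, adam_init(1), adam_config()), "finite")
  expect_error(adam_config(beta1 = 1), "beta")
})

test_that("adam update magnitude is invariant to gradient rescaling", {
  g <- c(0.3, -2, 11)
  theta <- c(1, 1, 1)
  u1 <- theta - adam_step(theta, g, adam_init(theta), adam_config())$theta
  u2 <- theta - adam_step(theta, 1000 * g, adam_init(theta),
                          adam_config())$theta
  expect_true(all(abs(u2 / u1 - 1) < 0.001))
})

test_that("adam with beta1 = beta2 = 0 approaches sign-gradient descent", {
  cfg <- adam_config(alpha = 0.01, beta1 = 0, beta2 = 0, epsilon = 1e-300)
  g <- c(3, -0.2, 1e-5)
  out <- adam_step(c(0, 0, 0), g, adam_init(c(0, 0, 0)), cfg)
  expect_equal(out$theta, -0.01 * sign(g), tolerance = 1e-9)
})

test_that("adam state mirrors nested parameter structure", {
  theta <- list(list(W = matrix(1, 2, 2), b = c(1, 1)),
                list(W = matrix(2, 2, 1), b = 3))
  st <- adam_init(theta)
  expect_equal(dim(st$first_moments[[1]]$W), c(2L, 2L))
  g <- rapply(theta, function(x) x * 0 + 1, how = "replace")
  out <- adam_step(theta, g, st, adam_config())
  expect_equal(out$theta[[2]]$b, 3 - 0.001, tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  # 4 cells, 6 features, 3 classes through the full sigmoid/softmax stack
  withr::with_seed(31, {
    X <- matrix(rnorm(24), 4, 6)
    y <- c(1L, 2L, 3L, 2L)
  })
  clf <- mlp_classifier(c("a", "b", "c"), topology = c(6, 5, 4, 3),
                        seed = 32)
  layers <- clf$layers
  loss_at <- function(layers) {
    A <- scdae:::forward_stack(layers, X)
    cross_entropy_loss(A[[length(A)]], y)
  }
  A <- scdae:::forward_stack(layers, X)
  P <- A[[length(A)]]
  Y <- matrix(0, 4, 3); Y[cbind(1:4, y)] <- 1
  grads <- scdae:::backward_stack(layers, A, P - Y)  # total-form loss
  h <- 1e-5
  for (l in 1:3) {
    W <- layers[[l]]$W
    check <- rbind(c(1, 1), c(nrow(W), ncol(W)), c(1, ncol(W)))
    for (r in seq_len(nrow(check))) {
      i <- check[r, 1]; j <- check[r, 2]
      lp <- layers; lp[[l]]$W[i, j] <- W[i, j] + h
      lm <- layers; lm[[l]]$W[i, j] <- W[i, j] - h
      fd <- (loss_at(lp) - loss_at(lm)) / (2 * h)
      expect_equal(grads[[l]]$W[i, j], fd, tolerance = 1e-5)
    }
    bp <- layers; bp[[l]]$b[1] <- layers[[l]]$b[1] + h
    bm <- layers; bm[[l]]$b[1] <- layers[[l]]$b[1] - h
    fd_b <- (loss_at(bp) - loss_at(bm)) / (2 * h)
    expect_equal(grads[[l]]$b[1], fd_b, tolerance = 1e-5)
  }
})

test_that("classifier reaches perfect accuracy on separated clusters", {
  withr::with_seed(41, {
    emb <- rbind(matrix(rnorm(100 * 10, mean = 2), 100, 10),
                 matrix(rnorm(100 * 10, mean = -2), 100, 10))
  })
  y <- rep(c("hi", "lo"), each = 100)
  cfg <- classifier_train_config(epochs = 100, batch_size = 64, seed = 2)
  clf <- train_classifier(emb, y, cfg, topology = c(10, 8, 4, 2))
  pred <- predict(clf, emb)
  expect_equal(accuracy(pred$labels, y), 1.0)
  # loss trend decreases on this separable fixture
  expect_lt(clf$loss_history[100], clf$loss_history[1])
  # determinism: identical seeds give identical weights
  clf2 <- train_classifier(emb, y, cfg, topology = c(10, 8, 4, 2))
  expect_identical(clf$layers, clf2$layers)
  # J = 1 rejected
  expect_error(train_classifier(emb, rep("one", 200), cfg), "2 classes")
})

test_that("prediction breaks exact ties toward the lowest class index", {
  clf <- mlp_classifier(c("A", "B"), topology = c(2, 2), seed = 1)
  clf$layers[[1]]$W <- matrix(0, 2, 2)
  clf$layers[[1]]$b <- c(0, 0)
  pred <- predict(clf, matrix(rnorm(10), 5, 2))
  expect_true(all(pred$labels == "A"))
  expect_true(all(pred$probabilities == 0.5))
})
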