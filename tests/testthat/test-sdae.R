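test_that("masking corruption honors rate limits and preserves the rest", {
  H <- matrix(1, 100, 100)
  expect_identical(mask_corrupt(H, corruption_spec(0, seed = 1)), H)
  expect_true(all(mask_corrupt(H, corruption_spec(1, seed = 1)) == 0))
  out <- mask_corrupt(H, corruption_spec(0.2, seed = 1))
  zeros <- sum(out == 0)
  # central 99.9% interval of Binomial(10000, 0.2)
  band <- stats::qbinom(c(0.0005, 0.9995), 10000, 0.2)
  expect_gte(zeros, band[1])
  expect_lte(zeros, band[2])
  expect_gte(zeros, 1680)
  expect_lte(zeros, 2320)
  # unmasked entries are bit-identical, input untouched
  withr::with_seed(3, Hr <- matrix(rnorm(400), 20, 20))
  out2 <- mask_corrupt(Hr, corruption_spec(0.3, seed = 9))
  kept <- out2 != 0
  expect_identical(out2[kept], Hr[kept])
  expect_identical(Hr[1, 1], Hr[1, 1])
  # determinism under the spec seed
  expect_identical(out2, mask_corrupt(Hr, corruption_spec(0.3, seed = 9)))
  expect_error(corruption_spec(1.5), "0, 1")
})

test_that("dae_apply matches a brute-force per-unit evaluation", {
  withr::with_seed(21, {
    W_e <- matrix(rnorm(20), 5, 4); b_e <- rnorm(4)
    W_d <- matrix(rnorm(20), 4, 5); b_d <- rnorm(5)
    H <- matrix(rnorm(15), 3, 5)
  })
  layer <- dae_layer(W_e, b_e, W_d, b_d, "relu", "tanh")
  out <- dae_apply(layer, H)
  # independent oracle: explicit double loops over cells and units
  hidden_ref <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) {
    s <- b_e[j]
    for (p in 1:5) s <- s + H[i, p] * W_e[p, j]
    hidden_ref[i, j] <- max(s, 0)
  }
  recon_ref <- matrix(0, 3, 5)
  for (i in 1:3) for (j in 1:5) {
    s <- b_d[j]
    for (p in 1:4) s <- s + hidden_ref[i, p] * W_d[p, j]
    recon_ref[i, j] <- tanh(s)
  }
  expect_equal(out$hidden, hidden_ref, tolerance = 1e-6)
  expect_equal(out$reconstruction, recon_ref, tolerance = 1e-6)
  # activation corner cases
  zero_layer <- dae_layer(matrix(0, 1, 1), 0, matrix(0, 1, 1), 0,
                          "relu", "linear")
  z <- dae_apply(zero_layer, matrix(-2, 1, 1))
  expect_equal(z$hidden[1, 1], 0)
  expect_equal(z$reconstruction[1, 1], 0)
  expect_error(dae_apply(layer, matrix(0, 2, 3)), "dimension")
})

test_that("reconstruction loss averages over cells only", {
  expect_equal(reconstruction_loss(matrix(c(1, 2), 1), matrix(0, 1, 2)), 5)
  m <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(m, m), 0)
  # quadratic homogeneity: doubling residuals quadruples the loss
  r <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(m, m + 2 * r),
               4 * reconstruction_loss(m, m + r))
  expect_gte(reconstruction_loss(m, m + r), 0)
  expect_error(reconstruction_loss(m, matrix(0, 2, 2)), "shape")
})

test_that("layer pretraining reduces reconstruction loss deterministically", {
  ds <- separable_dataset(200, 20, 3, seed = 5)
  X <- unclass(zscore_transform(ds$expression)$matrix)
  withr::with_seed(1, layer <- scdae:::new_dae_layer(20, 8, "tanh", "tanh"))
  cfg <- pretrain_config(epochs = 20, batch_size = 64)
  fit <- pretrain_layer(layer, X, cfg, seed = 2)
  expect_length(fit$loss_history, 20)
  expect_lt(fit$loss_history[20], fit$loss_history[1])
  # bitwise determinism under the same seed
  fit2 <- pretrain_layer(layer, X, cfg, seed = 2)
  expect_identical(fit$layer, fit2$layer)
  expect_error(pretrain_config(epochs = 0), "epochs")
})

test_that("greedy pretraining assigns tanh to bottleneck and last decoder", {
  ds <- separable_dataset(80, 12, 2, seed = 9)
  X <- zscore_transform(ds$expression)$matrix
  cfg <- pretrain_config(epochs = 2, batch_size = 32)
  model <- greedy_pretrain(c(12, 8, 6, 4), X, cfg, seed = 1)
  expect_length(model$layers, 3)
  acts_enc <- vapply(model$layers, function(l) l$encoder$act, "")
  acts_dec <- vapply(model$layers, function(l) l$decoder$act, "")
  expect_identical(acts_enc, c("relu", "relu", "tanh"))
  expect_identical(acts_dec, c("tanh", "relu", "relu"))
  expect_false(model$finetuned)
  # degenerate two-entry topology: single layer is both bottleneck and
  # last decoder
  single <- greedy_pretrain(c(12, 4), X, cfg, seed = 1)
  expect_identical(single$layers[[1]]$encoder$act, "tanh")
  expect_identical(single$layers[[1]]$decoder$act, "tanh")
  expect_error(greedy_pretrain(c(12), X, cfg), "topology")
})

test_that("greedy pretraining is order-faithful layer by layer", {
  # layer l is trained on the clean output of layers 1..l-1: freezing the
  # run and re-deriving layer 2's training input from layer 1 must match
  ds <- separable_dataset(60, 10, 2, seed = 4)
  X <- zscore_transform(ds$expression)$matrix
  cfg <- pretrain_config(epochs = 3, batch_size = 30)
  model <- greedy_pretrain(c(10, 6, 3), X, cfg, seed = 8)
  H1 <- dae_apply(model$layers[[1]], unclass(X))$hidden
  expect_equal(ncol(H1), 6)
  expect_equal(nrow(model$layers[[2]]$encoder$W), 6)
})

test_that("fine-tuning schedule follows base / factor^floor(e/interval)", {
  cfg <- finetune_config()
  expect_equal(finetune_lr(cfg, 0), 0.1)
  expect_equal(finetune_lr(cfg, 79), 0.1)
  expect_equal(finetune_lr(cfg, 80), 0.01)
  expect_equal(finetune_lr(cfg, 160), 0.001)
  expect_equal(finetune_lr(cfg, 240), 1e-4)
  expect_equal(finetune_lr(cfg, 320), 1e-5)
  expect_error(finetune_config(decay_factor = 1), "exceed")
})

test_that("unrolled stack mirrors encoder widths in reverse", {
  ds <- separable_dataset(60, 10, 2, seed = 4)
  X <- zscore_transform(ds$expression)$matrix
  model <- greedy_pretrain(c(10, 8, 6, 4, 3), X,
                           pretrain_config(epochs = 1, batch_size = 30),
                           seed = 1)
  expect_identical(unrolled_widths(model),
                   c(10L, 8L, 6L, 4L, 3L, 4L, 6L, 8L, 10L))
  stack <- scdae:::unroll_sdae(model)
  widths <- c(nrow(stack[[1]]$W), vapply(stack, function(l) ncol(l$W), 1L))
  expect_identical(as.integer(widths), unrolled_widths(model))
})

test_that("fine-tuning reduces reconstruction loss and sets the flag", {
  ds <- separable_dataset(300, 50, 3, seed = 12)
  X <- zscore_transform(ds$expression)$matrix
  pre <- greedy_pretrain(c(50, 24, 10), X,
                         pretrain_config(epochs = 10, batch_size = 64),
                         seed = 2)
  ft <- finetune_sdae(pre, X, finetune_config(epochs = 20, batch_size = 64),
                      seed = 3)
  expect_true(ft$model$finetuned)
  expect_lte(ft$loss_history[20], ft$loss_history[1])
  # determinism of the whole pretrain + finetune chain
  pre2 <- greedy_pretrain(c(50, 24, 10), X,
                          pretrain_config(epochs = 10, batch_size = 64),
                          seed = 2)
  ft2 <- finetune_sdae(pre2, X,
                       finetune_config(epochs = 20, batch_size = 64),
                       seed = 3)
  expect_identical(ft$model, ft2$model)
})

test_that("cell embeddings are deterministic, bounded and well-shaped", {
  ds <- separable_dataset(100, 30, 3, seed = 6)
  X <- zscore_transform(ds$expression)$matrix
  pre <- greedy_pretrain(c(30, 16, 8), X,
                         pretrain_config(epochs = 5, batch_size = 50),
                         seed = 1)
  expect_error(encode_cells(pre, X), "fine-tuned")
  emb_pre <- encode_cells(pre, X, allow_pretrained = TRUE)
  expect_equal(dim(emb_pre), c(100L, 8L))
  ft <- finetune_sdae(pre, X, finetune_config(epochs = 5, batch_size = 50),
                      seed = 2)
  emb <- encode_cells(ft$model, X)
  expect_equal(dim(emb), c(100L, 8L))
  # bottleneck is tanh: all entries strictly inside (-1, 1)
  expect_true(all(emb > -1 & emb < 1))
  # no stochastic operation at inference
  expect_identical(emb, encode_cells(ft$model, X))
  expect_identical(rownames(emb), cell_ids(X))
  expect_error(encode_cells(ft$model, matrix(0, 5, 7)), "align_genes")
})

test_that("trained embeddings separate clusters at least as well as raw data", {
  ds <- separable_dataset(240, 40, 3, seed = 15, separation = 3)
  X <- zscore_transform(ds$expression)$matrix
  pre <- greedy_pretrain(c(40, 24, 10), X,
                         pretrain_config(epochs = 15, batch_size = 64),
                         seed = 4)
  ft <- finetune_sdae(pre, X,
                      finetune_config(epochs = 30, batch_size = 64),
                      seed = 5)
  emb <- encode_cells(ft$model, X)
  ratio <- function(M, cls) {
    centers <- rowsum(M, cls) / as.vector(table(cls))
    within <- mean(rowSums((M - centers[cls, , drop = FALSE])^2))
    between <- mean(dist(centers)^2)
    between / within
  }
  cls <- ds$labels$labels
  expect_gt(ratio(emb, cls), ratio(unclass(X), cls))
})
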