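test_that("accuracy matches an independent counting loop exactly", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(accuracy(c("a", "b", "c", "d"), c("a", "b", "c", "x")),
               0.75)
  withr::with_seed(61, {
    pred <- sample(letters[1:5], 1000, replace = TRUE)
    true <- sample(letters[1:5], 1000, replace = TRUE)
  })
  hits <- 0
  for (i in seq_len(1000)) if (pred[i] == true[i]) hits <- hits + 1
  expect_identical(accuracy(pred, true), hits / 1000)
  # permutation equivariance: permuting the pair jointly changes nothing
  perm <- sample(1000)
  expect_identical(accuracy(pred[perm], true[perm]), accuracy(pred, true))
  expect_error(accuracy("a", c("a", "b")), "length")
})

test_that("confusion matrix counts, sums and trace are consistent", {
  true <- c("A", "A", "B", "B", "B", "C")
  pred <- c("A", "B", "B", "B", "A", "C")
  rep <- confusion_and_misclassified(pred, true,
                                     class_names = c("A", "B", "C"),
                                     cell_ids = sprintf("c%d", 1:6))
  expect_equal(sum(rep$confusion), 6)
  expect_equal(rep$confusion["A", "B"], 1L, ignore_attr = TRUE)
  expect_equal(rep$confusion["B", "A"], 1L, ignore_attr = TRUE)
  # row sums = true class counts; column sums = predicted counts
  expect_equal(unname(rowSums(rep$confusion)), c(2, 3, 1))
  expect_equal(unname(colSums(rep$confusion)),
               as.numeric(table(factor(pred, c("A", "B", "C")))))
  # trace / n equals the accuracy operation exactly
  expect_identical(rep$accuracy, accuracy(pred, true))
  expect_equal(nrow(rep$misclassified), 2)
  expect_setequal(rep$misclassified$cell_id, c("c2", "c5"))
  # perfect prediction: diagonal confusion, no misclassified rows
  perf <- confusion_and_misclassified(true, true)
  expect_equal(nrow(perf$misclassified), 0)
  expect_true(all(perf$confusion[upper.tri(perf$confusion)] == 0))
  expect_error(confusion_and_misclassified(c("Z"), c("A"),
                                           class_names = c("A", "B")),
               "vocabulary")
})

test_that("evaluation reports serialize to confusion and summary files", {
  true <- c("A", "B", "B")
  pred <- c("A", "B", "A")
  rep <- confusion_and_misclassified(pred, true, cell_ids = c("x", "y", "z"))
  dir <- withr::local_tempdir()
  write_evaluation_report(rep, dir)
  conf <- data.table::fread(file.path(dir, "confusion.tsv"))
  expect_equal(nrow(conf), 2)
  summ <- data.table::fread(file.path(dir, "summary.tsv"))
  expect_true("accuracy" %in% summ$key)
  expect_equal(as.numeric(summ$value[summ$key == "accuracy"]),
               rep$accuracy, tolerance = 1e-12)
})

test_that("cross-platform evaluation aligns genes and stays near within-batch accuracy", {
  spec <- synthetic_spec(400, 120, 4, latent_dim = 8, separation = 5,
                         noise_sd = 1, dropout_rate = 0.1, seed = 42)
  pair <- make_platform_pair(spec, batch_strength = 0.3,
                             gene_overlap = 0.8)
  cfg <- small_pipeline_config(seed = 5)
  repX <- cross_platform_evaluate(pair$a, pair$b, config = cfg)
  # the matched-gene count reflects the constructed 80% overlap
  expect_equal(repX$matched_genes, round(0.8 * 120))
  expect_equal(repX$unseen_label_cells, 0)
  # within-platform reference on A under the identical configuration
  repA <- compare_methods(pair$a$expression, pair$a$labels,
                          methods = "sdae_nn", config = cfg)
  expect_lte(abs(repX$accuracy - repA$per_method$sdae_nn), 0.05)
  # disjoint vocabularies rejected
  bad <- pair$b
  bad$labels <- label_set(bad$labels$cell_ids,
                          paste0("other_", bad$labels$labels))
  expect_error(cross_platform_evaluate(pair$a, bad, config = cfg),
               "vocabular")
})

test_that("test cells with types unseen in training are flagged and excluded", {
  spec <- synthetic_spec(200, 60, 3, latent_dim = 6, separation = 5,
                         noise_sd = 1, seed = 7)
  pair <- make_platform_pair(spec, batch_strength = 0)
  # relabel one class in the test set to a type absent from training
  lab <- pair$b$labels$labels
  unseen <- lab == "type_03"
  lab[unseen] <- "novel_type"
  pair$b$labels <- label_set(pair$b$labels$cell_ids, lab)
  rep <- cross_platform_evaluate(pair$a, pair$b,
                                 config = small_pipeline_config(seed = 2))
  expect_equal(rep$unseen_label_cells, sum(unseen))
  expect_equal(rep$n, 200 - sum(unseen))
})

test_that("compare_methods runs all methods on identical shared inputs", {
  ds <- separable_dataset(200, 40, 3, seed = 66)
  cfg <- small_pipeline_config(seed = 4)
  rep <- compare_methods(ds$expression, ds$labels,
                         methods = c("sdae_nn", "pca_nn", "raw_nn", "lr"),
                         config = cfg)
  expect_named(rep$per_method, c("sdae_nn", "pca_nn", "raw_nn", "lr"))
  expect_true(all(unlist(rep$per_method) >= 0 &
                    unlist(rep$per_method) <= 1))
  expect_match(rep$input_digest, ":")
  # identical config and seed reproduce the identical report
  rep2 <- compare_methods(ds$expression, ds$labels,
                          methods = c("pca_nn", "lr"), config = cfg)
  expect_identical(rep2$per_method$pca_nn, rep$per_method$pca_nn)
  expect_identical(rep2$per_method$lr, rep$per_method$lr)
  expect_identical(rep2$input_digest, rep$input_digest)
})
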