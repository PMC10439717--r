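# scdae — supervised cell type identification with stacked denoising autoencoder embeddings

`scdae` annotates single cells from expression matrices when a labelled
reference exists. It learns a low-dimensional **cell embedding** with a
stacked denoising autoencoder (SDAE) and predicts each cell's type with a
deep softmax classifier — a supervised alternative to the usual
cluster-then-annotate-by-markers workflow, aimed at labs that already
have an annotated atlas of their tissue and want new datasets labelled
consistently and automatically.

## The method

Given a cells × genes matrix $\bar X \in \mathbb R^{n\times d}$, each
gene is z-scored across cells, $\bar f = (f - E(f))/\mathrm{Std}(f)$.
A stack of denoising autoencoders is then trained greedily: each level
encodes $H^{(\mathfrak l)} = \phi(W_e^{(\mathfrak l)} H^{(\mathfrak l-1)}
+ b_e^{(\mathfrak l)})$ and is trained to reconstruct its *clean* input
from a masked version (each entry zeroed with probability 0.2), under
the loss

$$ L = \tfrac1n \sum_{i=1}^n \sum_{j=1}^d (\bar X_{ij} - X_{ij})^2 . $$

The default encoder is $d$-500-500-2000-1000 (ReLU, with tanh at the
1000-unit bottleneck); after layer-wise pretraining (200 epochs/layer,
SGD) the unrolled encoder–decoder
($d$-500-500-2000-1000-2000-500-500-$d$) is fine-tuned jointly
(400 epochs, learning rate 0.1 divided by 10 every 80 epochs). The
bottleneck activations are the cell embeddings. A four-layer network
(1000–528–256–$J$, sigmoid hidden layers, softmax output) maps
embeddings to $J$ cell types by minimizing cross-entropy
$L = -\sum_i\sum_j y_{ji}\log\bar y_{ji}$ with Adam
($\alpha=10^{-3},\beta_1=0.9,\beta_2=0.999,\varepsilon=10^{-8}$,
1200 epochs, batch 256). Accuracy is the fraction of exact label
matches on a held-out 20% split.

The package also ships the standard comparison methods (PCA + the same
network, the network on raw standardized expression, L2-regularized
multinomial logistic regression), a cross-platform evaluation protocol
with gene-space alignment, and a deterministic synthetic generator of
clustered, noisy, batch-distorted expression data so everything is
testable without downloading any accession.

## A worked example

```r
library(scdae)

# 600 synthetic cells, 200 genes, 4 types, 10% dropout zeros
ds  <- generate_dataset(synthetic_spec(n_cells = 600, n_genes = 200,
                                       n_types = 4, separation = 5,
                                       dropout_rate = 0.1, seed = 1))
cfg <- pipeline_config(hidden_widths = c(128, 128, 64),
                       classifier_hidden = c(64, 32),
                       fast = TRUE, seed = 1)
sp  <- split_train_test(600, test_fraction = 0.2, seed = 1)

model <- fit_pipeline(ds$expression[sp$train_indices, ],
                      label_set(ds$labels$cell_ids[sp$train_indices],
                                ds$labels$labels[sp$train_indices]), cfg)
model
#> cell_type_model: 200 genes -> 64-dim embedding -> 4 classes (training accuracy 1.000)

pred <- predict_cells(model, ds$expression[sp$test_indices, ])
accuracy(pred$labels, ds$labels$labels[sp$test_indices])
#> [1] 1
```

The fitted model reports perfect recovery on this well-separated
four-type population: the 64-dimensional embeddings keep the clusters
apart and the classifier labels every held-out cell correctly. On harder
designs (lower `separation`, `nonlinear = TRUE`) accuracies drop below 1
and the methods can be compared:

```r
rep <- compare_methods(ds$expression, ds$labels,
                       methods = c("sdae_nn", "pca_nn", "raw_nn", "lr"),
                       config = cfg)
rep$per_method
#> $sdae_nn  [1] 1
#> $pca_nn   [1] 1
#> $raw_nn   [1] 1
#> $lr       [1] 1
```

A thin command-line front end covers the same pipeline
(`inst/exec/scdae`: `simulate`, `train`, `embed`, `predict`, `evaluate`,
`compare`).

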