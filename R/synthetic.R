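#' Specification of a synthetic clustered expression dataset
#'
#' Describes a generative model for testing the embedding/classification
#' pipeline without external data: `n_types` cluster centers are drawn in
#' a latent space and scaled by `separation`; each cell is its type's
#' center plus unit latent noise, mapped to gene space through a fixed
#' random linear map (optionally passed through a smooth elementwise
#' nonlinearity so that linear feature selection is suboptimal), with
#' additive gene-level Gaussian noise, independent dropout zeros, and
#' optional multiplicative per-batch gene distortions mimicking
#' cross-platform shifts.
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of genes.
#' @param n_types Number of cell types `k >= 1`.
#' @param latent_dim Latent dimensionality (<= `n_genes`); default 10.
#' @param separation Between-cluster distance scale (>= 0); default 5.
#' @param noise_sd Gene-level additive Gaussian noise sd; default 1.
#' @param dropout_rate Probability an entry is zeroed, in `[0, 1)`;
#'   default 0.
#' @param nonlinear Logical; pass the latent-to-gene map through `tanh`.
#' @param batch Optional list `(n_batches, logfold_sd)`: cells are split
#'   evenly over batches and each gene in each batch is multiplied by
#'   `exp(N(0, logfold_sd))`.
#' @param type_proportions Optional simplex vector of length `n_types`;
#'   class counts are allocated deterministically by largest remainder.
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_cells, n_genes, n_types, latent_dim = 10,
                           separation = 5, noise_sd = 1, dropout_rate = 0,
                           nonlinear = FALSE, batch = NULL,
                           type_proportions = NULL, seed = 1L) {
  if (n_types < 1) stop("n_types must be >= 1", call. = FALSE)
  if (latent_dim > n_genes)
    stop("latent_dim must not exceed n_genes", call. = FALSE)
  if (separation < 0 || noise_sd < 0)
    stop("separation and noise_sd must be non-negative", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (is.null(type_proportions)) {
    type_proportions <- rep(1 / n_types, n_types)
  } else {
    if (length(type_proportions) != n_types ||
        any(type_proportions < 0) ||
        abs(sum(type_proportions) - 1) > 1e-8)
      stop("type_proportions must be a length-", n_types,
           " vector summing to 1", call. = FALSE)
  }
  if (!is.null(batch)) {
    if (is.null(batch$n_batches) || is.null(batch$logfold_sd))
      stop("batch must be a list(n_batches, logfold_sd)", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 latent_dim = as.integer(latent_dim),
                 separation = separation, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, nonlinear = isTRUE(nonlinear),
                 batch = batch, type_proportions = type_proportions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic class counts by largest remainder, so tiny fixtures have
# exact per-class sizes
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# internal: latent structure shared by a platform pair
draw_latent_structure <- function(spec) {
  centers <- matrix(stats::rnorm(spec$n_types * spec$latent_dim),
                    spec$n_types, spec$latent_dim) * spec$separation
  loading <- matrix(stats::rnorm(spec$latent_dim * spec$n_genes),
                    spec$latent_dim, spec$n_genes) / sqrt(spec$latent_dim)
  list(centers = centers, loading = loading)
}

# internal: draw cells given the latent structure (uses current stream)
draw_cells <- function(spec, structure_, prefix = "cell") {
  counts <- allocate_counts(spec$n_cells, spec$type_proportions)
  type_idx <- rep(seq_len(spec$n_types), counts)
  Z <- structure_$centers[type_idx, , drop = FALSE] +
    matrix(stats::rnorm(spec$n_cells * spec$latent_dim),
           spec$n_cells, spec$latent_dim)
  X <- Z %*% structure_$loading
  if (spec$nonlinear) X <- tanh(X)
  if (spec$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = spec$noise_sd),
                    nrow(X), ncol(X))
  batch_assignment <- NULL
  if (!is.null(spec$batch)) {
    nb <- spec$batch$n_batches
    batch_assignment <- rep_len(seq_len(nb), spec$n_cells)
    factors <- matrix(exp(stats::rnorm(nb * spec$n_genes,
                                       sd = spec$batch$logfold_sd)),
                      nb, spec$n_genes)
    X <- X * factors[batch_assignment, , drop = FALSE]
  }
  if (spec$dropout_rate > 0) {
    drop <- stats::runif(length(X)) < spec$dropout_rate
    X[drop] <- 0
  }
  ids <- sprintf("%s_%04d", prefix, seq_len(spec$n_cells))
  genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
  dimnames(X) <- list(ids, genes)
  list(expression = expression_matrix(X),
       labels = label_set(ids, sprintf("type_%02d", type_idx)),
       batch = batch_assignment)
}

#' Generate a synthetic clustered expression dataset
#'
#' Fully determined by `spec` (including its seed): the same spec yields
#' bit-identical data across runs.
#'
#' @param spec A [synthetic_spec].
#' @return A list with `expression` (an [expression_matrix]), `labels`
#'   (a [label_set] with classes `type_01`, `type_02`, ...) and `batch`
#'   (integer batch assignment, or `NULL` when no batch structure was
#'   requested).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("`spec` must be a synthetic_spec", call. = FALSE)
  local_rng(spec$seed)
  structure_ <- draw_latent_structure(spec)
  draw_cells(spec, structure_)
}

#' Generate a pair of batch-shifted datasets sharing cluster structure
#'
#' Emulates the same tissue profiled on two sequencing platforms: both
#' datasets use identical latent cluster centers, the identical
#' latent-to-gene map and the same label vocabulary, but cells are drawn
#' independently and each platform receives its own per-gene
#' multiplicative distortion `exp(N(0, batch_strength))`. Optionally only
#' a fraction of genes is shared between the two gene lists, to exercise
#' gene-space alignment.
#'
#' @param spec A [synthetic_spec] describing each platform's dataset
#'   (its `batch` field is ignored here).
#' @param batch_strength Log-scale sd of the per-gene platform factors;
#'   0 makes the platforms statistically exchangeable.
#' @param gene_overlap Fraction of genes present on both platforms, in
#'   `(0, 1]`; platform B renames a trailing block of genes so only
#'   `round(gene_overlap * n_genes)` identifiers match.
#' @return A list with elements `a` and `b`, each a list
#'   `(expression, labels)`.
#' @export
make_platform_pair <- function(spec, batch_strength = 0.3,
                               gene_overlap = 1) {
  if (gene_overlap <= 0 || gene_overlap > 1)
    stop("gene_overlap must lie in (0, 1]", call. = FALSE)
  local_rng(spec$seed)
  structure_ <- draw_latent_structure(spec)
  platforms <- vector("list", 2)
  for (p in 1:2) {
    ds <- draw_cells(spec, structure_, prefix = c("tenx", "ss2")[p])
    if (batch_strength > 0) {
      factors <- exp(stats::rnorm(spec$n_genes, sd = batch_strength))
      m <- as_plain_matrix(ds$expression) *
        matrix(factors, nrow(ds$expression), spec$n_genes, byrow = TRUE)
      dimnames(m) <- dimnames(ds$expression)
      ds$expression <- expression_matrix(m)
    }
    platforms[[p]] <- ds[c("expression", "labels")]
  }
  if (gene_overlap < 1) {
    n_shared <- round(gene_overlap * spec$n_genes)
    g <- gene_ids(platforms[[2]]$expression)
    if (n_shared < spec$n_genes)
      g[(n_shared + 1):spec$n_genes] <-
        sprintf("b_only_%04d", (n_shared + 1):spec$n_genes)
    m <- as_plain_matrix(platforms[[2]]$expression)
    colnames(m) <- g
    platforms[[2]]$expression <- expression_matrix(m)
  }
  list(a = platforms[[1]], b = platforms[[2]])
}

#' Shipped benchmark fixtures
#'
#' The two synthetic study designs the package uses to exercise the whole
#' pipeline end to end. `benchmark_nonlinear_spec` describes a moderately
#' separated five-type population whose latent-to-gene map is passed
#' through `tanh`, so that linear feature selection is not optimal — the
#' setting where a learned embedding should hold its ground against PCA.
#' `benchmark_platform_spec` describes the population used with
#' [make_platform_pair] for the cross-platform batch-robustness check.
#' Both are fixed designs: the only free argument is the seed.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec].
#' @export
benchmark_nonlinear_spec <- function(seed = 101L) {
  synthetic_spec(n_cells = 600, n_genes = 200, n_types = 5,
                 latent_dim = 8, separation = 2, noise_sd = 0.6,
                 dropout_rate = 0.1, nonlinear = TRUE, seed = seed)
}

#' @rdname benchmark_nonlinear_spec
#' @export
benchmark_platform_spec <- function(seed = 42L) {
  synthetic_spec(n_cells = 500, n_genes = 200, n_types = 4,
                 latent_dim = 8, separation = 5, noise_sd = 1,
                 dropout_rate = 0.1, seed = seed)
}

#' @rdname benchmark_nonlinear_spec
#' @param master_seed Master seed for the pipeline stages.
#' @return `benchmark_pipeline_config`: a [pipeline_config] sized for the
#'   200-gene benchmark fixtures (encoder 200-128-128-64, classifier
#'   64-64-32-J, reduced-epoch profile).
#' @export
benchmark_pipeline_config <- function(master_seed = 1L) {
  pipeline_config(hidden_widths = c(128, 128, 64),
                  classifier_hidden = c(64, 32),
                  fast = TRUE, seed = master_seed)
}
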