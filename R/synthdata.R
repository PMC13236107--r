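# Benchmark generators and preprocessing: the 18-configuration Gaussian-blob
# grid, stratified 80/20 train/test splits, train-fit min-max scaling, PCA
# feature reduction, and a synthetic log-scale gene-expression generator
# emulating a small immunotherapy-response cohort (150 samples, a handful of
# label-informative genes among thousands of null genes).

#' Generate one two-class Gaussian-blob dataset
#'
#' Class 0 is centered at `(p1, p2)`, class 1 at `(p2, p1)`, each with
#' isotropic standard deviation `cluster_std`; samples are drawn evenly from
#' the two classes without truncation and then min-max rescaled per feature
#' to `[0, 1]`.
#'
#' @param p1,p2 Center coordinates (the benchmark grid uses
#'   {0.3, 0.5, 1.0} for each).
#' @param cluster_std Cluster standard deviation ({0.3, 0.5} in the grid).
#' @param n_samples Total sample count (default 100, 50 per class).
#' @param seed Integer seed.
#' @return A list with `X` (`n_samples x 2` matrix in `[0, 1]`), `y`
#'   (binary labels) and the generating parameters.
#' @export
make_blobs <- function(p1, p2, cluster_std = 0.3, n_samples = 100L, seed = 1L) {
  n_samples <- as.integer(n_samples)
  n0 <- n_samples %/% 2L
  n1 <- n_samples - n0
  X <- with_seed(seed, {
    rbind(cbind(stats::rnorm(n0, p1, cluster_std), stats::rnorm(n0, p2, cluster_std)),
          cbind(stats::rnorm(n1, p2, cluster_std), stats::rnorm(n1, p1, cluster_std)))
  })
  X <- apply(X, 2L, function(v) (v - min(v)) / (max(v) - min(v)))
  colnames(X) <- c("x1", "x2")
  list(X = X, y = c(rep(0L, n0), rep(1L, n1)),
       p1 = p1, p2 = p2, cluster_std = cluster_std, seed = as.integer(seed))
}

#' The 18-configuration Gaussian-blob benchmark grid
#'
#' All combinations of `cluster_std` in {0.3, 0.5} and `p1, p2` each in
#' {0.3, 0.5, 1.0}: 18 datasets of 100 balanced samples.
#'
#' @param seed Integer seed (each configuration draws from a derived stream).
#' @return A list of 18 datasets as returned by [make_blobs()].
#' @export
make_blob_grid <- function(seed = 1L) {
  grid <- expand.grid(cluster_std = c(0.3, 0.5), p1 = c(0.3, 0.5, 1.0),
                      p2 = c(0.3, 0.5, 1.0), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    make_blobs(grid$p1[i], grid$p2[i], grid$cluster_std[i],
               seed = derive_seed(seed, i))
  })
}

#' Generate stratified train/test splits
#'
#' Produces `n_splits` distinct seeded 80/20 (by default) splits; each split
#' preserves class proportions so that no test set can be single-class.
#'
#' @param y Binary label vector (defines the sample count and strata).
#' @param n_splits Number of splits (default 10).
#' @param train_frac Training fraction in `(0, 1)` (default 0.8).
#' @param seed Integer seed.
#' @return A list of `n_splits` lists with integer vectors `train`, `test`.
#' @export
make_splits <- function(y, n_splits = 10L, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  n <- length(y)
  if (n < 5L || min(table(y)) < 2L) stop("too few samples to split")
  splits <- vector("list", n_splits)
  seen <- character(0)
  attempt <- 0L
  for (s in seq_len(n_splits)) {
    repeat {
      attempt <- attempt + 1L
      tr <- with_seed(derive_seed(seed, 61L, attempt), {
        unlist(lapply(unique(y), function(cls) {
          idx <- which(y == cls)
          sample(idx, round(train_frac * length(idx)))
        }))
      })
      key <- paste(sort(tr), collapse = ",")
      if (!key %in% seen) break
      if (attempt > 1000L) stop("could not generate distinct splits")
    }
    seen <- c(seen, key)
    splits[[s]] <- list(train = sort(tr), test = setdiff(seq_len(n), tr))
  }
  splits
}

#' Min-max scale with statistics fit on the training portion only
#'
#' Per feature: `(x - min) / (max - min)` using the training minima and
#' maxima; constant training features map to 0, and out-of-range values in
#' `other` are clipped to `[0, 1]`.
#'
#' @param train Training feature matrix.
#' @param other Optional matrix to transform with the training statistics.
#' @return A list with scaled `train`, scaled `other` (or `NULL`), and the
#'   fitted `min` / `max` vectors.
#' @export
minmax_scale <- function(train, other = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training matrix")
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- hi - lo
  scale_one <- function(M) {
    M <- sweep(as.matrix(M), 2L, lo)
    M <- sweep(M, 2L, ifelse(rng > 0, rng, 1), "/")
    M[, rng == 0] <- 0
    pmin(pmax(M, 0), 1)
  }
  list(train = scale_one(train),
       other = if (!is.null(other)) scale_one(other),
       min = lo, max = hi)
}

#' PCA feature reduction fit on the training portion
#'
#' Projects onto the top `f` principal components by variance (fit on the
#' training matrix only) and re-min-max-scales the scores to `[0, 1]` so
#' they remain amplitude-encodable.
#'
#' @param train Training feature matrix.
#' @param other Optional matrix projected with the training loadings.
#' @param f Number of components (`<= min(n_samples, n_features)`).
#' @return A list with `train`, `other` (scaled scores) and the per-component
#'   `explained_variance`.
#' @export
pca_reduce <- function(train, other = NULL, f) {
  train <- as.matrix(train)
  if (f > min(dim(train))) stop("f exceeds min(samples, features)")
  fit <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  tr <- fit$x[, seq_len(f), drop = FALSE]
  ot <- if (!is.null(other)) {
    stats::predict(fit, as.matrix(other))[, seq_len(f), drop = FALSE]
  }
  sc <- minmax_scale(tr, ot)
  list(train = sc$train, other = sc$other,
       explained_variance = fit$sdev[seq_len(f)]^2)
}

#' Configuration of the synthetic expression generator
#'
#' @param n_samples Cohort size (default 150).
#' @param n_genes Gene count (default 2000, a computational stand-in for a
#'   whole transcriptome).
#' @param n_informative Number of label-informative genes (default 8,
#'   mirroring a curated immune/RCC marker panel).
#' @param effect_size Class-conditional mean shift of informative genes, in
#'   units of the gene's within-class SD (default 1).
#' @param responder_fraction Fraction of class-1 (responder) samples,
#'   in `(0, 1)` (default 0.35).
#' @param noise_sd Multiplier on the gene-specific within-class SD
#'   (default 1).
#' @param seed Integer seed.
#' @return Object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_samples = 150L, n_genes = 2000L,
                                  n_informative = 8L, effect_size = 1.0,
                                  responder_fraction = 0.35, noise_sd = 1.0,
                                  seed = 1L) {
  if (n_informative > n_genes) stop("n_informative exceeds n_genes")
  if (responder_fraction <= 0 || responder_fraction >= 1) {
    stop("responder_fraction must lie in (0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 responder_fraction = responder_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a variance-stabilized expression cohort
#'
#' Generates log-scale (variance-stabilized) expression directly: null genes
#' are Normal with gene-specific baseline means (Uniform 4..12) and SDs
#' (Uniform 0.5..1.5, times `noise_sd`); the informative genes additionally
#' receive a class-conditional mean shift of `effect_size` within-class SDs
#' in class 1. Labels are assigned by `responder_fraction`.
#'
#' @param cfg An [expression_sim_config()].
#' @return A list with `X` (`n_samples x n_genes`), binary `y`,
#'   `informative` (indices of the planted genes) and `gene_names`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples; g <- cfg$n_genes
    n1 <- round(cfg$responder_fraction * n)
    y <- c(rep(0L, n - n1), rep(1L, n1))
    mu <- stats::runif(g, 4, 12)
    sd_g <- stats::runif(g, 0.5, 1.5) * cfg$noise_sd
    X <- matrix(stats::rnorm(n * g, mean = rep(mu, each = n),
                             sd = rep(sd_g, each = n)), nrow = n)
    informative <- sample(g, cfg$n_informative)
    for (j in informative) X[y == 1L, j] <- X[y == 1L, j] + cfg$effect_size * sd_g[j]
    gene_names <- sprintf("gene_%05d", seq_len(g))
    colnames(X) <- gene_names
    list(X = X, y = y, informative = sort(informative), gene_names = gene_names)
  })
}

#' Rank genes by a univariate two-sample statistic
#'
#' Welch t-statistics of class 1 vs class 0 per gene; used to check that the
#' planted informative genes of [simulate_expression()] are recoverable.
#'
#' @param X Sample-by-gene matrix; `y` binary labels.
#' @param y Binary labels.
#' @return Gene indices ordered by decreasing `|t|`.
#' @export
rank_genes_by_t <- function(X, y) {
  X <- as.matrix(X)
  i1 <- y == 1L; i0 <- !i1
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[i0, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2L, stats::var)
  v0 <- apply(X[i0, , drop = FALSE], 2L, stats::var)
  tt <- (m1 - m0) / sqrt(v1 / sum(i1) + v0 / sum(i0))
  order(abs(tt), decreasing = TRUE)
}

#' Write / read a labeled dataset as TSV
#'
#' The text format has a header of feature names followed by one sample per
#' row, with the label in the final `label` column.
#'
#' @param data A list with `X` and `y` (as from [make_blobs()]).
#' @param path File path.
#' @return `read_dataset` returns a list with `X` and `y`.
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(data$X)
  df$label <- data$y
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("dataset file lacks a 'label' column")
  y <- as.integer(df$label)
  X <- as.matrix(df[setdiff(names(df), "label")])
  list(X = X, y = y)
}
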