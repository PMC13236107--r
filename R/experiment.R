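# Experiment orchestration: configuration files, the generate -> split ->
# scale/PCA -> train -> predict -> evaluate pipeline, artifact writing
# (prediction and metric tables as TSV, a machine-readable JSON summary,
# line-oriented logs), and plain-text learner serialization.

#' Read a run configuration file
#'
#' Configurations are plain-text YAML (JSON is a YAML subset and also
#' accepted) with blocks `dataset`, `classifier` and top-level keys
#' `n_splits`, `train_frac`, `shots`, `seed`, `pca_components`,
#' `output_dir`.
#'
#' @param path Path to the configuration file.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @noRd
validate_run_config <- function(cfg) {
  if (is.null(cfg$dataset$type)) stop("config needs dataset$type")
  if (is.null(cfg$classifier$type)) stop("config needs classifier$type")
  known <- c("qcc", "qec", "qecru", "soft_vote", "bagging", "boosting", "rf", "xgboost")
  if (!cfg$classifier$type %in% known) {
    stop("unknown classifier type '", cfg$classifier$type, "' (expected one of ",
         paste(known, collapse = ", "), ")")
  }
  cfg$n_splits <- cfg$n_splits %||% 10L
  cfg$train_frac <- cfg$train_frac %||% 0.8
  cfg$shots <- cfg$shots %||% 8192L
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_experiment_dataset <- function(cfg) {
  ds <- cfg$dataset
  switch(ds$type,
    blob = make_blobs(ds$p1 %||% 0.3, ds$p2 %||% 1.0,
                      ds$cluster_std %||% 0.3, ds$n_samples %||% 100L,
                      seed = derive_seed(cfg$seed, 211L)),
    expression = {
      sim <- simulate_expression(expression_sim_config(
        n_samples = ds$n_samples %||% 150L, n_genes = ds$n_genes %||% 2000L,
        n_informative = ds$n_informative %||% 8L,
        effect_size = ds$effect_size %||% 1.0,
        responder_fraction = ds$responder_fraction %||% 0.35,
        noise_sd = ds$noise_sd %||% 1.0,
        seed = derive_seed(cfg$seed, 223L)))
      list(X = sim$X, y = sim$y)
    },
    tsv = read_dataset(ds$path),
    stop("unknown dataset type '", ds$type, "'")
  )
}

## classifier dispatch for one split; returns test-set probabilities
fit_predict_split <- function(cfg, X_tr, y_tr, X_te, split_seed) {
  cl <- cfg$classifier
  shots <- cfg$shots
  switch(cl$type,
    qcc = {
      i <- with_seed(derive_seed(split_seed, 1L), sample(nrow(X_tr), 1L))
      vapply(seq_len(nrow(X_te)), function(j) {
        predict_qcc(qcc_instance(X_tr[i, ], y_tr[i], X_te[j, ], shots),
                    shots = shots, seed = derive_seed(split_seed, 2L, j))
      }, numeric(1))
    },
    qec = ,
    qecru = {
      variant <- if (cl$type == "qecru") "haar" else "swap"
      qcfg <- qec_config(d = cl$d %||% 1L, n_train = cl$n_train %||% 2L,
                         n_feature = ncol(X_tr), n_swap = cl$n_swap %||% 1L,
                         shots = shots, variant = variant,
                         seed = derive_seed(split_seed, 3L))
      check_sim_width(qec_width(qcfg))
      i <- with_seed(derive_seed(split_seed, 4L),
                     sample(nrow(X_tr), qcfg$n_train))
      vapply(seq_len(nrow(X_te)), function(j) {
        predict_qec(qcfg, X_tr[i, , drop = FALSE], y_tr[i], X_te[j, ],
                    shots = shots, seed = derive_seed(split_seed, 5L, j))
      }, numeric(1))
    },
    soft_vote = {
      ens <- soft_vote_fit(X_tr, y_tr, n_learners = cl$n_learners %||% 3L,
                           learning_rate = cl$learning_rate %||% 0.1,
                           batch_size = cl$batch_size %||% 4L,
                           epochs = cl$epochs %||% 30L, seed = split_seed)
      soft_vote_predict(ens, X_te)
    },
    bagging = {
      ens <- bagging_fit(X_tr, y_tr, k = cl$n_learners %||% 3L,
                         learning_rate = cl$learning_rate %||% 0.1,
                         batch_size = cl$batch_size %||% 4L,
                         epochs = cl$epochs %||% 30L, seed = split_seed)
      stats::predict(ens, X_te)
    },
    boosting = {
      ens <- boosting_fit(X_tr, y_tr, k = cl$n_learners %||% 3L,
                          learning_rate = cl$learning_rate %||% 0.1,
                          batch_size = cl$batch_size %||% 4L,
                          epochs = cl$epochs %||% 30L, seed = split_seed)
      stats::predict(ens, X_te)
    },
    rf = rf_baseline(X_tr, y_tr, X_te, n_iter = cl$n_iter %||% 50L,
                     seed = split_seed)$p,
    xgboost = {
      grid <- xgb_search_grid()
      if (!is.null(cl$grid_size) && cl$grid_size < nrow(grid)) {
        grid <- grid[with_seed(derive_seed(split_seed, 6L),
                               sample(nrow(grid), cl$grid_size)), ]
      }
      xgb_baseline(X_tr, y_tr, X_te, grid = grid, seed = split_seed)$p
    }
  )
}

#' Run a configured benchmark experiment
#'
#' Executes the full pipeline: dataset generation (or loading), stratified
#' train/test splitting, min-max scaling fit on each training split
#' (optionally followed by PCA reduction for the quantum classifiers),
#' training/prediction, per-split metrics, and aggregation. Artifacts
#' (predictions and metrics as TSV, a JSON summary, a line-oriented log)
#' are written under `output_dir` when given. Runs are bit-reproducible
#' from the configuration and seed.
#'
#' @param config A configuration list (see [read_run_config()]) or a path to
#'   a configuration file.
#' @param output_dir Optional output directory (overrides the config).
#' @return A list with per-split `records`, the aggregate `summary`, the
#'   prediction table, and the resolved config.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_run_config(config)
  outdir <- output_dir %||% cfg$output_dir
  logf <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(outdir, "run.log")
  }
  log_line <- function(level, ...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE, sep = "")
    invisible(NULL)
  }

  log_line("INFO", "stage=generate dataset=", cfg$dataset$type, " seed=", cfg$seed)
  data <- build_experiment_dataset(cfg)
  baseline <- cfg$classifier$type %in% c("rf", "xgboost")

  splits <- make_splits(data$y, n_splits = cfg$n_splits,
                        train_frac = cfg$train_frac,
                        seed = derive_seed(cfg$seed, 227L))
  records <- NULL
  preds <- NULL
  for (s in seq_along(splits)) {
    t0 <- Sys.time()
    tr <- splits[[s]]$train; te <- splits[[s]]$test
    sc <- minmax_scale(data$X[tr, , drop = FALSE], data$X[te, , drop = FALSE])
    X_tr <- sc$train; X_te <- sc$other
    # classical baselines keep the unreduced feature space
    if (!baseline && !is.null(cfg$pca_components)) {
      red <- pca_reduce(X_tr, X_te, cfg$pca_components)
      X_tr <- red$train; X_te <- red$other
    }
    p <- fit_predict_split(cfg, X_tr, data$y[tr], X_te,
                           split_seed = derive_seed(cfg$seed, 229L, s))
    records <- rbind(records,
                     metric_record(cfg$classifier$type, s, data$y[te], p))
    preds <- rbind(preds,
                   data.frame(split = s, sample = te, p_class1 = p,
                              predicted = classify(p), label = data$y[te]))
    log_line("INFO", "stage=split split=", s, " n_train=", length(tr),
             " n_test=", length(te), " elapsed=",
             round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2), "s")
  }

  summary <- aggregate_splits(records)
  if (!is.null(outdir)) {
    utils::write.table(preds, file.path(outdir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(records, file.path(outdir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(config = cfg, summary = summary),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("INFO", "stage=report artifacts=", outdir)
  }
  list(records = records, summary = summary, predictions = preds, config = cfg)
}

#' Serialize a variational learner as plain text
#'
#' Key-value lines (`n_qubits`, `seed`, comma-separated `theta`), readable
#' back with `read_learner`.
#'
#' @param learner A [variational_learner()]; `path` file path.
#' @param path File path.
#' @export
write_learner <- function(learner, path) {
  lines <- c(paste0("n_qubits: ", learner$n_qubits),
             paste0("seed: ", learner$seed),
             paste0("theta: ", paste(format(learner$theta, digits = 17),
                                     collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_learner
#' @export
read_learner <- function(path) {
  kv <- yaml::read_yaml(path)
  variational_learner(kv$n_qubits,
                      theta = as.numeric(strsplit(as.character(kv$theta), ",")[[1]]),
                      seed = kv$seed %||% 1L)
}
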