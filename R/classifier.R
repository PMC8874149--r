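# classifier: the random forest. The score of an SV is the fraction of
# trees voting pathogenic; SVs larger than 3 Mb are scored 1.0 at inference
# and rejected at training time.

SV_SIZE_CAP <- 3e6

#' Random-forest configuration
#'
#' Defaults are the selected hyperparameters: max depth 10, one feature
#' considered per split, minimum 2 samples per leaf, minimum 4 samples to
#' split a node, 1,000 trees, no out-of-bag accuracy estimation.
#'
#' @param max_depth Maximum tree depth.
#' @param max_features_per_split Features considered at each split.
#' @param min_samples_leaf Minimum samples at a leaf node.
#' @param min_samples_split Minimum samples required to split a node.
#' @param n_trees Number of trees.
#' @param use_oob Whether to estimate out-of-bag accuracy.
#' @param seed RNG seed; fixed-seed training is bit-reproducible.
#' @return A `forest_config` list.
#' @export
forest_config <- function(max_depth = 10, max_features_per_split = 1,
                          min_samples_leaf = 2, min_samples_split = 4,
                          n_trees = 1000, use_oob = FALSE, seed = 1) {
  stopifnot(max_depth >= 1, max_features_per_split >= 1,
            min_samples_leaf >= 1, min_samples_split >= 1, n_trees >= 1)
  structure(list(max_depth = max_depth,
                 max_features_per_split = max_features_per_split,
                 min_samples_leaf = min_samples_leaf,
                 min_samples_split = min_samples_split,
                 n_trees = n_trees, use_oob = isTRUE(use_oob),
                 seed = as.integer(seed)),
            class = "forest_config")
}

.model_format_version <- "svforest-model-1"

#' Train the pathogenicity random forest
#'
#' Training medians (for later imputation of missing features at inference)
#' are computed from the raw feature matrix before imputation, then missing
#' values are imputed and the forest is fitted with exactly the supplied
#' configuration. Records larger than 3 Mb are rejected when sizes are
#' supplied, since such SVs are score-1 by rule rather than by the model.
#'
#' @param fm Feature matrix from [sv_features()] (may contain `NA`).
#' @param labels Character/factor vector with values `"pathogenic"` and
#'   `"benign"`, one per row.
#' @param cfg A [forest_config()].
#' @param sizes Optional SV sizes in bp; rows with size > 3 Mb are dropped
#'   with a message.
#' @return An `sv_model`: fitted forest, feature order, training medians,
#'   configuration snapshot, per-label training counts.
#' @export
train_forest <- function(fm, labels, cfg = forest_config(), sizes = NULL) {
  stopifnot(length(labels) == nrow(fm))
  labels <- as.character(labels)
  if (!is.null(sizes)) {
    big <- sizes > SV_SIZE_CAP
    if (any(big)) {
      message(sprintf("train_forest: dropping %d SV(s) > 3 Mb", sum(big)))
      fm <- fm[!big, , drop = FALSE]
      labels <- labels[!big]
    }
  }
  if (length(unique(labels)) < 2)
    stopf("training requires both pathogenic and benign examples")
  if (min(table(labels)) < 2)
    stopf("training requires >= 2 examples of each label")
  medians <- feature_medians(fm)
  fm <- impute_features(fm, medians)
  x <- as.matrix(fm[, sv_feature_names])
  if (any(is.na(x)))
    stopf("NaN/NA in features after imputation: %s",
          paste(sv_feature_names[colSums(is.na(x)) > 0], collapse = ", "))
  dat <- data.frame(.label = factor(labels, levels = c("benign", "pathogenic")),
                    x, check.names = FALSE)
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = cfg$n_trees, mtry = cfg$max_features_per_split,
    max.depth = if (is.finite(cfg$max_depth)) cfg$max_depth else 0,
    min.bucket = cfg$min_samples_leaf,
    min.node.size = cfg$min_samples_split,
    importance = "impurity", probability = FALSE,
    oob.error = cfg$use_oob, seed = cfg$seed, num.threads = 1
  )
  structure(list(
    forest = forest,
    feature_order = sv_feature_names,
    medians = medians,
    config = cfg,
    training_counts = table(labels),
    format_version = .model_format_version
  ), class = "sv_model")
}

#' @export
print.sv_model <- function(x, ...) {
  cat(sprintf("sv_model: %d trees over %d features; trained on %s\n",
              x$config$n_trees, length(x$feature_order),
              paste(sprintf("%d %s", x$training_counts,
                            names(x$training_counts)), collapse = ", ")))
  invisible(x)
}

#' Score SVs with a trained model
#'
#' The score is the fraction of trees voting pathogenic, in `[0, 1]`.
#' Missing feature values are imputed with the model's training medians.
#' Any SV larger than 3 Mb receives score exactly 1.0 regardless of its
#' features (few benign SVs that large have been observed).
#'
#' @param model An `sv_model`.
#' @param fm Feature matrix from [sv_features()] covering the model's
#'   feature order.
#' @param sizes Optional SV sizes in bp, enabling the > 3 Mb rule.
#' @return Numeric scores in `[0, 1]`, one per row of `fm`.
#' @export
predict_scores <- function(model, fm, sizes = NULL) {
  miss <- setdiff(model$feature_order, names(fm))
  if (length(miss))
    stopf("feature matrix lacks model feature(s): %s",
          paste(miss, collapse = ", "))
  fm <- impute_features(fm, model$medians)
  x <- as.data.frame(fm[, model$feature_order, drop = FALSE])
  pred <- stats::predict(model$forest, data = x, predict.all = TRUE,
                         num.threads = 1)
  lev <- model$forest$forest$levels
  votes <- matrix(lev[pred$predictions], nrow = nrow(x))
  score <- rowMeans(votes == "pathogenic")
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == nrow(fm))
    score[sizes > SV_SIZE_CAP] <- 1.0
  }
  score
}

#' Gini feature importances
#'
#' Mean decrease in impurity per feature, normalized to sum to 1.
#'
#' @param model An `sv_model`.
#' @return Named non-negative numeric vector over the 17 features.
#' @export
gini_importances <- function(model) {
  imp <- model$forest$variable.importance
  if (is.null(imp)) stopf("model carries no importance values")
  imp <- imp[model$feature_order]
  imp / sum(imp)
}

#' Confidence intervals for Gini importances by refitting
#'
#' Refits the forest `n_reps` times under different seeds and reports
#' per-feature quantiles of the normalized importances.
#'
#' @inheritParams train_forest
#' @param n_reps Number of refits (the published analysis used 1,000; the
#'   default is desk-scale).
#' @param level Confidence level.
#' @return Data frame `feature`, `mean`, `lower`, `upper`.
#' @export
gini_importance_ci <- function(fm, labels, cfg = forest_config(),
                               n_reps = 50, level = 0.95) {
  reps <- vapply(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    gini_importances(train_forest(fm, labels, cfg_r))
  }, numeric(length(sv_feature_names)))
  a <- (1 - level) / 2
  data.frame(
    feature = sv_feature_names,
    mean = rowMeans(reps),
    lower = apply(reps, 1, stats::quantile, probs = a),
    upper = apply(reps, 1, stats::quantile, probs = 1 - a),
    row.names = NULL
  )
}

#' Hyperparameter grid search with leave-one-chromosome-out validation
#'
#' Evaluates every row of `param_grid` by mean validation AUC across the
#' supplied folds; validation can be restricted to records from trusted
#' sources (the protocol validates on the curated clinical catalog only).
#'
#' @param fm Feature matrix.
#' @param labels Label vector (`"pathogenic"`/`"benign"`).
#' @param folds Folds from [loco_folds()] (row indices `train`/`test`).
#' @param param_grid Data frame whose columns are [forest_config()] argument
#'   names; each row is one configuration.
#' @param sources Optional per-row source tags.
#' @param validation_sources Optional source tags to validate on.
#' @param seed Seed used for every fit.
#' @return List: `best` (a `forest_config`) and `results` (grid with
#'   `mean_auc`).
#' @export
grid_search <- function(fm, labels, folds, param_grid, sources = NULL,
                        validation_sources = NULL, seed = 1) {
  if (!nrow(param_grid)) stopf("empty parameter grid")
  labels <- as.character(labels)
  mean_auc <- numeric(nrow(param_grid))
  for (g in seq_len(nrow(param_grid))) {
    args <- as.list(param_grid[g, , drop = FALSE])
    args$seed <- seed
    cfg <- do.call(forest_config, args)
    aucs <- c()
    for (f in folds) {
      va <- f$test
      if (!is.null(validation_sources))
        va <- va[sources[va] %in% validation_sources]
      if (!length(va) || length(unique(labels[va])) < 2) {
        warnf("grid_search: fold skipped (no two-class validation subset)")
        next
      }
      model <- train_forest(fm[f$train, , drop = FALSE], labels[f$train], cfg)
      sc <- predict_scores(model, fm[va, , drop = FALSE])
      aucs <- c(aucs, roc_auc(sc, labels[va])$auc)
    }
    mean_auc[g] <- mean(aucs)
  }
  results <- cbind(param_grid, mean_auc = mean_auc)
  best <- as.list(param_grid[which.max(mean_auc), , drop = FALSE])
  best$seed <- seed
  list(best = do.call(forest_config, best), results = results)
}

#' The published hyperparameter search grid
#'
#' Full factorial over max depth (5, 10, 15, unlimited), max features per
#' split (1-4), min samples per leaf (1, 2, 4), min samples to split (2, 4),
#' trees (500, 1,000, 3,000) and out-of-bag use — 576 combinations.
#' Unlimited depth is encoded as `Inf`.
#'
#' @return Data frame of 576 configurations.
#' @export
default_param_grid <- function() {
  expand.grid(max_depth = c(5, 10, 15, Inf),
              max_features_per_split = 1:4,
              min_samples_leaf = c(1, 2, 4),
              min_samples_split = c(2, 4),
              n_trees = c(500, 1000, 3000),
              use_oob = c(TRUE, FALSE))
}

#' Save / load a trained model
#'
#' The file embeds the forest, feature order, training medians,
#' configuration and a format version; loading a file with a different
#' format version is an error naming both versions.
#'
#' @param model An `sv_model`.
#' @param path File path.
#' @return `load_model` returns the `sv_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sv_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read model file %s: %s", path, conditionMessage(e)))
  if (!identical(model$format_version, .model_format_version))
    stopf("model format version mismatch: file has '%s', package expects '%s'",
          model$format_version %||% "<none>", .model_format_version)
  model
}
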