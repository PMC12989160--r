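# Stratified k-fold cross-validation of the full pipeline:
# impute -> normalise -> select-K-best -> train -> evaluate, all fitted
# inside each training fold so no information leaks into validation.

#' Stratified k-fold cross-validation
#'
#' Partitions the rows into `k_folds` stratified folds (every record
#' validates exactly once; fold sizes differ by at most one). For each
#' fold the model is retrained from fresh initialisation on the remaining
#' folds: median imputation, min-max scaling and feature selection are
#' all fitted on the training folds only and reapplied to the validation
#' fold.
#'
#' @param fm A `feature_matrix`.
#' @param config An [mlp_config()].
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment; per-fold model seeds are
#'   derived from it.
#' @param n_features Optional K for [select_k_best()] inside each fold;
#'   `NULL` uses all features.
#' @param scorer Feature-selection scorer (default `anova_f`).
#' @return List with `folds` (per-fold `MetricsReport`s), `mean` (averaged
#'   numeric metrics), `pooled_auc_roc` (AUC over the pooled out-of-fold
#'   probabilities), `selected` (per-fold selected feature names) and
#'   `fold_id`.
#' @export
kfold_cv <- function(fm, config = mlp_config(), k_folds = 10L, seed = 1L,
                     n_features = NULL, scorer = "anova_f") {
  stopifnot(inherits(fm, "feature_matrix"))
  fold_id <- stratified_folds(fm$y, k = k_folds, seed = seed)
  reports <- vector("list", k_folds)
  selected <- vector("list", k_folds)
  oof_prob <- rep(NA_real_, length(fm$y))
  for (f in seq_len(k_folds)) {
    tr <- which(fold_id != f); va <- which(fold_id == f)
    fit <- fit_pipeline(subset_fm(fm, tr),
                        config_with_seed(config, seed + f),
                        n_features = n_features, scorer = scorer)
    pred <- predict_pipeline(fit, fm$x[va, , drop = FALSE])
    reports[[f]] <- classification_metrics(fm$y[va], pred$label, pred$prob)
    selected[[f]] <- fit$features
    oof_prob[va] <- pred$prob
  }
  metric_names <- c("sensitivity", "specificity", "accuracy",
                    "balanced_accuracy", "mcc", "auc_roc", "auc_pr")
  mean_metrics <- lapply(metric_names, function(mn) {
    mean(vapply(reports, `[[`, numeric(1), mn), na.rm = TRUE)
  })
  names(mean_metrics) <- metric_names
  list(folds = reports, mean = mean_metrics,
       pooled_auc_roc = roc_auc(fm$y, oof_prob),
       selected = selected, fold_id = fold_id)
}

#' @keywords internal
config_with_seed <- function(config, seed) {
  config$seed <- as.integer(seed %% .Machine$integer.max)
  config
}

#' Fit the full pipeline on training data
#'
#' Median imputation, min-max normalisation, optional select-K-best and
#' classifier training, bundled with everything needed to score new data.
#'
#' @param fm Training `feature_matrix`.
#' @param config An [mlp_config()].
#' @param n_features Optional K for feature selection (`NULL` = all).
#' @param scorer Feature-selection scorer.
#' @return A `pipeline_fit` bundle: `imputer`, `scaler`, `features`,
#'   `model`, `config`.
#' @export
fit_pipeline <- function(fm, config = mlp_config(), n_features = NULL,
                         scorer = "anova_f") {
  imp <- median_impute(fm$x)
  nm <- minmax_normalize(imp$x)
  feats <- colnames(fm$x)
  if (!is.null(n_features) && n_features < length(feats)) {
    feats <- select_k_best(nm$x, fm$y, n_features, scorer = scorer)
  }
  model <- mlp_train(nm$x[, feats, drop = FALSE], fm$y, config)
  structure(list(imputer = imp$medians, scaler = nm$scaler,
                 features = feats, model = model, config = config),
            class = "pipeline_fit")
}

#' Score new data with a fitted pipeline
#' @param fit A `pipeline_fit`.
#' @param x Numeric matrix with the training columns.
#' @param threshold Optional decision threshold override.
#' @return List with `prob` and `label`.
#' @export
predict_pipeline <- function(fit, x, threshold = NULL) {
  x <- apply_imputer(fit$imputer, x)
  x <- suppressWarnings(apply_scaler(fit$scaler, x))
  predict(fit$model, x[, fit$features, drop = FALSE],
          threshold = threshold)
}

#' Train/test evaluation with a held-out split
#'
#' Convenience wrapper: split (stratified or protein-grouped), fit the
#' pipeline on the training side, report metrics on the test side.
#'
#' @param fm A `feature_matrix`.
#' @param config An [mlp_config()].
#' @param seed Split seed.
#' @param grouped Use [protein_grouped_split()] instead of the stratified
#'   row split.
#' @param n_features,scorer Passed to [fit_pipeline()].
#' @return List with `fit`, `split` and `metrics` (a `MetricsReport`).
#' @export
evaluate_holdout <- function(fm, config = mlp_config(), seed = 1L,
                             grouped = FALSE, n_features = NULL,
                             scorer = "anova_f") {
  split <- if (grouped) protein_grouped_split(fm, seed = seed)
           else split_80_20(fm, seed = seed)
  fit <- fit_pipeline(subset_fm(fm, split$train), config,
                      n_features = n_features, scorer = scorer)
  pred <- predict_pipeline(fit, fm$x[split$test, , drop = FALSE])
  list(fit = fit, split = split,
       metrics = classification_metrics(fm$y[split$test], pred$label,
                                        pred$prob))
}
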