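# Univariate feature selection (select-K-best) and the K sweep.

#' Univariate feature scores against a binary label
#'
#' Scores every column of `x` independently against the label. Available
#' scorers: `anova_f`, the two-group one-way ANOVA F statistic;
#' `mutual_info`, mutual information after equal-width discretisation of
#' each feature into `bins` bins; `chi2`, the chi-squared statistic of
#' per-class feature sums (requires non-negative features, as for count or
#' min-max-scaled data).
#'
#' @param x Numeric matrix with column names.
#' @param y Binary labels.
#' @param scorer One of `"anova_f"`, `"mutual_info"`, `"chi2"`.
#' @param bins Discretisation bins for `mutual_info` (default 10).
#' @return Named numeric score vector (constant features score 0).
#' @export
feature_scores <- function(x, y, scorer = c("anova_f", "mutual_info",
                                            "chi2"), bins = 10L) {
  scorer <- match.arg(scorer)
  y <- as.integer(y)
  switch(scorer,
    anova_f = apply(x, 2L, anova_f_score, y = y),
    mutual_info = apply(x, 2L, mutual_info_score, y = y, bins = bins),
    chi2 = chi2_scores(x, y))
}

#' @keywords internal
anova_f_score <- function(v, y) {
  g1 <- v[y == 1L]; g0 <- v[y == 0L]
  n1 <- length(g1); n0 <- length(g0); n <- n1 + n0
  if (n1 == 0L || n0 == 0L) return(0)
  gm <- mean(v)
  ssb <- n1 * (mean(g1) - gm)^2 + n0 * (mean(g0) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / 1) / (ssw / (n - 2))
}

#' @keywords internal
mutual_info_score <- function(v, y, bins = 10L) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  b <- cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- table(b, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}

#' @keywords internal
chi2_scores <- function(x, y) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("chi2 scorer requires non-negative features", call. = FALSE)
  }
  # per-class column sums vs expectation under label-independence
  obs <- rbind(colSums(x[y == 1L, , drop = FALSE]),
               colSums(x[y == 0L, , drop = FALSE]))
  tot <- colSums(obs)
  frac <- c(mean(y == 1L), mean(y == 0L))
  exp_ <- outer(frac, tot)
  sc <- colSums((obs - exp_)^2 / exp_)
  sc[tot == 0] <- 0
  setNames(sc, colnames(x))
}

#' Select the K best features
#'
#' Ranks the columns by score (descending) and keeps the top `k`. Tied
#' scores are broken by column-name order, making the selection
#' deterministic.
#'
#' @param x Numeric matrix with column names.
#' @param y Binary labels.
#' @param k Number of features to keep (`1 <= k <= ncol(x)`).
#' @param scorer Passed to [feature_scores()].
#' @return Character vector of `k` selected column names, in rank order.
#' @export
select_k_best <- function(x, y, k, scorer = "anova_f") {
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  if (k > ncol(x)) stop("k exceeds the number of features", call. = FALSE)
  sc <- feature_scores(x, y, scorer)
  ord <- order(-sc, colnames(x))
  colnames(x)[ord][seq_len(k)]
}

#' Sweep K to find the best feature-set size
#'
#' For each candidate `k`, runs the full cross-validated pipeline
#' (selection refitted inside every training fold) and records the mean
#' CV balanced accuracy; returns the `k` maximising it, smallest `k`
#' winning ties.
#'
#' @param fm A `feature_matrix`.
#' @param k_grid Integer vector of candidate K values (classically up to
#'   50).
#' @param config Model configuration from [mlp_config()].
#' @param k_folds CV folds (default 5 for the sweep).
#' @param seed Seed controlling folds and training.
#' @param scorer Passed to [select_k_best()].
#' @return List with `best_k` and `results` (data frame of k vs mean
#'   balanced accuracy).
#' @export
sweep_k <- function(fm, k_grid, config, k_folds = 5L, seed = 1L,
                    scorer = "anova_f") {
  stopifnot(length(k_grid) >= 1L)
  bacc <- vapply(k_grid, function(k) {
    cv <- kfold_cv(fm, config, k_folds = k_folds, seed = seed,
                   n_features = k, scorer = scorer)
    cv$mean$balanced_accuracy
  }, numeric(1))
  res <- data.frame(k = k_grid, balanced_accuracy = bacc)
  best <- res$k[order(-res$balanced_accuracy, res$k)][1]
  list(best_k = best, results = res)
}
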