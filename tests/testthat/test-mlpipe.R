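# Normalisation, feature selection, splitting, the neural classifier and
# the evaluation metrics.

test_that("min-max normalisation maps training columns to [0,1]", {
  x <- cbind(a = c(2, 4, 6), b = c(3, 3, 3), ss_H = c(0, 1, 0))
  nm <- minmax_normalize(x)
  expect_equal(unname(nm$x[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm$x[, "b"]), c(0, 0, 0))   # constant column
  expect_equal(unname(nm$x[, "ss_H"]), c(0, 1, 0))  # one-hot passthrough
  test <- cbind(a = 8, b = 3, ss_H = 1)
  expect_warning(out <- apply_scaler(nm$scaler, test), "clipped")
  expect_equal(unname(out[, "a"]), 1)
})

test_that("select-K-best ranks by F statistic with deterministic ties", {
  set.seed(2)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  colnames(x) <- sprintf("f%02d", 1:10)
  x[, 1] <- y + rnorm(n, sd = 0.01)
  colnames(x)[1] <- "planted"
  expect_equal(select_k_best(x, y, 1), "planted")
  # direct F computation confirms the ranking
  f_direct <- apply(x, 2, function(v) {
    summary(stats::aov(v ~ factor(y)))[[1]]$`F value`[1]
  })
  sc <- feature_scores(x, y, "anova_f")
  expect_equal(unname(sc), unname(f_direct), tolerance = 1e-8)
  expect_equal(select_k_best(x, y, 10),
               colnames(x)[order(-sc, colnames(x))])
  # duplicate columns tie; name order decides
  xd <- cbind(zz = x[, 2], aa = x[, 2])
  expect_equal(select_k_best(xd, y, 1), "aa")
  expect_error(select_k_best(x, y, 0), "positive")
})

test_that("mutual information and chi2 scorers favour the planted feature", {
  set.seed(12)
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(runif(n * 5), n, 5)
  colnames(x) <- sprintf("f%d", 1:5)
  x[, 3] <- (y + runif(n) * 0.3) / 1.3
  expect_equal(select_k_best(x, y, 1, scorer = "mutual_info"), "f3")
  expect_equal(select_k_best(x, y, 1, scorer = "chi2"), "f3")
})

test_that("the 80:20 split is stratified, reproducible and exact", {
  y <- c(rep(1L, 60), rep(0L, 40))
  sp <- split_80_20(y, seed = 4)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_equal(sum(y[sp$train]), 48)  # 0.8 * 60
  expect_identical(split_80_20(y, seed = 4), sp)
  expect_false(identical(split_80_20(y, seed = 5)$train, sp$train))
  expect_error(split_80_20(rep(1L, 10)), "both classes")
})

test_that("protein-grouped splits never share a protein across sides", {
  fm <- gen_feature_matrix(n = 200, p = 5, n_proteins = 10, seed = 6)
  sp <- protein_grouped_split(fm, seed = 2)
  expect_length(intersect(fm$protein_id[sp$train],
                          fm$protein_id[sp$test]), 0L)
  # two proteins: one each side
  fm2 <- feature_matrix(cbind(f = rnorm(10)), rep(c(0, 1), 5),
                        rep(c("a", "b"), each = 5))
  sp2 <- protein_grouped_split(fm2, seed = 1)
  expect_length(sp2$train_proteins, 1L)
  expect_length(sp2$test_proteins, 1L)
  # ten equal-size proteins split 8:2
  pid <- rep(sprintf("p%02d", 1:10), each = 10)
  fm3 <- feature_matrix(cbind(f = rnorm(100)), rep(c(0, 1), 50), pid)
  sp3 <- protein_grouped_split(fm3, seed = 3)
  expect_length(sp3$train_proteins, 8L)
  expect_length(sp3$test_proteins, 2L)
  expect_error(protein_grouped_split(
    feature_matrix(cbind(f = rnorm(5)), c(0, 1, 0, 1, 0),
                   rep("only", 5))), "at least 2")
})

test_that("stratified folds partition the data with balanced sizes", {
  y <- c(rep(1L, 53), rep(0L, 47))
  f <- stratified_folds(y, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% c(10)))
  # every record in exactly one fold
  expect_length(f, 100L)
  # class balance: each fold has 5-6 drivers
  expect_true(all(tapply(y, f, sum) %in% 5:6))
  expect_error(stratified_folds(c(rep(1L, 30), rep(0L, 3)), k = 10),
               "too small")
})

test_that("the classifier separates well-separated Gaussians like a logistic oracle", {
  set.seed(10)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = rnorm(n) + 6 * y, f2 = rnorm(n))
  # independent oracle: logistic regression reaches >= 0.99 here
  glm_fit <- suppressWarnings(glm(y ~ x, family = binomial))
  glm_acc <- mean((fitted(glm_fit) >= 0.5) == y)
  expect_gte(glm_acc, 0.99)
  xs <- minmax_normalize(x)$x
  model <- mlp_train(xs, y, mlp_config(hidden = 8L, epochs = 100,
                                       patience = 10, seed = 1))
  pred <- predict(model, xs)
  expect_gte(mean(pred$label == y), 0.99)
})

test_that("zero training epochs returns the loss at initialisation", {
  set.seed(11)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0L, 1L), 10)
  model <- mlp_train(x, y, mlp_config(hidden = 4L, epochs = 0, seed = 2))
  p <- predict(model, x)$prob
  expect_equal(missdriver:::bce_loss(y, p),
               -mean(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(model$epochs_run, 0L)
})

test_that("training is deterministic under a fixed seed", {
  fm <- gen_feature_matrix(n = 120, p = 6, n_planted = 2, d = 2, seed = 3)
  cfg <- mlp_config(hidden = c(8L), epochs = 20, seed = 7)
  m1 <- mlp_train(fm$x, fm$y, cfg)
  m2 <- mlp_train(fm$x, fm$y, cfg)
  expect_identical(m1$par, m2$par)
  m3 <- mlp_train(fm$x, fm$y, mlp_config(hidden = c(8L), epochs = 20,
                                         seed = 8))
  expect_false(identical(m1$par, m3$par))
})

test_that("prediction enforces the schema and maps the boundary to driver", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0L, 1L), 10)
  model <- mlp_train(x, y, mlp_config(hidden = 4L, epochs = 5, seed = 1))
  bad <- x; colnames(bad) <- c("a", "zz")
  expect_error(predict(model, bad), "zz")
  # boundary inclusive
  expect_equal(predict(model, x, threshold = 0)$label, rep(1L, 20))
  # probabilities invariant to row order
  ord <- sample(20)
  p1 <- predict(model, x)$prob
  p2 <- predict(model, x[ord, ])$prob
  expect_equal(p2, p1[ord])
})

test_that("confusion metrics reproduce the defining formulas", {
  mk <- function(TP, TN, FP, FN) {
    labels <- c(rep(1, TP + FN), rep(0, TN + FP))
    preds <- c(rep(1, TP), rep(0, FN), rep(0, TN), rep(1, FP))
    classification_metrics(labels, preds)
  }
  perfect <- mk(50, 50, 0, 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$mcc, 1)
  chance <- mk(25, 25, 25, 25)
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)
})

test_that("metrics are invariant under simultaneous permutation", {
  set.seed(20)
  y <- rbinom(100, 1, 0.5)
  p <- rbinom(100, 1, 0.5)
  pr <- runif(100)
  m1 <- classification_metrics(y, p, pr)
  ord <- sample(100)
  m2 <- classification_metrics(y[ord], p[ord], pr[ord])
  expect_equal(m1, m2)
})

test_that("single-class truth flags curve areas as undefined", {
  m <- classification_metrics(rep(1, 10), rep(1, 10), runif(10))
  expect_false(m$auc_defined)
  expect_true(is.na(m$auc_roc))
})

test_that("cross-validation partitions rows and aces separable data", {
  fm <- gen_feature_matrix(n = 150, p = 6, n_planted = 2, d = 8,
                           seed = 5)
  cv <- kfold_cv(fm, mlp_config(hidden = 8L, epochs = 60, patience = 5),
                 k_folds = 5, seed = 2)
  counts <- table(cv$fold_id)
  expect_length(counts, 5L)
  expect_true(max(counts) - min(counts) <= 1)
  accs <- vapply(cv$folds, `[[`, numeric(1), "accuracy")
  expect_true(all(accs == 1))
})

test_that("the K sweep prefers compact feature sets when extras are noise", {
  fm <- gen_feature_matrix(n = 300, p = 20, n_planted = 3, d = 3, seed = 8)
  cfg <- mlp_config(hidden = 8L, epochs = 120, patience = 10)
  sw <- sweep_k(fm, k_grid = c(3L, 5L, 10L, 20L), cfg, k_folds = 5,
                seed = 1)
  expect_lte(sw$best_k, 10L)
  expect_equal(sweep_k(fm, k_grid = 5L, cfg, k_folds = 3,
                       seed = 1)$best_k, 5L)
})

test_that("holdout evaluation works with grouped splits", {
  fm <- gen_feature_matrix(n = 300, p = 10, n_planted = 3, d = 3,
                           n_proteins = 20, seed = 9)
  ev <- evaluate_holdout(fm, mlp_config(hidden = 8L, epochs = 40,
                                        patience = 5),
                         seed = 2, grouped = TRUE, n_features = 5)
  expect_length(intersect(fm$protein_id[ev$split$train],
                          fm$protein_id[ev$split$test]), 0L)
  expect_gte(ev$metrics$balanced_accuracy, 0.85)
})
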