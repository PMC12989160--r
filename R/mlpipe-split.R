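# Data splitting: stratified 80:20 and protein-grouped splits, and
# stratified k-fold assignment.

#' @keywords internal
labels_of <- function(data) {
  if (inherits(data, "feature_matrix")) return(data$y)
  if (is.data.frame(data) && "label" %in% names(data)) {
    return(as.integer(data$label == "driver"))
  }
  as.integer(data)
}

#' Stratified 80:20 split
#'
#' Splits records into training and test sets by count (largest-remainder
#' rounding), stratified by label so that class proportions in the training
#' set are within one record of the global proportions. Seed-reproducible.
#'
#' @param data A `feature_matrix`, labelled `mutation_table`, or binary
#'   label vector.
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.8).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_80_20 <- function(data, seed = 1L, train_frac = 0.8) {
  y <- labels_of(data)
  n <- length(y)
  if (n < 5L) stop("need at least 5 records to split", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("both classes must be present to stratify the split",
         call. = FALSE)
  }
  n_train <- round(train_frac * n)
  ideal <- vapply(classes, function(cl) train_frac * sum(y == cl),
                  numeric(1))
  base <- floor(ideal)
  extra <- n_train - sum(base)
  if (extra > 0L) {
    give <- order(-(ideal - base))[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    take <- min(base[ci], length(idx) - 1L)  # keep every class in test
    train <- c(train, sample(idx, take))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Protein-grouped train/test split
#'
#' Splits at protein granularity so that no protein contributes mutations
#' to both sides (the leakage guard): proteins are shuffled and assigned
#' to the training side until the target mutation fraction is reached,
#' best-effort 80:20 by mutation count. Both sides always receive at least
#' one protein.
#'
#' @param data A `feature_matrix` or `mutation_table` with protein ids.
#' @param seed Integer seed.
#' @param train_frac Target training fraction (default 0.8).
#' @return List with index vectors `train` and `test`, plus
#'   `train_proteins` and `test_proteins`.
#' @export
protein_grouped_split <- function(data, seed = 1L, train_frac = 0.8) {
  pid <- if (inherits(data, "feature_matrix")) data$protein_id
         else data$protein_id
  proteins <- unique(pid)
  if (length(proteins) < 2L) {
    stop("protein-grouped split needs at least 2 proteins", call. = FALSE)
  }
  n <- length(pid)
  target <- train_frac * n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(proteins)
  sizes <- vapply(shuffled, function(p) sum(pid == p), integer(1))
  train_prot <- character(0)
  count <- 0
  for (i in seq_along(shuffled)) {
    if (count < target) {
      train_prot <- c(train_prot, shuffled[i])
      count <- count + sizes[i]
    }
  }
  test_prot <- setdiff(shuffled, train_prot)
  if (length(test_prot) == 0L) {
    move <- train_prot[length(train_prot)]
    train_prot <- setdiff(train_prot, move)
    test_prot <- move
  }
  list(train = which(pid %in% train_prot),
       test = which(pid %in% test_prot),
       train_proteins = train_prot, test_proteins = test_prot)
}

#' Stratified fold assignment
#'
#' Assigns every record to exactly one of `k` folds, stratified by class,
#' with fold sizes differing by at most one.
#'
#' @param y Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per record.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  n <- length(y)
  if (n < k) stop("fewer records than folds", call. = FALSE)
  classes <- sort(unique(y))
  tab <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (length(classes) > 1L && min(tab) < k) {
    stop("a class is too small for stratification into ", k, " folds",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- integer(n)
  offset <- 0L
  for (cl in classes) {
    idx <- sample(which(y == cl))
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
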