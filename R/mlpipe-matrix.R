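# Feature-matrix container, min-max normalisation and missing-value
# policy for the classification pipeline.

#' Construct a feature matrix
#'
#' The pipeline's training container: a numeric matrix of named feature
#' columns, a binary label vector (driver = 1, passenger = 0) and the
#' protein id of every row (used for protein-grouped splitting).
#'
#' @param x Numeric matrix with column names.
#' @param y Binary labels (0/1 or `passenger`/`driver`).
#' @param protein_id Character vector of per-row protein ids (optional).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, y, protein_id = NULL) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (is.character(y) || is.factor(y)) {
    y <- as.integer(as.character(y) == "driver")
  }
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  if (is.null(protein_id)) protein_id <- rep(NA_character_, nrow(x))
  structure(list(x = x, y = y, protein_id = as.character(protein_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d mutations x %d features (%d drivers, %d passengers)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' @keywords internal
subset_fm <- function(fm, rows = NULL, cols = NULL) {
  x <- fm$x
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  if (!is.null(cols)) x <- x[, cols, drop = FALSE]
  feature_matrix(x, if (is.null(rows)) fm$y else fm$y[rows],
                 if (is.null(rows)) fm$protein_id else fm$protein_id[rows])
}

#' @keywords internal
is_onehot_col <- function(v) {
  u <- unique(v[!is.na(v)])
  length(u) > 0L && all(u %in% c(0, 1))
}

#' Fit a per-column min-max scaler on training data
#'
#' Every non-one-hot column is rescaled to `[0, 1]` by
#' `(x - min) / (max - min)` using the training minimum and maximum.
#' Columns containing only 0/1 values (one-hot secondary-structure
#' encodings) pass through untouched; constant columns map to 0.
#'
#' @param x Numeric training matrix with column names.
#' @param passthrough Extra column names to leave unscaled (in addition to
#'   auto-detected 0/1 columns).
#' @return List with `x` (the scaled matrix) and `scaler` (reusable on new
#'   data via [apply_scaler()]).
#' @export
minmax_normalize <- function(x, passthrough = character(0)) {
  stopifnot(is.matrix(x))
  mins <- apply(x, 2L, min, na.rm = TRUE)
  maxs <- apply(x, 2L, max, na.rm = TRUE)
  skip <- colnames(x) %in% passthrough |
    vapply(seq_len(ncol(x)), function(j) is_onehot_col(x[, j]), logical(1))
  scaler <- list(min = mins, max = maxs, skip = skip,
                 columns = colnames(x))
  list(x = apply_scaler(scaler, x, warn_clip = FALSE), scaler = scaler)
}

#' Apply a fitted min-max scaler to new data
#'
#' Applies training minima/maxima verbatim; values outside the training
#' range are clipped to `[0, 1]` with a warning (new data may exceed the
#' training range).
#'
#' @param scaler Scaler from [minmax_normalize()].
#' @param x Matrix with the same columns as the training data.
#' @param warn_clip Warn when clipping occurs (default `TRUE`).
#' @return Scaled matrix.
#' @export
apply_scaler <- function(scaler, x, warn_clip = TRUE) {
  if (!identical(colnames(x), scaler$columns)) {
    stop("column mismatch between scaler and data", call. = FALSE)
  }
  out <- x
  clipped <- FALSE
  for (j in seq_len(ncol(x))) {
    if (scaler$skip[j]) next
    rng <- scaler$max[j] - scaler$min[j]
    v <- if (rng == 0) rep(0, nrow(x)) else (x[, j] - scaler$min[j]) / rng
    if (any(v < 0 | v > 1, na.rm = TRUE)) clipped <- TRUE
    out[, j] <- pmin(pmax(v, 0), 1)
  }
  if (clipped && warn_clip) {
    warning("values outside the training range were clipped to [0, 1]",
            call. = FALSE)
  }
  out
}

#' Impute missing feature values with training-column medians
#'
#' Explicit missing-value policy applied before training: medians are
#' computed on training rows only and reapplied verbatim to new data.
#' Columns that are entirely missing are imputed with 0 and flagged.
#'
#' @param x Training matrix.
#' @return List with `x` (imputed) and `medians` (reusable via
#'   [apply_imputer()]).
#' @export
median_impute <- function(x) {
  med <- apply(x, 2L, function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  list(x = apply_imputer(med, x), medians = med)
}

#' @rdname median_impute
#' @param medians Named medians from [median_impute()].
#' @export
apply_imputer <- function(medians, x) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[is.na(v)] <- medians[j]
    x[, j] <- v
  }
  x
}
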