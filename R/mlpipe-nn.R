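# Feed-forward neural classifier: fully connected ReLU hidden layers with
# He-normal initialisation and a single sigmoid output unit, trained by
# mini-batch stochastic gradient descent with momentum, L2 weight decay,
# binary cross-entropy loss and early stopping with best-weight restore.

#' Model configuration
#'
#' Defaults follow a small tabular-data network: two ReLU hidden layers of
#' 64 and 32 units, SGD with learning rate 0.01 and momentum 0.9, L2
#' penalty 1e-4, batch size 32, at most 500 epochs with early stopping
#' (patience 10) on a held-out validation split. Between 1 and 5 hidden
#' layers are allowed.
#'
#' @param hidden Integer vector of hidden-layer sizes (length 1-5).
#' @param lr Learning rate (> 0).
#' @param momentum SGD momentum coefficient.
#' @param l2 L2 regulariser weight.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs (validation loss).
#' @param val_fraction Fraction of training rows held out for early
#'   stopping.
#' @param threshold Decision threshold on the output probability; the
#'   boundary maps to the positive (driver) class.
#' @param seed Integer seed fixing initialisation, shuffling and the
#'   validation split.
#' @return A `mlp_config` list.
#' @export
mlp_config <- function(hidden = c(64L, 32L), lr = 0.01, momentum = 0.9,
                       l2 = 1e-4, batch_size = 32L, epochs = 500L,
                       patience = 10L, val_fraction = 0.1,
                       threshold = 0.5, seed = 1L) {
  if (length(hidden) < 1L || length(hidden) > 5L) {
    stop("between 1 and 5 hidden layers are supported", call. = FALSE)
  }
  if (lr <= 0) stop("learning rate must be positive", call. = FALSE)
  structure(list(hidden = as.integer(hidden), lr = lr, momentum = momentum,
                 l2 = l2, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, threshold = threshold,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' @keywords internal
mlp_init <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                  sd = sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' @keywords internal
mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  for (l in seq_len(L - 1L)) {
    z <- sweep(acts[[l]] %*% par$W[[l]], 2L, par$b[[l]], `+`)
    acts[[l + 1L]] <- pmax(z, 0)
  }
  z <- sweep(acts[[L]] %*% par$W[[L]], 2L, par$b[[L]], `+`)
  p <- 1 / (1 + exp(-z))
  list(prob = as.numeric(p), acts = acts)
}

#' @keywords internal
bce_loss <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the feed-forward classifier
#'
#' @param x Numeric training matrix (already imputed and normalised) with
#'   column names.
#' @param y Binary labels (driver = 1).
#' @param config An [mlp_config()].
#' @return An `mlp_model`: fitted weights, the training schema (column
#'   names), the config, the best validation loss and the epoch count
#'   actually run.
#' @export
mlp_train <- function(x, y, config = mlp_config()) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  par <- mlp_init(ncol(x), config$hidden)
  vel <- list(W = lapply(par$W, function(w) w * 0),
              b = lapply(par$b, function(bb) bb * 0))

  # stratified validation split for early stopping
  n <- nrow(x)
  use_val <- config$val_fraction > 0 && config$patience > 0 &&
    n >= 20L && min(sum(y == 1), sum(y == 0)) >= 4L
  if (use_val) {
    val_idx <- unlist(lapply(c(0, 1), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(config$val_fraction * length(idx))))
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    tr_idx <- seq_len(n); val_idx <- integer(0)
  }
  Xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  Xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]

  L <- length(par$W)
  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L
  n_tr <- nrow(Xt)
  epochs_run <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + config$batch_size - 1L, n_tr)]
      Xb <- Xt[bi, , drop = FALSE]; yb <- yt[bi]
      m <- length(bi)
      fw <- mlp_forward(par, Xb)
      delta <- matrix((fw$prob - yb) / m, ncol = 1L)  # dL/dz at output
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$acts[[l]], delta) + 2 * config$l2 * par$W[[l]]
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(par$W[[l]])) * (fw$acts[[l]] > 0)
        }
        vel$W[[l]] <- config$momentum * vel$W[[l]] - config$lr * gW
        vel$b[[l]] <- config$momentum * vel$b[[l]] - config$lr * gb
        par$W[[l]] <- par$W[[l]] + vel$W[[l]]
        par$b[[l]] <- par$b[[l]] + vel$b[[l]]
      }
    }
    epochs_run <- epoch
    monitor_x <- if (use_val) Xv else Xt
    monitor_y <- if (use_val) yv else yt
    loss <- bce_loss(monitor_y, mlp_forward(par, monitor_x)$prob)
    if (!is.finite(loss)) {
      stop("non-finite training loss at epoch ", epoch,
           "; lower the learning rate", call. = FALSE)
    }
    if (loss < best$loss - 1e-12) {
      best <- list(loss = loss, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  par <- if (best$epoch > 0L) best$par else par
  structure(list(par = par, schema = colnames(x), config = config,
                 best_val_loss = best$loss, best_epoch = best$epoch,
                 epochs_run = epochs_run),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d inputs -> %s -> 1 (sigmoid); best epoch %d\n",
              length(x$schema),
              paste(x$config$hidden, collapse = "-"), x$best_epoch))
  invisible(x)
}

#' Predict driver probabilities and labels
#'
#' @param object A fitted `mlp_model`.
#' @param x Matrix whose columns match the training schema (any order).
#' @param threshold Decision threshold; probabilities at or above it map
#'   to the driver class. Defaults to the training config's threshold.
#' @param ... Unused.
#' @return List with `prob` (numeric, in `[0, 1]`) and `label`
#'   (integer 0/1).
#' @export
predict.mlp_model <- function(object, x, threshold = NULL, ...) {
  if (is.null(threshold)) threshold <- object$config$threshold
  missing_cols <- setdiff(object$schema, colnames(x))
  extra <- setdiff(colnames(x), object$schema)
  if (length(missing_cols) > 0L || length(extra) > 0L) {
    stop("feature schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  x <- x[, object$schema, drop = FALSE]
  prob <- mlp_forward(object$par, x)$prob
  list(prob = prob, label = as.integer(prob >= threshold))
}
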