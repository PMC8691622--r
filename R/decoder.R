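# L1-regularized logistic decoder for object edge vs surface, as printed:
# P(edge | X) = 1 / (1 + exp(X W + w0)), so a more-negative linear score
# means a larger edge probability. Only the sign of the learned weights
# differs from the conventional logistic form; an equivalence test
# documents this.

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Edge probability under a decoder model
#'
#' `p = 1 / (1 + exp(X W + w0))`; a trial is classified as edge when
#' `p >= 0.5` (the boundary goes to edge).
#'
#' @param object a `decoder_model` from [train_decoder()], or a list with
#'   `W` and `w0`.
#' @param X trials x features matrix on the model's feature scale (the
#'   trained model stores its standardization and applies it).
#' @param ... unused.
#' @return Data frame with `p` (edge probability) and `class` (1 = edge,
#'   0 = surface).
#' @export
predict.decoder_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$W))
    stop("feature count (", ncol(X), ") does not match model (",
         length(object$W), ")")
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  p <- .sigmoid(-(drop(X %*% object$W) + object$w0))
  data.frame(p = p, class = as.integer(p >= 0.5))
}

#' Decoder loss (cross-entropy + L1 penalty)
#'
#' `J = -(1/m) sum(y ln p + (1 - y) ln(1 - p)) + lambda/(2m) sum(|W|)`
#' with the intercept unpenalized; probabilities are clipped away from 0
#' and 1 at machine-safe bounds.
#'
#' @param W weight vector.
#' @param w0 intercept.
#' @param X trials x features matrix.
#' @param y binary labels (1 = edge).
#' @param lambda L1 regularization weight.
#' @return Scalar loss.
#' @export
decoder_loss <- function(W, w0, X, y, lambda) {
  m <- length(y)
  stopifnot(m > 0, all(y %in% c(0, 1)))
  p <- .sigmoid(-(drop(as.matrix(X) %*% W) + w0))
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p)) +
    lambda / (2 * m) * sum(abs(W))
}

# Proximal-gradient (FISTA) minimization of the decoder loss. The smooth
# part is an ordinary logistic log-likelihood (in the printed sign
# convention, the gradient is that of conventional logistic regression
# with labels 1 - y); the L1 part is handled by soft-thresholding. The
# objective is convex, so no multi-start is needed.
.fit_l1_logistic <- function(X, y, lambda, maxit = 3000, tol = 1e-10) {
  m <- nrow(X)
  d <- ncol(X)
  yc <- 1 - y  # conventional-logistic labels for the printed sign
  # Lipschitz constant of the smooth gradient: 0.25 * lambda_max(G'G)/m
  # with G = [X, 1], via power iteration.
  v <- rep(1, d + 1) / sqrt(d + 1)
  gmul <- function(v) {
    u <- drop(X %*% v[seq_len(d)]) + v[d + 1]
    c(drop(crossprod(X, u)), sum(u))
  }
  for (i in 1:30) {
    v <- gmul(v)
    v <- v / sqrt(sum(v^2))
  }
  L <- 0.25 * sqrt(sum(gmul(v)^2)) / m + 1e-12
  step <- 1 / L
  thr <- step * lambda / (2 * m)
  w <- numeric(d); w0 <- 0
  zw <- w; zw0 <- w0; tk <- 1
  obj_old <- decoder_loss(w, w0, X, y, lambda)
  for (it in seq_len(maxit)) {
    q <- .sigmoid(drop(X %*% zw) + zw0)
    r <- q - yc
    gw <- drop(crossprod(X, r)) / m
    g0 <- mean(r)
    wn <- zw - step * gw
    wn <- sign(wn) * pmax(abs(wn) - thr, 0)
    w0n <- zw0 - step * g0
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zw <- wn + (tk - 1) / tn * (wn - w)
    zw0 <- w0n + (tk - 1) / tn * (w0n - w0)
    w <- wn; w0 <- w0n; tk <- tn
    if (it %% 20 == 0) {
      obj <- decoder_loss(w, w0, X, y, lambda)
      if (abs(obj_old - obj) < tol * max(1, abs(obj))) break
      obj_old <- obj
    }
  }
  list(W = w, w0 = w0, iterations = it,
       objective = decoder_loss(w, w0, X, y, lambda))
}

# Stratified 60/15/25 split indices.
.stratified_split <- function(y, fractions, seed) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  .with_seed(seed, {
    split <- character(length(y))
    for (cls in unique(y)) {
      i <- sample(which(y == cls))
      n <- length(i)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      split[i[seq_len(n_tr)]] <- "train"
      split[i[n_tr + seq_len(n_va)]] <- "validation"
      split[i[(n_tr + n_va + 1):n]] <- "test"
    }
    split
  })
}

#' Default regularization grid
#'
#' 20 values equally spaced in log between 0.001 and 40.
#' @return Numeric vector of length 20.
#' @export
lambda_grid <- function() exp(seq(log(0.001), log(40), length.out = 20))

#' Train the edge/surface decoder
#'
#' Seeded stratified split into training (60%), validation (15%) and test
#' (25%) sets; for each candidate regularization weight the convex
#' objective is minimized by proximal gradient on the training set, the
#' weight with the lowest validation MSE (between predicted edge
#' probability and label) is selected, the model is refit on
#' train + validation, and test accuracy is reported. Features are
#' z-scored using training-set statistics by default, so power and rate
#' features live on comparable scales.
#'
#' @param ds a [decode_dataset()].
#' @param lambda fixed regularization weight, or `NULL` (default) to
#'   select from `grid`.
#' @param grid candidate weights (default [lambda_grid()]).
#' @param seed integer seed for the split.
#' @param fractions train/validation/test fractions (default
#'   `c(0.6, 0.15, 0.25)`).
#' @param standardize z-score features on training statistics (default
#'   TRUE).
#' @param refit refit on train + validation after selection (default
#'   TRUE).
#' @return Object of class `decoder_model`: `W`, `w0`, `lambda`,
#'   `test_accuracy`, `split`, `validation_mse` (per grid value),
#'   `center`/`scale` (standardization), diagnostics.
#' @export
train_decoder <- function(ds, lambda = NULL, grid = lambda_grid(),
                          seed = 1, fractions = c(0.6, 0.15, 0.25),
                          standardize = TRUE, refit = TRUE) {
  stopifnot(inherits(ds, "decode_dataset"))
  if (min(table(ds$y)) < 20)
    stop("need at least 20 trials per class")
  split <- .stratified_split(ds$y, fractions, seed)
  for (s in c("train", "validation", "test"))
    if (length(unique(ds$y[split == s])) < 2)
      stop("split '", s, "' contains a single class")
  X <- ds$X
  ctr <- scl <- NULL
  if (standardize) {
    tr <- split == "train"
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  itr <- split == "train"; iva <- split == "validation"
  ite <- split == "test"
  val_mse <- NULL
  if (is.null(lambda)) {
    val_mse <- vapply(grid, function(lam) {
      f <- .fit_l1_logistic(X[itr, , drop = FALSE], ds$y[itr], lam)
      p <- .sigmoid(-(drop(X[iva, , drop = FALSE] %*% f$W) + f$w0))
      mean((p - ds$y[iva])^2)
    }, numeric(1))
    lambda <- grid[which.min(val_mse)]
  }
  fit_rows <- if (refit) itr | iva else itr
  f <- .fit_l1_logistic(X[fit_rows, , drop = FALSE], ds$y[fit_rows],
                        lambda)
  p_te <- .sigmoid(-(drop(X[ite, , drop = FALSE] %*% f$W) + f$w0))
  acc <- mean((p_te >= 0.5) == (ds$y[ite] == 1))
  structure(list(W = f$W, w0 = f$w0, lambda = lambda,
                 test_accuracy = acc, split = split,
                 validation_mse = val_mse, grid = grid,
                 center = ctr, scale = scl,
                 feature_kind = ds$feature_kind,
                 iterations = f$iterations, objective = f$objective),
            class = "decoder_model")
}

#' Restrict a decoding dataset to a subset of sites
#'
#' @param ds a [decode_dataset()].
#' @param sites site indices to keep.
#' @return A [decode_dataset()] with the corresponding column triplets.
#' @export
subset_sites <- function(ds, sites) {
  n_sites <- ncol(ds$X) / 3
  stopifnot(all(sites >= 1), all(sites <= n_sites))
  cols <- as.vector(vapply(sites, function(j) 3 * (j - 1) + 1:3,
                           numeric(3)))
  decode_dataset(ds$X[, cols, drop = FALSE], ds$y, ds$feature_kind,
                 ds$site_ids[sites])
}

#' Decoding accuracy as a function of the number of sites
#'
#' For each site count, repeatedly samples that many sites without
#' replacement from the pool, trains the decoder on the restricted
#' dataset, and records test accuracy; returns mean and standard error
#' per count for each supplied feature kind.
#'
#' @param pools named list of [decode_dataset()] objects over the same
#'   trials (e.g. `list(gamma = ..., mua = ...)`).
#' @param counts site counts to evaluate.
#' @param repeats site samples per count (default 10).
#' @param seed integer seed.
#' @param lambda fixed regularization weight (default 0.1, the value used
#'   for all-site decoding); pass `NULL` to select per fit.
#' @return Data frame: `feature_kind`, `count`, `mean_accuracy`, `se`.
#' @export
accuracy_vs_nsites <- function(pools, counts, repeats = 10, seed = 1,
                               lambda = 0.1) {
  n_sites <- ncol(pools[[1]]$X) / 3
  stopifnot(all(counts <= n_sites), all(counts >= 1))
  seeds <- .child_seeds(seed, repeats * length(counts) + 1)
  site_draws <- .with_seed(seeds[1], {
    lapply(seq_len(repeats * length(counts)), function(i) {
      cnt <- counts[ceiling(i / repeats)]
      sample.int(n_sites, cnt)
    })
  })
  out <- list()
  for (kind in names(pools)) {
    for (ci in seq_along(counts)) {
      accs <- vapply(seq_len(repeats), function(r) {
        i <- (ci - 1) * repeats + r
        sub <- subset_sites(pools[[kind]], site_draws[[i]])
        train_decoder(sub, lambda = lambda, seed = seeds[i + 1])$
          test_accuracy
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        feature_kind = kind, count = counts[ci],
        mean_accuracy = mean(accs),
        se = stats::sd(accs) / sqrt(length(accs)))
    }
  }
  do.call(rbind, out)
}
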