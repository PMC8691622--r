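test_that("prediction follows the printed logistic form", {
  model <- structure(list(W = c(0, 0), w0 = 0, center = NULL,
                          scale = NULL), class = "decoder_model")
  pr <- predict(model, matrix(rnorm(10), 5, 2))
  expect_true(all(pr$p == 0.5))
  expect_true(all(pr$class == 1))  # boundary p = 0.5 goes to edge
  # X W + w0 = -ln 3  =>  p = 0.75
  m2 <- structure(list(W = c(1), w0 = 0, center = NULL, scale = NULL),
                  class = "decoder_model")
  pr2 <- predict(m2, matrix(-log(3), 1, 1))
  expect_equal(pr2$p, 0.75)
  # large positive score saturates to surface
  pr3 <- predict(m2, matrix(50, 1, 1))
  expect_lt(pr3$p, 1e-20)
  expect_equal(pr3$class, 0)
  expect_error(predict(m2, matrix(1, 1, 3)), "feature count")
})

test_that("the loss matches closed forms", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  expect_equal(decoder_loss(c(0, 0), 0, X, y, 5), log(2))
  # doubling lambda doubles the penalty term exactly
  W <- c(0.5, -2)
  l1 <- decoder_loss(W, 1, X, y, 2)
  l2 <- decoder_loss(W, 1, X, y, 4)
  expect_equal(l2 - l1, 2 / (2 * 20) * sum(abs(W)))
  # perfectly confident correct predictions drive the loss to zero
  Xs <- matrix(c(-100, 100), 2, 1)
  expect_lt(decoder_loss(c(1), 0, Xs, c(1, 0), 0), 1e-10)
})

test_that("training solves the convex objective", {
  gt <- fx_gt("edge_surface")
  ds <- simulate_edge_surface(gt, n_sites = 1, n_trials = 400, seed = 5)
  X <- scale(ds$gamma$X)
  y <- ds$gamma$y
  f <- gammatrio:::.fit_l1_logistic(X, y, 0.5)
  expect_lte(f$objective, decoder_loss(rep(0, 3), 0, X, y, 0.5) + 1e-8)
  # brute-force grid equivalence on a 2-feature toy
  set.seed(9)
  X2 <- matrix(rnorm(80), 40, 2)
  y2 <- rbinom(40, 1, plogis(-(X2 %*% c(1, -1))))
  f2 <- gammatrio:::.fit_l1_logistic(X2, y2, 0.3)
  lo <- rep(-3, 3); hi <- rep(3, 3); bestv <- Inf
  for (round in 1:4) {
    gs <- lapply(1:3, function(i) seq(lo[i], hi[i], length.out = 21))
    vals <- as.matrix(expand.grid(gs))
    obj <- apply(vals, 1, function(p)
      decoder_loss(p[1:2], p[3], X2, y2, 0.3))
    i <- which.min(obj)
    bestv <- obj[i]
    bp <- vals[i, ]
    step <- (hi - lo) / 20
    lo <- bp - step
    hi <- bp + step
  }
  expect_lt(abs(f2$objective - bestv), 1e-3)
  # monotone shrinkage of the L1 norm across the lambda grid
  l1 <- vapply(lambda_grid(), function(l)
    sum(abs(gammatrio:::.fit_l1_logistic(X, y, l)$W)), numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("solution agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  X2 <- matrix(rnorm(200), 100, 2)
  y2 <- rbinom(100, 1, plogis(-(X2 %*% c(1.5, -1))))
  lam <- 0.4
  f <- gammatrio:::.fit_l1_logistic(X2, y2, lam)
  g <- glmnet::glmnet(X2, 1 - y2, family = "binomial", alpha = 1,
                      lambda = lam / (2 * length(y2)),
                      standardize = FALSE, thresh = 1e-12)
  wg <- as.numeric(stats::coef(g))
  # flipping the labels absorbs the printed sign convention, so the
  # conventional solver must land on identical coefficients
  expect_equal(f$W, wg[2:3], tolerance = 1e-3)
  expect_equal(f$w0, wg[1], tolerance = 1e-3)
})

test_that("sign-convention flip reproduces the same probabilities", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  W <- rnorm(3); w0 <- 0.4
  p_printed <- 1 / (1 + exp(drop(X %*% W) + w0))
  p_conventional <- plogis(drop(X %*% (-W)) + (-w0))
  expect_equal(p_printed, p_conventional)
})

test_that("training behaves across signal regimes", {
  gt <- fx_gt("edge_surface")
  # linearly separable features
  set.seed(21)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  Xsep <- matrix(rnorm(3 * n), n, 3) + outer(ifelse(y == 1, 6, -6),
                                             c(1, 1, 1))
  dsep <- decode_dataset(Xsep, y, "gamma")
  msep <- train_decoder(dsep, lambda = 0.01, seed = 1)
  expect_gte(msep$test_accuracy, 0.95)
  # heavy shrinkage kills the weights on weak-signal data
  weak <- simulate_edge_surface(gt, 1, 400, seed = 31)
  gt0 <- gt
  gt0$edge_surface_effects$gamma_d[] <- 0
  null_ds <- simulate_edge_surface(gt0, 1, 400, seed = 32)
  mshrunk <- train_decoder(null_ds$gamma, lambda = 40, seed = 1)
  expect_true(all(abs(mshrunk$W) < 1e-3))
  # no-signal data decodes at chance
  m0 <- train_decoder(null_ds$gamma, lambda = 0.1, seed = 2)
  expect_lt(abs(m0$test_accuracy - 0.5), 0.15)
  # deterministic given the seed
  m1 <- train_decoder(weak$gamma, seed = 5)
  m2 <- train_decoder(weak$gamma, seed = 5)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$lambda, m2$lambda)
  few <- c(1:15, (n / 2 + 1):(n / 2 + 15))
  expect_error(train_decoder(decode_dataset(Xsep[few, ], y[few],
                                            "gamma")),
               "at least 20")
})

test_that("site-count curves favor the stronger feature set", {
  gt <- fx_gt("edge_surface")
  pool <- simulate_edge_surface(gt, n_sites = 6, n_trials = 400,
                                seed = 8)
  curve <- accuracy_vs_nsites(pool, counts = c(1, 3, 6), repeats = 4,
                              seed = 3)
  cg <- curve[curve$feature_kind == "gamma", ]
  cm <- curve[curve$feature_kind == "mua", ]
  expect_true(all(cg$mean_accuracy > cm$mean_accuracy))
  curve2 <- accuracy_vs_nsites(pool, counts = c(1, 3, 6), repeats = 4,
                               seed = 3)
  expect_identical(curve$mean_accuracy, curve2$mean_accuracy)
  expect_error(accuracy_vs_nsites(pool, counts = 10, repeats = 2,
                                  seed = 1))
})
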