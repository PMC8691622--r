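# Fitting the two-dimensional model (aperiodic baseline + three Gaussian
# gamma components) to a spectrum grid by bounded nonlinear least squares
# with seeded multi-start.

# Parameter vector layout: k, a, b, c, sf0, then per component
# (sigma, mu0, mu1, n, A1, sigma1, A2, sigma2) for LG, MG, HG.
# The peak-frequency sigmoid is reparameterized by its two endpoints
# mu0 = mu(0) = K0 and mu1 = mu(Inf) = K0 + K; box-bounding both inside
# the component's band window confines the whole (monotone) trajectory.
.par_pack <- function(p) {
  c(p$baseline$k, p$baseline$a, p$baseline$b, p$baseline$c, p$sf0,
    unlist(lapply(p$components, function(cp)
      c(cp$sigma, cp$K0, cp$K0 + cp$K, cp$n, cp$A1, cp$sigma1, cp$A2,
        cp$sigma2))))
}

.par_unpack <- function(theta, band_windows) {
  labs <- c("LG", "MG", "HG")
  comps <- lapply(seq_len(3), function(i) {
    v <- theta[5 + (i - 1) * 8 + 1:8]
    component_params(labs[i], sigma = v[1], K0 = v[2], K = v[3] - v[2],
                     n = v[4], A1 = v[5], sigma1 = v[6], A2 = v[7],
                     sigma2 = v[8])
  })
  model_params(baseline_params(theta[1], theta[2], theta[3], theta[4]),
               comps, sf0 = theta[5], band_windows = band_windows)
}

.fit_bounds <- function(grid, band_windows) {
  maxp <- max(grid$power)
  maxsf <- max(grid$sfs)
  lo_b <- c(0, 0.1, 0, 0, 0.01)
  hi_b <- c(maxp * 1e8, 4, 1e4, maxp, 2 * maxsf)
  lo_c <- hi_c <- NULL
  for (w in band_windows) {
    lo_c <- c(lo_c, c(1, w[1], w[1], 0.5, 0, 0.02, 0, 0.02))
    hi_c <- c(hi_c, c(15, w[2], w[2], 6, 5 * maxp, 2 * maxsf, 5 * maxp,
                      2 * maxsf))
  }
  list(lower = c(lo_b, lo_c), upper = c(hi_b, hi_c))
}

# Data-driven initial parameter vector: baseline from the lower envelope
# of the grid, components from band-restricted residual peaks.
.data_start <- function(grid, band_windows) {
  f <- grid$frequencies
  env <- apply(grid$power, 2, min)
  c0 <- max(min(env) * 0.9, 0)
  a0 <- 1.5
  k0 <- max((env[1] - c0), 1e-6) * f[1]^a0
  base0 <- k0 / f^a0 + c0
  theta <- c(k0, a0, 0, c0, 0.3)
  for (w in band_windows) {
    sel <- f >= w[1] & f <= w[2]
    resid <- sweep(grid$power[, sel, drop = FALSE], 2, base0[sel])
    wk <- pmax(apply(resid, 1, max), 0)
    mu_hat <- f[sel][apply(resid, 1, which.max)]
    # peak-frequency endpoints read off only where the component carries
    # appreciable weight; elsewhere the argmax is noise
    informative <- which(wk > 0.2 * max(wk))
    if (!length(informative)) informative <- seq_along(wk)
    margin <- 0.02 * diff(w)
    mu0 <- min(max(mu_hat[informative[1]], w[1] + margin), w[2] - margin)
    mu1 <- min(max(mu_hat[informative[length(informative)]],
                   w[1] + margin), w[2] - margin)
    a1 <- max(wk)
    ipk <- which.max(wk)
    s1 <- if (a1 > 0) {
      below <- which(wk <= a1 / 2 & seq_along(wk) > ipk)
      sf_half <- if (length(below)) grid$sfs[min(below)]
                 else max(grid$sfs)
      max(sf_half / sqrt(2 * log(2)), 0.05)
    } else 0.3
    a2 <- if (a1 > 0 && wk[1] < 0.8 * a1) max(a1 - wk[1], 0) else 0
    theta <- c(theta, 4, mu0, mu1, 2, a1, s1, a2, 0.08)
  }
  theta
}

.random_start <- function(grid, band_windows) {
  maxp <- max(grid$power)
  minp <- min(grid$power)
  f1 <- grid$frequencies[1]
  a0 <- stats::runif(1, 0.5, 3)
  c0 <- stats::runif(1, 0, minp)
  k0 <- max(mean(grid$power[, 1]) - c0, 1e-6) * f1^a0
  theta <- c(k0, a0, stats::runif(1, 0, 50), c0,
             exp(stats::runif(1, log(0.05), log(1.5))))
  for (w in band_windows) {
    mus <- sort(stats::runif(2, w[1], w[2]))
    if (stats::runif(1) < 0.5) mus <- rev(mus)
    a1 <- stats::runif(1, 0, 2 * maxp)
    theta <- c(theta, stats::runif(1, 2, 8), mus[1], mus[2],
               stats::runif(1, 1, 4), a1,
               exp(stats::runif(1, log(0.05), log(1))),
               stats::runif(1, 0, a1),
               exp(stats::runif(1, log(0.03), log(0.3))))
  }
  theta
}

# Multiplicative/additive jitter of an incumbent solution for
# basin-hopping polish rounds; the sigmoid shape parameters (n, sf0) that
# drive the local traps get the largest perturbation.
.jitter_start <- function(theta, bounds) {
  th <- theta
  th[5] <- th[5] * exp(stats::rnorm(1, 0, 0.4))             # sf0
  for (i in 0:2) {
    o <- 5 + i * 8
    th[o + 1] <- th[o + 1] * exp(stats::rnorm(1, 0, 0.15))  # sigma
    th[o + 2] <- th[o + 2] + stats::rnorm(1, 0, 1.5)        # mu0
    th[o + 3] <- th[o + 3] + stats::rnorm(1, 0, 1.5)        # mu1
    th[o + 4] <- th[o + 4] * exp(stats::rnorm(1, 0, 0.5))   # n
    th[o + 5] <- th[o + 5] * exp(stats::rnorm(1, 0, 0.1))   # A1
    th[o + 6] <- th[o + 6] * exp(stats::rnorm(1, 0, 0.1))   # sigma1
    th[o + 7] <- th[o + 7] * exp(stats::rnorm(1, 0, 0.1))   # A2
    th[o + 8] <- th[o + 8] * exp(stats::rnorm(1, 0, 0.1))   # sigma2
  }
  pmin(pmax(th, bounds$lower), bounds$upper)
}

#' Fit the two-dimensional spectral model to a spectrum grid
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) over all model parameters, minimizing the mean
#' squared error between model and data over the flattened SF x frequency
#' grid, with a data-driven first start plus seeded random restarts; the
#' lowest-MSE solution is kept. Each component's peak-frequency
#' trajectory is confined to its band window by construction.
#'
#' @param grid a [spectrum_grid()]; must cover at least 20-120 Hz and 5
#'   SFs.
#' @param restarts number of random restarts in addition to the
#'   data-driven start (default 20).
#' @param polish number of basin-hopping rounds: seeded jitters of the
#'   best solution so far, each re-optimized and kept only on improvement
#'   (default 8). Escapes the occasional local minimum in the coupled
#'   sigmoid shape parameters.
#' @param seed integer seed for the restart draws.
#' @param band_windows band windows (default [gamma_bands()]).
#' @param snr_threshold component-counting threshold (default 3).
#' @param control `minpack.lm::nls.lm.control` list.
#' @return Object of class `fit_result`: `params` (fitted
#'   [model_params()]), `gof` (goodness of fit), `component_snr` (if the
#'   grid has a blank spectrum), `n_components`, `residuals` matrix,
#'   `diagnostics` (per-start MSE, convergence info).
#' @export
fit_model <- function(grid, restarts = 20, polish = 8, seed = 1,
                      band_windows = gamma_bands(), snr_threshold = 3,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-12, ptol = 1e-12)) {
  stopifnot(inherits(grid, "spectrum_grid"))
  if (length(grid$sfs) < 5)
    stop("spectrum grid needs at least 5 spatial frequencies")
  if (any(grid$frequencies <= 0))
    stop("spectrum grid has non-positive frequencies")
  bounds <- .fit_bounds(grid, band_windows)
  target <- as.numeric(grid$power)
  resid_fun <- function(theta) {
    p <- .par_unpack(theta, band_windows)
    as.numeric(eval_model(p, grid$sfs, grid$frequencies)) - target
  }
  starts <- list(.data_start(grid, band_windows))
  if (restarts > 0) {
    rnd <- .with_seed(seed, lapply(seq_len(restarts), function(i)
      .random_start(grid, band_windows)))
    starts <- c(starts, rnd)
  }
  run_lm <- function(th0) {
    tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(th0, lower = bounds$lower,
                           upper = bounds$upper, fn = resid_fun,
                           control = control)),
      error = function(e) NULL)
  }
  best <- NULL
  mses <- numeric(length(starts))
  n_failed <- 0
  for (i in seq_along(starts)) {
    res <- run_lm(pmin(pmax(starts[[i]], bounds$lower), bounds$upper))
    if (is.null(res)) {
      n_failed <- n_failed + 1
      mses[i] <- Inf
      next
    }
    mses[i] <- mean(res$fvec^2)
    if (is.null(best) || mses[i] < mean(best$fvec^2)) best <- res
  }
  if (is.null(best))
    stop("optimizer failed on all ", length(starts), " starts")
  if (polish > 0) {
    for (j in seq_len(polish)) {
      th <- .with_seed(seed + j + 1L, .jitter_start(best$par, bounds))
      res <- run_lm(th)
      if (!is.null(res) && mean(res$fvec^2) < mean(best$fvec^2))
        best <- res
      if (mean(best$fvec^2) < 1e-12 * mean(target^2)) break
    }
  }
  params <- .par_unpack(best$par, band_windows)
  pred <- eval_model(params, grid$sfs, grid$frequencies)
  gof <- goodness_of_fit(grid$power, pred)
  snr <- NULL
  ncomp <- NA_integer_
  if (!is.null(grid$blank_power)) {
    snr <- component_snr(params, grid$blank_power, grid$frequencies,
                         grid$sfs)
    ncomp <- count_components(snr, snr_threshold)
  }
  structure(list(params = params, gof = gof, component_snr = snr,
                 n_components = ncomp, residuals = grid$power - pred,
                 diagnostics = list(
                   mse = mses, best_start = which.min(mses),
                   iterations = best$niter,
                   converged = best$info %in% 1:4,
                   restarts = restarts, n_failed_starts = n_failed),
                 grid = grid, snr_threshold = snr_threshold),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Two-dimensional gamma spectrum fit\n")
  cat(sprintf("  goodness of fit: %.4f\n", x$gof))
  if (!is.null(x$component_snr)) {
    cat("  component SNR: ",
        paste(sprintf("%s=%.2f", names(x$component_snr), x$component_snr),
              collapse = ", "), "\n", sep = "")
    cat("  components counted (SNR > ", x$snr_threshold, "): ",
        x$n_components, "\n", sep = "")
  }
  invisible(x)
}

#' Fitted SF tuning curve of one component
#'
#' Extracts a component's amplitude (weight) profile from a fit as a
#' tuning curve over the grid's sampled SF range.
#'
#' @param fit a [fit_model()] result.
#' @param band `"LG"`, `"MG"` or `"HG"`.
#' @param n_points number of SF samples of the curve (log-spaced).
#' @return A [tuning_curve()] with the component label as source.
#' @export
component_tuning <- function(fit, band = c("LG", "MG", "HG"),
                             n_points = 50) {
  band <- match.arg(band)
  sfs <- exp(seq(log(min(fit$grid$sfs)), log(max(fit$grid$sfs)),
                 length.out = n_points))
  tuning_curve(sfs, eval_weight(fit$params$components[[band]], sfs),
               source = band)
}
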