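# Spatial-frequency tuning metrics, difference-of-Gaussians tuning fits,
# and the 1D-Gaussian receptive-field fit.

#' Construct a tuning curve
#'
#' @param sfs spatial frequencies, cycles/degree, increasing, >= 5 values.
#' @param response non-negative responses (power or firing rate), same
#'   length.
#' @param source tag: `"LG"`, `"MG"`, `"HG"`, `"MUA"` or
#'   `"baseline-band"`.
#' @return Object of class `tuning_curve`.
#' @export
tuning_curve <- function(sfs, response,
                         source = c("LG", "MG", "HG", "MUA",
                                    "baseline-band")) {
  source <- match.arg(source)
  stopifnot(length(sfs) >= 5, length(response) == length(sfs),
            all(diff(sfs) > 0), all(is.finite(response)),
            all(response >= 0))
  structure(list(sfs = sfs, response = response, source = source),
            class = "tuning_curve")
}

# Dense evaluation of a tuning curve over its sampled SF range: the DoG
# fit when it succeeds with adequate fit quality, else monotone (hyman)
# spline interpolation of the samples.
.dense_curve <- function(t, n = 10000, dog_fit = NULL) {
  g <- exp(seq(log(min(t$sfs)), log(max(t$sfs)), length.out = n))
  if (is.null(dog_fit))
    dog_fit <- tryCatch(fit_dog(t, restarts = 5, seed = 1),
                        error = function(e) NULL)
  if (!is.null(dog_fit) && is.finite(dog_fit$gof) && dog_fit$gof > 0.9) {
    comp <- component_params("LG", 1, 30, 0, 1, dog_fit$A1, dog_fit$sigma1,
                             dog_fit$A2, dog_fit$sigma2)
    list(sfs = g, response = eval_weight(comp, g))
  } else {
    fun <- stats::splinefun(t$sfs, t$response, method = "hyman")
    list(sfs = g, response = pmax(fun(g), 0))
  }
}

#' Cutoff spatial frequency
#'
#' The largest SF at which the (fitted, continuous) tuning curve equals
#' 50% of its peak, evaluated on a dense grid spanning the sampled SF
#' range. If the response never falls to half maximum within the range,
#' the maximum sampled SF is returned with `censored = TRUE`. Invariant
#' to positive scaling of the response.
#'
#' @param t a [tuning_curve()].
#' @param dense optional precomputed dense curve (internal use).
#' @return List with `cutoff` (cycles/degree) and `censored` (logical).
#' @export
cutoff_sf <- function(t, dense = NULL) {
  if (is.null(dense)) dense <- .dense_curve(t)
  r <- dense$response
  if (max(r) <= 0) stop("cutoff SF undefined for an all-zero curve")
  half <- max(r) / 2
  above <- which(r >= half)
  i <- above[length(above)]
  if (i == length(r))
    return(list(cutoff = max(t$sfs), censored = TRUE))
  # linear interpolation of the descending crossing
  x1 <- dense$sfs[i]; x2 <- dense$sfs[i + 1]
  y1 <- r[i]; y2 <- r[i + 1]
  list(cutoff = x1 + (half - y1) * (x2 - x1) / (y2 - y1),
       censored = FALSE)
}

#' Spatial-frequency selectivity
#'
#' `1 - response(lowest sampled SF) / response(optimal SF)`, computed on
#' the fitted continuous curve and clipped to `[0, 1]`. A low-pass curve
#' peaking at the lowest SF has selectivity 0; a curve with zero response
#' at the lowest SF and a positive peak has selectivity 1.
#'
#' @param t a [tuning_curve()].
#' @param dense optional precomputed dense curve (internal use).
#' @return Scalar in `[0, 1]`.
#' @export
sf_selectivity <- function(t, dense = NULL) {
  if (is.null(dense)) dense <- .dense_curve(t)
  r <- dense$response
  if (max(r) <= 0) stop("SF selectivity undefined for an all-zero curve")
  min(max(1 - r[1] / max(r), 0), 1)
}

#' Both tuning metrics from one dense evaluation
#'
#' Computes [cutoff_sf()] and [sf_selectivity()] from a single fitted
#' continuous curve (cheaper than calling each separately).
#'
#' @param t a [tuning_curve()].
#' @return List with `cutoff`, `censored`, `selectivity`.
#' @export
tuning_metrics <- function(t) {
  dense <- .dense_curve(t)
  co <- cutoff_sf(t, dense)
  list(cutoff = co$cutoff, censored = co$censored,
       selectivity = sf_selectivity(t, dense))
}

#' Fit a difference of Gaussians to a tuning curve
#'
#' Bounded least squares of
#' `A1 exp(-SF^2/(2 sigma1^2)) - A2 exp(-SF^2/(2 sigma2^2))` (floored at
#' 0) with seeded multi-start, as used for the component amplitude
#' profiles and for MUA / baseline-band tuning.
#'
#' @param t a [tuning_curve()].
#' @param restarts random restarts in addition to a moment-based start.
#' @param seed integer seed.
#' @return List with `A1`, `sigma1`, `A2`, `sigma2`, `gof` (`NA` with
#'   `degenerate = TRUE` for constant data) and `fitted` values.
#' @export
fit_dog <- function(t, restarts = 10, seed = 1) {
  y <- t$response
  s <- t$sfs
  if (diff(range(y)) == 0) {
    return(list(A1 = 0, sigma1 = 1, A2 = 0, sigma2 = 1, gof = NA_real_,
                degenerate = TRUE, fitted = rep(mean(y), length(y))))
  }
  lower <- c(0, 0.01, 0, 0.01)
  upper <- c(10 * max(y), 4 * max(s), 10 * max(y), 4 * max(s))
  fn <- function(p) {
    pmax(p[1] * exp(-s^2 / (2 * p[2]^2)) -
           p[3] * exp(-s^2 / (2 * p[4]^2)), 0) - y
  }
  ipk <- which.max(y)
  st0 <- c(max(y), max(s[ipk], 0.1) / sqrt(2 * log(2)),
           max(max(y) - y[1], 0), max(s[1], 0.05))
  starts <- c(list(st0), .with_seed(seed, lapply(seq_len(restarts),
    function(i) c(stats::runif(1, 0, 2 * max(y)),
                  exp(stats::runif(1, log(0.05), log(max(s)))),
                  stats::runif(1, 0, 2 * max(y)),
                  exp(stats::runif(1, log(0.02), log(0.5)))))))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(st, lower = lower, upper = upper, fn = fn)),
      error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) || mean(res$fvec^2) < mean(best$fvec^2)))
      best <- res
  }
  if (is.null(best)) stop("DoG fit failed on all starts")
  p <- best$par
  fitted <- fn(p) + y
  list(A1 = p[1], sigma1 = p[2], A2 = p[3], sigma2 = p[4],
       gof = goodness_of_fit(y, fitted), degenerate = FALSE,
       fitted = fitted)
}

#' Fit a 1D Gaussian to a receptive-field map marginal
#'
#' Least-squares Gaussian (amplitude, center, sigma, offset) to the
#' averaged response along one axis of a sparse-noise RF map; the center
#' and sigma estimate the RF position and radius on that axis. Adding a
#' constant to the map changes only the offset.
#'
#' @param position stimulus positions, degrees, >= 5 values.
#' @param response mean response at each position.
#' @param restarts random restarts (default 10).
#' @param seed integer seed.
#' @return List with `center` (deg), `radius` (Gaussian sigma, deg),
#'   `amplitude`, `offset`, `gof`.
#' @export
fit_rf_gaussian <- function(position, response, restarts = 10, seed = 1) {
  stopifnot(length(position) >= 5, length(response) == length(position))
  if (diff(range(response)) == 0) stop("flat RF map: Gaussian fit undefined")
  span <- diff(range(position))
  fn <- function(p) {
    p[1] * exp(-(position - p[2])^2 / (2 * p[3]^2)) + p[4] - response
  }
  lower <- c(0, min(position) - span, span / 100, -Inf)
  upper <- c(10 * diff(range(response)), max(position) + span,
             4 * span, Inf)
  st0 <- c(diff(range(response)), position[which.max(response)],
           span / 4, min(response))
  starts <- c(list(st0), .with_seed(seed, lapply(seq_len(restarts),
    function(i) c(stats::runif(1, 0, 2 * diff(range(response))),
                  stats::runif(1, min(position), max(position)),
                  stats::runif(1, span / 20, span),
                  stats::runif(1, min(response), max(response))))))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(st, lower = lower, upper = upper, fn = fn)),
      error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) || mean(res$fvec^2) < mean(best$fvec^2)))
      best <- res
  }
  if (is.null(best)) stop("RF Gaussian fit failed on all starts")
  p <- best$par
  list(center = p[2], radius = p[3], amplitude = p[1], offset = p[4],
       gof = goodness_of_fit(response, fn(p) + response))
}
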