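#' Default gamma band windows
#'
#' Frequency windows (Hz) of the three narrowband gamma components: low
#' gamma (LG), medium gamma (MG) and high gamma (HG). The windows are
#' non-overlapping and ordered; the model fit confines each component's
#' peak-frequency trajectory to its window.
#'
#' @return Named list of length-2 numeric vectors `(lo, hi)` in Hz.
#' @export
gamma_bands <- function() {
  list(LG = c(25, 45), MG = c(45, 65), HG = c(65, 100))
}

#' Aperiodic baseline parameters
#'
#' The aperiodic (1/f-like) part of the LFP power spectrum is
#' `k / (f^a + b) + c`: a power-law decay with scale `k`, exponent `a`,
#' denominator offset `b` (a knee) and additive floor `c`.
#'
#' @param k scale, > 0 (power units).
#' @param a decay exponent, > 0 (dimensionless); `a > 0` makes the baseline
#'   strictly decreasing in frequency.
#' @param b denominator offset, >= 0 (Hz^a units).
#' @param c additive floor, >= 0 (power units).
#' @return Object of class `baseline_params`.
#' @export
baseline_params <- function(k, a, b = 0, c = 0) {
  stopifnot(k >= 0, a > 0, b >= 0, c >= 0)
  structure(list(k = k, a = a, b = b, c = c), class = "baseline_params")
}

#' Parameters of one gamma component
#'
#' Each component is a Gaussian bump in frequency whose amplitude follows a
#' difference of Gaussians (DoG) in spatial frequency and whose peak
#' frequency follows a Naka-Rushton (sigmoid) function of spatial
#' frequency.
#'
#' @param label one of `"LG"`, `"MG"`, `"HG"`.
#' @param sigma Gaussian bandwidth in Hz, > 0.
#' @param K0 peak-frequency offset in Hz (value at SF = 0).
#' @param K peak-frequency swing in Hz (signed; asymptote is `K0 + K`).
#' @param n Hill exponent of the sigmoid, > 0.
#' @param A1,sigma1 amplitude (>= 0) and SF width (> 0, cycles/degree) of
#'   the excitatory Gaussian of the DoG amplitude profile.
#' @param A2,sigma2 amplitude (>= 0) and SF width (> 0) of the subtractive
#'   Gaussian.
#' @return Object of class `component_params`.
#' @export
component_params <- function(label, sigma, K0, K, n, A1, sigma1, A2, sigma2) {
  label <- match.arg(label, c("LG", "MG", "HG"))
  stopifnot(sigma > 0, n > 0, A1 >= 0, sigma1 > 0, A2 >= 0, sigma2 > 0)
  structure(list(label = label, sigma = sigma, K0 = K0, K = K, n = n,
                 A1 = A1, sigma1 = sigma1, A2 = A2, sigma2 = sigma2),
            class = "component_params")
}

#' Full two-dimensional spectral model parameters
#'
#' Bundles the aperiodic baseline, exactly three gamma components (LG, MG,
#' HG in order), the shared half-saturation spatial frequency `sf0` of the
#' peak-frequency sigmoids, and the band windows that confine each
#' component.
#'
#' @param baseline a [baseline_params()] object.
#' @param components list of three [component_params()] (LG, MG, HG).
#' @param sf0 shared half-saturation SF, cycles/degree, > 0.
#' @param band_windows named list of band windows, see [gamma_bands()].
#' @return Object of class `model_params`.
#' @export
model_params <- function(baseline, components, sf0,
                         band_windows = gamma_bands()) {
  stopifnot(inherits(baseline, "baseline_params"),
            length(components) == 3L, sf0 > 0)
  labs <- vapply(components, `[[`, "", "label")
  stopifnot(identical(labs, c("LG", "MG", "HG")))
  lo <- vapply(band_windows, `[`, 0, 1)
  hi <- vapply(band_windows, `[`, 0, 2)
  stopifnot(all(lo < hi), all(hi[-3] <= lo[-1]))
  names(components) <- labs
  structure(list(baseline = baseline, components = components, sf0 = sf0,
                 band_windows = band_windows), class = "model_params")
}

#' Evaluate the aperiodic baseline
#'
#' @param p a [baseline_params()] object.
#' @param f frequency vector, Hz, all > 0.
#' @return Power at each frequency: `k / (f^a + b) + c`.
#' @export
eval_baseline <- function(p, f) {
  stopifnot(all(f > 0))
  p$k / (f^p$a + p$b) + p$c
}

#' Evaluate a component's peak-frequency trajectory
#'
#' Naka-Rushton sigmoid of spatial frequency:
#' `mu(SF) = K0 + K * SF^n / (SF^n + sf0^n)`.
#'
#' @param comp a [component_params()] object.
#' @param sf0 half-saturation SF, cycles/degree.
#' @param sf spatial frequency vector, cycles/degree, >= 0.
#' @return Peak frequency in Hz at each SF.
#' @export
eval_mu <- function(comp, sf0, sf) {
  stopifnot(all(sf >= 0), sf0 > 0)
  s <- sf^comp$n
  comp$K0 + comp$K * s / (s + sf0^comp$n)
}

#' Evaluate a component's amplitude (weight) profile
#'
#' Difference of Gaussians in spatial frequency,
#' `A1 exp(-SF^2/(2 sigma1^2)) - A2 exp(-SF^2/(2 sigma2^2))`, floored at 0:
#' the raw difference can dip below zero, but a negative spectral bump is
#' unphysical, so evaluation clamps while `floor = FALSE` exposes the raw
#' value for diagnostics.
#'
#' @param comp a [component_params()] object.
#' @param sf spatial frequency vector, cycles/degree, >= 0.
#' @param floor clamp negative weights to 0 (default `TRUE`).
#' @return Component weight (power units) at each SF.
#' @export
eval_weight <- function(comp, sf, floor = TRUE) {
  stopifnot(all(sf >= 0))
  w <- comp$A1 * exp(-sf^2 / (2 * comp$sigma1^2)) -
       comp$A2 * exp(-sf^2 / (2 * comp$sigma2^2))
  if (floor) pmax(w, 0) else w
}

#' Evaluate the full two-dimensional spectral model
#'
#' Power(SF, f) = Baseline(f) + sum over components of
#' `W_i(SF) * exp(-(f - mu_i(SF))^2 / (2 sigma_i^2))`.
#'
#' @param p a [model_params()] object.
#' @param sf spatial frequency vector, cycles/degree.
#' @param f frequency vector, Hz, > 0.
#' @return `length(sf) x length(f)` matrix of model power.
#' @export
eval_model <- function(p, sf, f) {
  stopifnot(all(f > 0), all(sf >= 0))
  base <- eval_baseline(p$baseline, f)
  out <- matrix(rep(base, each = length(sf)), nrow = length(sf))
  for (comp in p$components) {
    w <- eval_weight(comp, sf)
    mu <- eval_mu(comp, p$sf0, sf)
    out <- out + outer(seq_along(sf), seq_along(f), function(i, j) {
      w[i] * exp(-(f[j] - mu[i])^2 / (2 * comp$sigma^2))
    })
  }
  dimnames(out) <- list(sf = signif(sf, 6), f = signif(f, 6))
  out
}

#' Goodness of fit of a model prediction
#'
#' `1 - SS_residual / SS_total`, with SS_total taken about the grand mean
#' of the data over the flattened grid. Equals 1 for a perfect fit, 0 for a
#' constant prediction at the data mean, and can be negative for a fit
#' worse than the mean.
#'
#' @param data numeric vector or matrix of observed power.
#' @param prediction model prediction, same shape.
#' @return Scalar goodness of fit, <= 1.
#' @export
goodness_of_fit <- function(data, prediction) {
  stopifnot(identical(dim(data), dim(prediction)),
            length(data) == length(prediction))
  d <- as.numeric(data)
  m <- as.numeric(prediction)
  ss_tot <- sum((d - mean(d))^2)
  if (ss_tot == 0) stop("goodness of fit undefined for constant data")
  1 - sum((d - m)^2) / ss_tot
}

#' Per-component signal-to-noise ratio
#'
#' SNR of a fitted gamma component: its maximum weight over the sampled
#' spatial frequencies divided by the mean blank-condition power inside the
#' component's band window.
#'
#' @param params a [model_params()] object (typically fitted).
#' @param blank_power blank-condition power spectrum (vector).
#' @param blank_freqs frequencies (Hz) of `blank_power`.
#' @param sfs spatial frequencies over which to take the max weight.
#' @return Named numeric vector of 3 SNR values (LG, MG, HG).
#' @export
component_snr <- function(params, blank_power, blank_freqs, sfs) {
  stopifnot(length(blank_power) == length(blank_freqs))
  vapply(params$components, function(comp) {
    win <- params$band_windows[[comp$label]]
    sel <- blank_freqs >= win[1] & blank_freqs <= win[2]
    if (!any(sel))
      stop("blank spectrum has no frequencies inside the ", comp$label,
           " band window")
    max(eval_weight(comp, sfs)) / mean(blank_power[sel])
  }, numeric(1))
}

#' Count required gamma components
#'
#' A component is counted as present when its SNR is strictly greater than
#' the threshold (an SNR exactly at the threshold is not counted).
#'
#' @param snrs numeric vector of 3 component SNRs, >= 0.
#' @param threshold SNR threshold (default 3).
#' @return Integer in 0..3.
#' @export
count_components <- function(snrs, threshold = 3) {
  stopifnot(all(snrs >= 0))
  sum(snrs > threshold)
}

#' Site inclusion signal-to-noise ratio
#'
#' SD of the per-trial response under visual stimulation divided by the SD
#' under the blank condition; a site passes when the ratio exceeds 3. A
#' zero blank SD is degenerate: the site is flagged and excluded rather
#' than assigned an infinite SNR.
#'
#' @param stim_response per-trial responses under stimulation (firing rate
#'   or band power).
#' @param blank_response per-trial responses under the blank condition.
#' @param threshold inclusion threshold (default 3).
#' @return List with `snr`, logical `included`, and logical `degenerate`.
#' @export
site_snr <- function(stim_response, blank_response, threshold = 3) {
  stopifnot(length(stim_response) >= 2, length(blank_response) >= 2)
  sb <- stats::sd(blank_response)
  if (sb == 0)
    return(list(snr = NA_real_, included = FALSE, degenerate = TRUE))
  s <- stats::sd(stim_response) / sb
  list(snr = s, included = s > threshold, degenerate = FALSE)
}
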