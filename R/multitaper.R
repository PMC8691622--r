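# Slepian (discrete prolate spheroidal) tapers and multitaper spectra.
#
# Tapers are computed from the symmetric tridiagonal matrix whose
# eigenvectors are the DPSS (Percival & Walden's tridiagonal formulation):
# diagonal ((N-1-2t)/2)^2 cos(2 pi W), off-diagonal t(N-t)/2. This is exact
# and numerically stable for the window lengths used here (<= a few
# thousand samples).

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n number of samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5); must satisfy `k <= 2*nw - 1` for
#'   well-concentrated tapers.
#' @return `n x k` matrix; columns are unit-energy tapers ordered by
#'   decreasing spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  stopifnot(n >= 2, nw > 0, k >= 1)
  if (k > 2 * nw - 1)
    stop("k must be at most 2*nw - 1 (got k = ", k, ", nw = ", nw, ")")
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t * (n - t) / 2)[-1]
  # full symmetric matrix; eigen() on a banded matrix is fast enough here
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), seq_len(n))] <- diag_main
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign: symmetric tapers have positive mean,
  # antisymmetric ones a positive initial lobe
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    s <- sum(v)
    if (abs(s) > 1e-8) {
      if (s < 0) v <- -v
    } else if (v[which.max(abs(v))[1]] < 0 && v[1] > 0) {
      # keep as is
    } else if (v[1] < 0) v <- -v
    tapers[, j] <- v
  }
  .taper_cache[[key]] <- tapers
  tapers
}

# Select window samples from a trials x samples matrix. `window` is in
# seconds relative to `onset` (itself seconds from the first sample).
.window_index <- function(n_samples, rate, window, onset) {
  stopifnot(length(window) == 2, window[2] > window[1])
  i0 <- round((onset + window[1]) * rate) + 1
  i1 <- round((onset + window[2]) * rate)
  if (i0 < 1 || i1 > n_samples)
    stop("analysis window [", window[1], ", ", window[2],
         "] s (onset ", onset, " s) falls outside the trial")
  i0:i1
}

#' Multitaper power spectral density
#'
#' Slepian-tapered eigenspectra averaged over tapers per trial, then over
#' trials. Each windowed trial is mean-subtracted before tapering so DC
#' does not leak into low frequencies. The estimate is a one-sided density:
#' for white noise of variance `s^2` sampled at `rate`,
#' `sum(psd * df) ~ s^2`.
#'
#' @param x numeric matrix, trials x samples (a single trial may be passed
#'   as a vector).
#' @param rate sampling rate, Hz.
#' @param window analysis window `c(t0, t1)` in seconds relative to
#'   `onset`; default `c(0.3, 2.0)` (300 to 2000 ms after stimulus onset).
#' @param onset time of stimulus onset in seconds from the first sample
#'   (default 0; pass the pre-stimulus duration for full-trial input).
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5).
#' @return List with `frequencies` (Hz), `per_trial` (trials x n_freq
#'   matrix) and `power` (mean over trials).
#' @export
multitaper_psd <- function(x, rate, window = c(0.3, 2.0), onset = 0,
                           nw = 3, k = 5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(rate > 0)
  idx <- .window_index(ncol(x), rate, window, onset)
  xs <- x[, idx, drop = FALSE]
  n <- length(idx)
  tapers <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  freqs <- (seq_len(nf) - 1) * rate / n
  xs <- xs - rowMeans(xs)
  per_trial <- matrix(0, nrow(xs), nf)
  for (tr in seq_len(nrow(xs))) {
    acc <- numeric(nf)
    for (j in seq_len(k)) {
      sp <- stats::fft(xs[tr, ] * tapers[, j])[seq_len(nf)]
      acc <- acc + (2 / rate) * (Re(sp)^2 + Im(sp)^2)
    }
    per_trial[tr, ] <- acc / k
  }
  # one-sided correction: DC and Nyquist are not doubled
  per_trial[, 1] <- per_trial[, 1] / 2
  if (n %% 2 == 0) per_trial[, nf] <- per_trial[, nf] / 2
  list(frequencies = freqs, per_trial = per_trial,
       power = colMeans(per_trial))
}

# Tapered FFTs for coherence: returns array [trial, taper, freq].
.taper_ffts <- function(x, rate, window, onset, nw, k) {
  idx <- .window_index(ncol(x), rate, window, onset)
  xs <- x[, idx, drop = FALSE]
  n <- length(idx)
  tapers <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  xs <- xs - rowMeans(xs)
  out <- array(complex(real = 0), dim = c(nrow(xs), k, nf))
  for (tr in seq_len(nrow(xs)))
    for (j in seq_len(k))
      out[tr, j, ] <- stats::fft(xs[tr, ] * tapers[, j])[seq_len(nf)]
  list(ffts = out, frequencies = (seq_len(nf) - 1) * rate / n)
}

#' Field-field coherence (multitaper)
#'
#' Coherence magnitude `|S_xy| / sqrt(S_xx S_yy)` with the cross- and
#' auto-spectra pooled jointly over tapers and trials (a single pooled
#' estimate; per-trial coherence is not defined). Invariant to linear
#' scaling of either signal.
#'
#' @param x,y trial-aligned numeric matrices, trials x samples, equal
#'   shape.
#' @inheritParams multitaper_psd
#' @return Object of class `coherence_result`: list with `frequencies`,
#'   `coherence` (in `[0, 1]`), `n_trials`, `nw`, `k`.
#' @export
coherence <- function(x, y, rate, window = c(0.3, 2.0), onset = 0,
                      nw = 3, k = 5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  if (!all(dim(x) == dim(y)))
    stop("x and y must have identical trials x samples shape")
  if (nrow(x) == 1 && k == 1)
    stop("coherence with a single trial and single taper is degenerate ",
         "(identically 1)")
  fx <- .taper_ffts(x, rate, window, onset, nw, k)
  fy <- .taper_ffts(y, rate, window, onset, nw, k)
  sxy <- apply(fx$ffts * Conj(fy$ffts), 3, sum)
  sxx <- apply(Mod(fx$ffts)^2, 3, sum)
  syy <- apply(Mod(fy$ffts)^2, 3, sum)
  coh <- Mod(sxy) / sqrt(sxx * syy)
  coh[!is.finite(coh)] <- 0
  structure(list(frequencies = fx$frequencies, coherence = pmin(coh, 1),
                 n_trials = nrow(x), nw = nw, k = k),
            class = "coherence_result")
}

# Bin spike times (seconds from trial start) onto the LFP sample grid.
.bin_spikes <- function(spikes, n_samples, rate) {
  out <- matrix(0, length(spikes), n_samples)
  for (tr in seq_along(spikes)) {
    st <- spikes[[tr]]
    if (length(st) == 0) next
    b <- pmin(pmax(floor(st * rate) + 1, 1), n_samples)
    tab <- tabulate(b, nbins = n_samples)
    out[tr, ] <- tab
  }
  out
}

#' Spike-field coherence (multitaper)
#'
#' Coherence between the binarized spike point process (binned at the LFP
#' sampling rate) and the LFP, using the same pooled multitaper estimator
#' as [coherence()]. Trials with no spikes inside the analysis window are
#' excluded and counted.
#'
#' @param spikes list of per-trial spike-time vectors (seconds from trial
#'   start).
#' @param lfp trials x samples LFP matrix.
#' @inheritParams multitaper_psd
#' @return A `coherence_result` with an extra `n_excluded` field.
#' @export
spike_field_coherence <- function(spikes, lfp, rate, window = c(0.3, 2.0),
                                  onset = 0, nw = 3, k = 5) {
  if (is.vector(lfp)) lfp <- matrix(lfp, nrow = 1)
  if (length(spikes) != nrow(lfp))
    stop("spike trial count (", length(spikes),
         ") does not match LFP trial count (", nrow(lfp), ")")
  sp <- .bin_spikes(spikes, ncol(lfp), rate)
  idx <- .window_index(ncol(lfp), rate, window, onset)
  keep <- rowSums(sp[, idx, drop = FALSE]) > 0
  if (!any(keep))
    stop("no trials contain spikes inside the analysis window")
  res <- coherence(sp[keep, , drop = FALSE], lfp[keep, , drop = FALSE],
                   rate, window, onset, nw, k)
  res$n_excluded <- sum(!keep)
  res
}

#' Trial-shuffle control for spike-field coherence
#'
#' Spike trial identities are permuted within each stimulus condition
#' (destroying within-trial spike-LFP locking while preserving condition
#' statistics) and the SFC recomputed; the mean over shuffles is the
#' control spectrum.
#'
#' @param spikes list of per-trial spike-time vectors.
#' @param lfp trials x samples LFP matrix.
#' @param conditions per-trial condition labels (vector, length = trials).
#' @param n_shuffles number of shuffles, >= 1 (default 100).
#' @param seed integer seed for the permutations.
#' @inheritParams multitaper_psd
#' @return A `coherence_result` whose `coherence` is the mean shuffled SFC;
#'   `per_shuffle` holds the individual shuffle spectra.
#' @export
shuffle_control <- function(spikes, lfp, conditions, n_shuffles = 100,
                            seed = 1, rate, window = c(0.3, 2.0),
                            onset = 0, nw = 3, k = 5) {
  stopifnot(n_shuffles >= 1, length(conditions) == length(spikes))
  tab <- table(conditions)
  if (any(tab < 2))
    stop("every condition needs at least 2 trials to permute; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  acc <- NULL
  per <- list()
  res <- NULL
  .with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      perm <- seq_along(spikes)
      for (cond in unique(conditions)) {
        i <- which(conditions == cond)
        perm[i] <- i[sample(length(i))]
      }
      res <- spike_field_coherence(spikes[perm], lfp, rate, window, onset,
                                   nw, k)
      if (is.null(acc)) acc <- res$coherence * 0
      acc <- acc + res$coherence
      per[[s]] <- res$coherence
    }
  })
  res$coherence <- acc / n_shuffles
  res$per_shuffle <- do.call(rbind, per)
  res$n_shuffles <- n_shuffles
  res
}
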