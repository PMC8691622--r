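# The SF x frequency power surface that the two-dimensional model is
# fitted to.

#' Construct a spectrum grid
#'
#' Trial-averaged power over spatial frequency and frequency, plus the
#' blank-condition spectrum used for component SNR.
#'
#' @param frequencies increasing frequency vector, Hz; must cover at least
#'   20-120 Hz.
#' @param sfs increasing SF vector, cycles/degree, >= 5 values.
#' @param power `length(sfs) x length(frequencies)` matrix, >= 0.
#' @param blank_power optional blank-condition power vector over
#'   `frequencies`.
#' @param per_trial optional list (per SF) of trials x frequencies
#'   matrices.
#' @return Object of class `spectrum_grid`.
#' @export
spectrum_grid <- function(frequencies, sfs, power, blank_power = NULL,
                          per_trial = NULL) {
  power <- as.matrix(power)
  stopifnot(all(diff(frequencies) > 0), all(diff(sfs) > 0),
            nrow(power) == length(sfs),
            ncol(power) == length(frequencies),
            all(power >= 0))
  if (min(frequencies) > 20 || max(frequencies) < 120)
    stop("spectrum grid must cover at least 20-120 Hz (got ",
         min(frequencies), "-", max(frequencies), " Hz)")
  if (!is.null(blank_power))
    stopifnot(length(blank_power) == length(frequencies),
              all(blank_power >= 0))
  structure(list(frequencies = frequencies, sfs = sfs, power = power,
                 blank_power = blank_power, per_trial = per_trial),
            class = "spectrum_grid")
}

#' Compute a spectrum grid from a recording
#'
#' Multitaper PSD per SF condition (trial-averaged) and for the blank
#' condition, restricted to the requested frequency range.
#'
#' @param rec a `recording` (see [simulate_recording()]).
#' @param freq_range frequency range to retain, Hz (default
#'   `c(20, 120)`).
#' @param window analysis window relative to stimulus onset, s.
#' @param nw,k multitaper settings.
#' @param keep_trials keep per-trial spectra (default FALSE).
#' @return A [spectrum_grid()].
#' @export
compute_spectrum_grid <- function(rec, freq_range = c(20, 120),
                                  window = c(0.3, 2.0), nw = 3, k = 5,
                                  keep_trials = FALSE) {
  onset <- rec$epochs[["pre"]]
  sfs <- sort(unique(rec$conditions[!is.na(rec$conditions)]))
  if (length(sfs) == 0) stop("recording has no stimulus conditions")
  first <- multitaper_psd(rec$lfp[which(!is.na(rec$conditions))[1], ,
                                  drop = FALSE],
                          rec$rate, window, onset, nw, k)
  sel <- first$frequencies >= freq_range[1] &
         first$frequencies <= freq_range[2]
  freqs <- first$frequencies[sel]
  power <- matrix(0, length(sfs), length(freqs))
  per_trial <- if (keep_trials) vector("list", length(sfs)) else NULL
  for (i in seq_along(sfs)) {
    rows <- which(!is.na(rec$conditions) & rec$conditions == sfs[i])
    psd <- multitaper_psd(rec$lfp[rows, , drop = FALSE], rec$rate,
                          window, onset, nw, k)
    power[i, ] <- psd$power[sel]
    if (keep_trials) per_trial[[i]] <- psd$per_trial[, sel, drop = FALSE]
  }
  blank_rows <- which(is.na(rec$conditions))
  blank <- NULL
  if (length(blank_rows))
    blank <- multitaper_psd(rec$lfp[blank_rows, , drop = FALSE], rec$rate,
                            window, onset, nw, k)$power[sel]
  spectrum_grid(freqs, sfs, power, blank, per_trial)
}

#' Simulate a spectrum grid directly from ground truth
#'
#' Convenience wrapper: simulates `n_trials` LFP trials per SF (plus blank
#' trials), then computes the multitaper spectrum grid. This is the
#' trial-sampled input used throughout validation.
#'
#' @param gt a [make_ground_truth()] object.
#' @param n_trials trials per SF.
#' @param n_blank blank trials.
#' @param seed integer seed.
#' @inheritParams compute_spectrum_grid
#' @return A [spectrum_grid()].
#' @export
simulate_spectrum_grid <- function(gt, n_trials = 50, n_blank = n_trials,
                                   seed = 1, freq_range = c(20, 120),
                                   window = c(0.3, 2.0), nw = 3, k = 5) {
  rec <- simulate_recording(gt, n_trials, n_blank, seed)
  compute_spectrum_grid(rec, freq_range, window, nw, k)
}

#' Noiseless spectrum grid from model parameters
#'
#' Evaluates the model exactly on a regular grid (no trial sampling); the
#' blank spectrum is the aperiodic baseline.
#'
#' @param params a [model_params()] object.
#' @param sfs SF vector.
#' @param frequencies frequency vector, Hz (default 20-120 in 1-Hz bins).
#' @return A [spectrum_grid()].
#' @export
model_spectrum_grid <- function(params, sfs,
                                frequencies = seq(20, 120, by = 1)) {
  spectrum_grid(frequencies, sfs, eval_model(params, sfs, frequencies),
                blank_power = eval_baseline(params$baseline, frequencies))
}
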