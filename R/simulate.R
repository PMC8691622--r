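# Synthetic-data generator: recordings with known ground truth for every
# downstream stage (spectra, model fit, tuning, laminar, decoding).

#' Construct ground truth for the synthetic-data generator
#'
#' Assembles full model parameters plus spike-locking, laminar and
#' edge/surface effect settings under a named preset:
#' * `three_gamma_default` — three components whose spatial-frequency (SF)
#'   tuning matches the qualitative structure of cat V1: HG low-pass
#'   (cutoff ~0.09 cpd, selectivity ~0), MG band-pass at intermediate SF
#'   (cutoff ~0.33, selectivity ~0.54), LG band-pass preferring high SF
#'   (cutoff ~0.68, selectivity ~0.77); LG peak frequency falls
#'   monotonically from 35 to 25 Hz with SF. Component amplitudes are
#'   scaled so each component's SNR (max weight / mean blank band power)
#'   equals `snr_target`.
#' * `lg_only` — only the LG component present.
#' * `two_gamma` — LG and MG present, HG absent.
#' * `no_gamma` — all component amplitudes zero; baseline only.
#' * `laminar` — as default, plus per-band Gaussian depth profiles peaking
#'   at relative depth 0.2 (LG), 0.4 (MG), 0.5 (HG).
#' * `edge_surface` — as default, plus per-band edge-surface log-power
#'   differences (LG positive, MG/HG negative; standardized effect 1 per
#'   gamma feature, 0.3 per MUA feature).
#'
#' @param preset preset name (see above).
#' @param seed integer seed stored with the ground truth; all simulators
#'   derive their randomness from it (same preset + seed gives identical
#'   output).
#' @param snr_target per-component SNR the amplitudes are scaled to
#'   (default 6).
#' @param sfs SF grid, cycles/degree (default 10 log-spaced values
#'   0.03-2.5).
#' @return Object of class `ground_truth`.
#' @export
make_ground_truth <- function(preset = c("three_gamma_default", "lg_only",
                                         "two_gamma", "no_gamma",
                                         "laminar", "edge_surface"),
                              seed = 1, snr_target = 6,
                              sfs = exp(seq(log(0.03), log(2.5),
                                            length.out = 10))) {
  preset <- match.arg(preset)
  base <- baseline_params(k = 200, a = 1.5, b = 0, c = 0.5)
  bands <- gamma_bands()
  # DoG shapes chosen to hit the target tuning metrics (cutoff SF
  # 0.68/0.33/0.09 cpd; SF selectivity 0.77/0.54/~0); unit peak scale,
  # rescaled below to the requested component SNR.
  shapes <- list(
    LG = list(sigma = 3.5, K0 = 35, K = -10, n = 2,
              A1 = 1, sigma1 = 0.527, A2 = 0.840, sigma2 = 0.0936),
    MG = list(sigma = 4.0, K0 = 50, K = 8, n = 2,
              A1 = 1, sigma1 = 0.239, A2 = 0.708, sigma2 = 0.0653),
    HG = list(sigma = 5.0, K0 = 72, K = 6, n = 2,
              A1 = 1, sigma1 = 0.09 / sqrt(2 * log(2)), A2 = 0,
              sigma2 = 0.1))
  active <- switch(preset,
                   no_gamma = character(0),
                   lg_only = "LG",
                   two_gamma = c("LG", "MG"),
                   c("LG", "MG", "HG"))
  sf_dense <- exp(seq(log(min(sfs)), log(max(sfs)), length.out = 2000))
  comps <- lapply(names(shapes), function(lab) {
    s <- shapes[[lab]]
    scale <- 0
    if (lab %in% active) {
      win <- bands[[lab]]
      f_band <- seq(win[1], win[2], by = 0.5)
      blank_mean <- mean(eval_baseline(base, f_band))
      tmp <- component_params(lab, s$sigma, s$K0, s$K, s$n,
                              s$A1, s$sigma1, s$A2, s$sigma2)
      peak_w <- max(eval_weight(tmp, sf_dense))
      scale <- snr_target * blank_mean / peak_w
    }
    component_params(lab, s$sigma, s$K0, s$K, s$n,
                     s$A1 * scale, s$sigma1, s$A2 * scale, s$sigma2)
  })
  params <- model_params(base, comps, sf0 = 0.3, band_windows = bands)
  structure(list(
    preset = preset,
    model_params = params,
    sfs = sfs,
    lock_targets = c(LG = 0.8, MG = 0.5, HG = 0.8),
    laminar_profiles = list(
      LG = list(peak_red = 0.2, width = 0.15, amplitude = 10),
      MG = list(peak_red = 0.4, width = 0.15, amplitude = 10),
      HG = list(peak_red = 0.5, width = 0.15, amplitude = 10)),
    edge_surface_effects = list(
      gamma_d = c(LG = 1, MG = -1, HG = -1),  # standardized, log-power
      gamma_sd = 0.5,                          # log-power trial SD
      gamma_mean = c(LG = 1.5, MG = 1.5, HG = 1),
      mua_d = c(0.3, -0.3, -0.3),              # per time-bin rate features
      mua_sd = 5, mua_mean = 20),
    epochs = c(pre = 0.4, stim = 2.0, post = 0.4),
    rate = 500,
    seed = as.integer(seed)), class = "ground_truth")
}

# Gaussian noise trace whose expected one-sided spectral density equals
# `psd` (evaluated on the FFT grid): independent random phases per
# frequency, inverse FFT. Uses the current RNG stream.
.shaped_noise <- function(psd_fun, n, rate) {
  f <- (seq_len(n) - 1) * rate / n
  half <- if (n %% 2 == 0) n / 2 else (n - 1) / 2
  z <- complex(real = rep(0, n))
  idx <- 2:(if (n %% 2 == 0) half else half + 1)
  s <- psd_fun(f[idx])
  amp <- sqrt(n * rate * s / 4)
  z[idx] <- complex(real = stats::rnorm(length(idx)) * amp,
                    imaginary = stats::rnorm(length(idx)) * amp)
  z[n + 2 - idx] <- Conj(z[idx])
  if (n %% 2 == 0) {
    snyq <- psd_fun(f[half + 1])
    z[half + 1] <- complex(real = stats::rnorm(1) *
                             sqrt(n * rate * snyq / 2))
  }
  Re(stats::fft(z, inverse = TRUE)) / n
}

#' Simulate one LFP trial
#'
#' Spectrally shaped Gaussian noise with independent random phases, so the
#' expected multitaper power spectrum over the stimulus window equals the
#' ground-truth model spectrum at the given SF. The pre- and post-stimulus
#' epochs carry the aperiodic baseline spectrum only; blank trials
#' (`sf = NA`) are baseline-only throughout.
#'
#' @param gt a [make_ground_truth()] object.
#' @param sf stimulus spatial frequency (cycles/degree), or `NA` for a
#'   blank trial.
#' @param seed integer seed for this trial.
#' @param rate sampling rate, Hz (default from `gt`).
#' @return Numeric vector of `rate * sum(epochs)` samples (microvolt
#'   scale).
#' @export
simulate_lfp_trial <- function(gt, sf, seed, rate = gt$rate) {
  stopifnot(rate > 0)
  ep <- gt$epochs
  if (sum(ep) <= 0) stop("non-positive trial duration")
  n_pre <- round(ep[["pre"]] * rate)
  n_stim <- round(ep[["stim"]] * rate)
  n_post <- round(ep[["post"]] * rate)
  base_fun <- function(f) {
    s <- numeric(length(f))
    ok <- f > 0
    s[ok] <- eval_baseline(gt$model_params$baseline, f[ok])
    s
  }
  stim_fun <- if (is.na(sf)) base_fun else function(f) {
    s <- numeric(length(f))
    ok <- f > 0
    s[ok] <- as.numeric(eval_model(gt$model_params, sf, f[ok]))
    s
  }
  .with_seed(seed, {
    c(.shaped_noise(base_fun, n_pre, rate),
      .shaped_noise(stim_fun, n_stim, rate),
      .shaped_noise(base_fun, n_post, rate))
  })
}

#' Simulate phase-locked Poisson spikes for one trial
#'
#' Inhomogeneous Poisson process with instantaneous rate
#' `base_rate * (1 + m cos(phi(t)))`, where `phi` is the narrowband phase
#' of the chosen component band of the supplied LFP trace (band-pass plus
#' analytic-signal phase) and `m` is the ground-truth locking depth for
#' that component.
#'
#' @param gt a [make_ground_truth()] object.
#' @param lfp numeric vector, one trial's LFP.
#' @param component `"LG"`, `"MG"` or `"HG"`.
#' @param base_rate mean firing rate, Hz, > 0.
#' @param seed integer seed.
#' @param sf stimulus SF used to center the band-pass at the component's
#'   peak frequency; defaults to the band-window midpoint when `NA`.
#' @param rate sampling rate, Hz.
#' @return Vector of spike times, seconds from trial start.
#' @export
simulate_spikes <- function(gt, lfp, component = c("LG", "MG", "HG"),
                            base_rate = 20, seed = 1, sf = NA,
                            rate = gt$rate) {
  component <- match.arg(component)
  stopifnot(base_rate > 0)
  m <- gt$lock_targets[[component]]
  if (m < 0 || m > 1) stop("locking depth m must lie in [0, 1]")
  center <- if (is.na(sf)) mean(gt$model_params$band_windows[[component]])
            else eval_mu(gt$model_params$components[[component]],
                         gt$model_params$sf0, sf)
  ph <- analytic_phase(bandpass_filter(lfp, rate, center))
  r <- base_rate * (1 + m * cos(ph))
  p <- pmin(r / rate, 1)
  .with_seed(seed, {
    hit <- stats::runif(length(p)) < p
    (which(hit) - 0.5) / rate
  })
}

#' Simulate a multi-trial recording for one site
#'
#' Generates `n_trials` LFP trials at each SF in `gt$sfs` plus
#' `n_blank` blank trials, with per-trial condition labels and epoch
#' markers; optionally attaches phase-locked spike trains.
#'
#' @param gt a [make_ground_truth()] object.
#' @param n_trials trials per SF condition.
#' @param n_blank blank trials (default equal to `n_trials`).
#' @param seed integer seed.
#' @param spikes_from component label to phase-lock spikes to, or `NA`
#'   (default) for no spikes.
#' @param base_rate spike base rate, Hz.
#' @param site_id,depth_mm,region site metadata.
#' @return Object of class `recording`: list with `lfp` (trials x
#'   samples), `spikes` (list or NULL), `conditions` (per-trial SF, NA for
#'   blank), `epochs`, `rate`, `meta`.
#' @export
simulate_recording <- function(gt, n_trials = 20, n_blank = n_trials,
                               seed = 1, spikes_from = NA, base_rate = 20,
                               site_id = "site1", depth_mm = NA,
                               region = "V1") {
  conds <- c(rep(gt$sfs, each = n_trials), rep(NA_real_, n_blank))
  seeds <- .child_seeds(seed, 2 * length(conds))
  n_samp <- round(sum(gt$epochs) * gt$rate)
  lfp <- matrix(0, length(conds), n_samp)
  for (i in seq_along(conds))
    lfp[i, ] <- simulate_lfp_trial(gt, conds[i], seeds[i])
  spikes <- NULL
  if (!is.na(spikes_from)) {
    spikes <- vector("list", length(conds))
    for (i in seq_along(conds))
      spikes[[i]] <- simulate_spikes(gt, lfp[i, ], spikes_from, base_rate,
                                     seeds[length(conds) + i],
                                     sf = conds[i])
  }
  structure(list(lfp = lfp, spikes = spikes, conditions = conds,
                 epochs = gt$epochs, rate = gt$rate,
                 meta = list(site_id = site_id, depth_mm = depth_mm,
                             region = region)),
            class = "recording")
}

#' Simulate a laminar-probe session
#'
#' Per-channel summaries of a linear-array penetration: physical depths,
#' MUA signal-to-noise ratios, SF selectivity, and per-band power drawn
#' from the ground-truth Gaussian depth profiles (in relative-depth
#' coordinates) plus truncated Gaussian noise. Channels outside the
#' visually driven span get sub-threshold SNR, so anchor finding recovers
#' the intended surface/input-layer/white-matter references.
#'
#' @param gt a [make_ground_truth()] object.
#' @param n_channels number of channels, >= 8 (default 24).
#' @param spacing inter-channel spacing, mm (default 0.1).
#' @param seed integer seed.
#' @param noise_sd relative noise SD on band powers and profiles
#'   (default 0.1; 0 gives noiseless recovery).
#' @param driven channel index range with visually driven spiking
#'   (default channels 2 to `n_channels - 1`).
#' @param session_id session identifier.
#' @return Object of class `laminar_session`: list with `channels` (data
#'   frame: channel, depth_mm, mua_snr, sf_selectivity, LG/MG/HG power),
#'   `session_id`, and `truth` (intended anchors and peak depths).
#' @export
simulate_laminar_session <- function(gt, n_channels = 24, spacing = 0.1,
                                     seed = 1, noise_sd = 0.1,
                                     driven = c(2, n_channels - 1),
                                     session_id = "session1") {
  stopifnot(n_channels >= 8, spacing > 0)
  for (p in gt$laminar_profiles)
    if (p$peak_red < 0 || p$peak_red > 1)
      stop("laminar profile peaks must lie in [0, 1] relative depth")
  depth <- (seq_len(n_channels) - 1) * spacing
  is_driven <- seq_len(n_channels) >= driven[1] &
               seq_len(n_channels) <= driven[2]
  cha2 <- which(is_driven)[1]
  cha3 <- which(is_driven)[sum(is_driven)]
  surface <- depth[cha2] - 0.05
  white <- depth[cha3] + 0.05
  cha1 <- which.min(abs(depth - (surface + white) / 2))
  red <- assign_red(depth, list(surface_mm = surface,
                                cha1_mm = depth[cha1],
                                white_mm = white))$red
  .with_seed(seed, {
    mua_snr <- ifelse(is_driven,
                      pmax(6 + stats::rnorm(n_channels, 0, 6 * noise_sd),
                           3.5),
                      pmin(1 + stats::rnorm(n_channels, 0, noise_sd), 2.5))
    span <- max(abs(depth - depth[cha1]))
    sf_sel <- 0.2 + 0.6 * abs(depth - depth[cha1]) / span +
      stats::rnorm(n_channels, 0, 0.2 * noise_sd)
    bp <- sapply(names(gt$laminar_profiles), function(b) {
      pr <- gt$laminar_profiles[[b]]
      mu <- pr$amplitude *
        exp(-(red - pr$peak_red)^2 / (2 * pr$width^2))
      pmax(mu * (1 + stats::rnorm(n_channels, 0, noise_sd)), 0)
    })
    channels <- data.frame(channel = seq_len(n_channels),
                           depth_mm = depth, mua_snr = mua_snr,
                           sf_selectivity = sf_sel)
    channels <- cbind(channels, as.data.frame(bp))
  })
  # intended Cha1 must carry the minimum selectivity even under noise
  channels$sf_selectivity[cha1] <-
    min(channels$sf_selectivity) - 0.01
  structure(list(channels = channels, session_id = session_id,
                 truth = list(cha1 = cha1, cha2 = cha2, cha3 = cha3,
                              peak_red = vapply(gt$laminar_profiles,
                                                `[[`, 0, "peak_red"))),
            class = "laminar_session")
}

#' Construct a decoding dataset
#'
#' @param X trials x (3 * n_sites) feature matrix; columns ordered
#'   site-major as (site, band/bin) triplets.
#' @param y per-trial labels: 1 = edge, 0 = surface.
#' @param feature_kind `"gamma"` (per-site LG/MG/HG log power) or `"mua"`
#'   (per-site mean rate in three time bins).
#' @param site_ids site identifiers, length `ncol(X) / 3`.
#' @return Object of class `decode_dataset`.
#' @export
decode_dataset <- function(X, y, feature_kind = c("gamma", "mua"),
                           site_ids = NULL) {
  feature_kind <- match.arg(feature_kind)
  X <- as.matrix(X)
  stopifnot(ncol(X) %% 3 == 0, nrow(X) == length(y),
            all(y %in% c(0, 1)), !anyNA(X))
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(ncol(X) / 3))
  stopifnot(length(site_ids) == ncol(X) / 3)
  structure(list(X = X, y = as.integer(y), feature_kind = feature_kind,
                 site_ids = site_ids), class = "decode_dataset")
}

#' Simulate edge/surface decoding datasets
#'
#' Per-site, per-band log-gamma-power features drawn from class-dependent
#' Gaussians with the configured edge-surface mean differences (LG
#' positive, MG/HG negative), and matched MUA-rate features (three time
#' bins per site) with a smaller class difference. Classes are exactly
#' balanced.
#'
#' @param gt a [make_ground_truth()] object (uses
#'   `gt$edge_surface_effects`).
#' @param n_sites number of sites, >= 1.
#' @param n_trials total trials; must be even (half edge, half surface).
#' @param seed integer seed.
#' @return List with `gamma` and `mua` [decode_dataset()] objects sharing
#'   the same labels.
#' @export
simulate_edge_surface <- function(gt, n_sites = 1, n_trials = 400,
                                  seed = 1) {
  stopifnot(n_sites >= 1, n_trials %% 2 == 0)
  eff <- gt$edge_surface_effects
  y <- rep(c(1L, 0L), each = n_trials / 2)
  sgn <- ifelse(y == 1, 0.5, -0.5)
  .with_seed(seed, {
    xg <- matrix(0, n_trials, 3 * n_sites)
    xm <- matrix(0, n_trials, 3 * n_sites)
    for (j in seq_len(n_sites)) {
      for (b in 1:3) {
        dg <- eff$gamma_d[b] * eff$gamma_sd
        xg[, 3 * (j - 1) + b] <- eff$gamma_mean[b] + sgn * dg +
          stats::rnorm(n_trials, 0, eff$gamma_sd)
        dm <- eff$mua_d[b] * eff$mua_sd
        xm[, 3 * (j - 1) + b] <- eff$mua_mean + sgn * dm +
          stats::rnorm(n_trials, 0, eff$mua_sd)
      }
    }
    list(gamma = decode_dataset(xg, y, "gamma"),
         mua = decode_dataset(xm, y, "mua"))
  })
}
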