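# Laminar (relative-depth) alignment of linear-array channels, per-band
# depth power profiles, and the session-resampling bootstrap test.

#' Find the three laminar reference channels
#'
#' From per-channel MUA signal-to-noise ratios and SF selectivity:
#' * `cha1` — the channel with the lowest SF selectivity, taken to sit in
#'   the middle of the input layer (ties resolve to the shallower
#'   channel);
#' * `cha2` — the uppermost channel with SNR > 3 whose 3 consecutive
#'   deeper channels also have SNR > 3 (the cortical surface is placed
#'   0.050 mm above it);
#' * `cha3` — the deepest channel with SNR > 3 whose 3 consecutive
#'   shallower channels also have SNR > 3 (the gray/white-matter boundary
#'   is placed 0.050 mm below it).
#'
#' @param mua_snr per-channel SNR, ordered shallow to deep.
#' @param sf_selectivity per-channel SF selectivity, same order.
#' @param depth_mm per-channel physical depth, mm, strictly increasing.
#' @param snr_threshold SNR criterion (default 3, strict inequality).
#' @return List with `cha1`, `cha2`, `cha3` (channel indices),
#'   `surface_mm`, `cha1_mm`, `white_mm`.
#' @export
find_anchors <- function(mua_snr, sf_selectivity, depth_mm,
                         snr_threshold = 3) {
  n <- length(mua_snr)
  stopifnot(n >= 8, length(sf_selectivity) == n, length(depth_mm) == n,
            all(diff(depth_mm) > 0))
  ok <- mua_snr > snr_threshold
  run4_down <- vapply(seq_len(n - 3),
                      function(i) all(ok[i:(i + 3)]), logical(1))
  run4_up <- vapply(4:n, function(i) all(ok[(i - 3):i]), logical(1))
  if (!any(run4_down))
    stop("no channel satisfies the 4-consecutive-channel SNR rule")
  cha2 <- which(run4_down)[1]
  cha3 <- (4:n)[which(run4_up)[length(which(run4_up))]]
  cha1 <- which.min(sf_selectivity)  # which.min ties -> shallower
  if (cha1 <= cha2 || cha1 >= cha3)
    stop("input-layer channel (lowest selectivity, channel ", cha1,
         ") falls outside the span (", cha2, ", ", cha3,
         "); session rejected")
  list(cha1 = cha1, cha2 = cha2, cha3 = cha3,
       surface_mm = depth_mm[cha2] - 0.05,
       cha1_mm = depth_mm[cha1],
       white_mm = depth_mm[cha3] + 0.05)
}

#' Assign relative depth (ReD) to channels
#'
#' Piecewise-linear map of physical depth with three exact anchor values:
#' the surface reference maps to ReD 0, the input-layer channel to 0.5 and
#' the white-matter reference to 1; channels outside the span are clipped
#' and flagged. Interpolation is linear in physical depth on each of the
#' two segments.
#'
#' @param channel_depths physical depths, mm.
#' @param anchors list with `surface_mm`, `cha1_mm`, `white_mm`
#'   (as returned by [find_anchors()]).
#' @return List with `red` (per-channel ReD in `[0, 1]`) and `clipped`
#'   (logical, channels outside the anchor span).
#' @export
assign_red <- function(channel_depths, anchors) {
  s <- anchors$surface_mm
  m <- anchors$cha1_mm
  w <- anchors$white_mm
  if (!(s < m && m < w))
    stop("anchor depths must satisfy surface < input-layer < white matter")
  red <- ifelse(channel_depths <= m,
                0.5 * (channel_depths - s) / (m - s),
                0.5 + 0.5 * (channel_depths - m) / (w - m))
  clipped <- red < 0 | red > 1
  list(red = pmin(pmax(red, 0), 1), clipped = clipped)
}

#' Per-band laminar power profile
#'
#' Attaches per-channel band powers to relative-depth coordinates, using
#' anchors found from the session's MUA SNR and selectivity profiles.
#'
#' @param session a `laminar_session` (see [simulate_laminar_session()])
#'   or any list with a `channels` data frame holding `depth_mm`,
#'   `mua_snr`, `sf_selectivity` and per-band power columns.
#' @param bands band labels expected as power columns (default LG, MG,
#'   HG).
#' @return Object of class `laminar_profile`: data frame with `channel`,
#'   `depth_mm`, `red`, one power column per band; anchors kept as an
#'   attribute.
#' @export
band_power_profile <- function(session, bands = c("LG", "MG", "HG")) {
  ch <- session$channels
  stopifnot(all(c("depth_mm", "mua_snr", "sf_selectivity", bands) %in%
                  names(ch)))
  anchors <- find_anchors(ch$mua_snr, ch$sf_selectivity, ch$depth_mm)
  red <- assign_red(ch$depth_mm, anchors)
  out <- data.frame(channel = seq_len(nrow(ch)), depth_mm = ch$depth_mm,
                    red = red$red)
  out[bands] <- ch[bands]
  structure(out, class = c("laminar_profile", "data.frame"),
            anchors = anchors, session_id = session$session_id)
}

#' Relative depth of a band's power peak
#'
#' ReD of the channel with maximum band power. Ties resolve to the
#' shallower channel; a maximum on the first or last channel, or an
#' all-equal profile, is flagged.
#'
#' @param profile a [band_power_profile()] result.
#' @param band band label (column of `profile`).
#' @return List with `red`, `channel`, `boundary` (logical) and
#'   `degenerate` (logical, all powers equal).
#' @export
peak_red <- function(profile, band) {
  stopifnot(nrow(profile) >= 8, band %in% names(profile))
  p <- profile[[band]]
  degenerate <- diff(range(p)) == 0
  i <- which.max(p)  # ties -> shallower
  list(red = profile$red[i], channel = profile$channel[i],
       boundary = i == 1L || i == nrow(profile), degenerate = degenerate)
}

#' Session-resampling bootstrap for per-band peak depths
#'
#' Resamples sessions with replacement (resample size = number of
#' sessions), computes the mean peak ReD per band on each draw, and for
#' each ordered band pair reports the proportion of draws in which the
#' first band's mean exceeds the second's — a one-sided p-value against
#' the null that the first is no larger than the second. With exact ties
#' on every draw the strict inequality gives p = 0; this convention is
#' recorded in the output.
#'
#' @param peaks matrix or data frame, sessions x bands, of per-session
#'   peak ReD values.
#' @param n_boot number of bootstrap draws (default 10000).
#' @param seed integer seed.
#' @return List with `p` (named vector over ordered band pairs, e.g.
#'   `"LG>MG"`), `boot_means` (n_boot x bands), `n_boot`, and
#'   `tie_convention`.
#' @export
bootstrap_peak_locations <- function(peaks, n_boot = 10000, seed = 1) {
  peaks <- as.matrix(peaks)
  n <- nrow(peaks)
  stopifnot(n >= 2, n_boot >= 100)
  bands <- colnames(peaks)
  if (is.null(bands)) bands <- paste0("band", seq_len(ncol(peaks)))
  means <- .with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    t(apply(idx, 1, function(i) colMeans(peaks[i, , drop = FALSE])))
  })
  colnames(means) <- bands
  pairs <- utils::combn(seq_along(bands), 2)
  p <- c()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p[paste0(bands[a], ">", bands[b])] <- mean(means[, a] > means[, b])
    p[paste0(bands[b], ">", bands[a])] <- mean(means[, b] > means[, a])
  }
  list(p = p, boot_means = means, n_boot = n_boot,
       tie_convention = "strict > (ties count against the alternative)")
}
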