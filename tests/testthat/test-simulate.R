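test_that("ground-truth presets have the intended structure", {
  gt0 <- fx_gt("no_gamma")
  for (cp in gt0$model_params$components) {
    expect_equal(cp$A1, 0)
    expect_equal(cp$A2, 0)
  }
  expect_gt(eval_baseline(gt0$model_params$baseline, 50), 0)
  gt <- fx_gt()
  # LG peak frequency monotone non-increasing across the SF grid
  mu_lg <- eval_mu(gt$model_params$components$LG, gt$model_params$sf0,
                   gt$sfs)
  expect_true(all(diff(mu_lg) <= 0))
  expect_true(all(mu_lg >= 25 & mu_lg <= 45))
  mu_mg <- eval_mu(gt$model_params$components$MG, gt$model_params$sf0,
                   gt$sfs)
  mu_hg <- eval_mu(gt$model_params$components$HG, gt$model_params$sf0,
                   gt$sfs)
  expect_true(all(mu_mg >= 45 & mu_mg <= 65))
  expect_true(all(mu_hg >= 65 & mu_hg <= 100))
  # qualitative tuning: HG low-pass, LG prefers the highest SFs
  w <- sapply(gt$model_params$components, function(cp)
    eval_weight(cp, gt$sfs))
  expect_equal(which.max(w[, "HG"]), 1)
  expect_gt(which.max(w[, "LG"]), which.max(w[, "MG"]))
  # determinism
  expect_identical(fx_gt(), make_ground_truth("three_gamma_default",
                                              seed = 1))
  expect_error(make_ground_truth("nonesuch"))
})

test_that("simulated trials have the target spectrum", {
  # baseline-only: mean PSD within 10% of the closed-form baseline
  gt0 <- fx_gt("no_gamma")
  lfp <- t(sapply(1:500, function(i) simulate_lfp_trial(gt0, 0.3,
                                                        seed = i)))
  psd <- multitaper_psd(lfp, 500, onset = 0.4)
  sel <- psd$frequencies >= 20 & psd$frequencies <= 120
  target <- eval_baseline(gt0$model_params$baseline,
                          psd$frequencies[sel])
  expect_lt(max(abs(psd$power[sel] - target) / target), 0.1)
  # three-gamma: local maximum within 2 Hz of the LG peak frequency
  gt <- fx_gt()
  sf <- gt$sfs[6]
  mu <- eval_mu(gt$model_params$components$LG, gt$model_params$sf0, sf)
  lfp2 <- t(sapply(1:500, function(i) simulate_lfp_trial(gt, sf,
                                                         seed = 900 + i)))
  psd2 <- multitaper_psd(lfp2, 500, onset = 0.4)
  near <- abs(psd2$frequencies - mu) <= 6
  fpk <- psd2$frequencies[near][which.max(psd2$power[near])]
  expect_lt(abs(fpk - mu), 2)
  # determinism of a single trial
  expect_identical(simulate_lfp_trial(gt, sf, seed = 7),
                   simulate_lfp_trial(gt, sf, seed = 7))
})

test_that("spike simulation respects its locking contract", {
  gt <- fx_gt()
  lfp <- simulate_lfp_trial(gt, 0.3, seed = 1)
  s1 <- simulate_spikes(gt, lfp, "LG", 20, seed = 3, sf = 0.3)
  expect_identical(s1, simulate_spikes(gt, lfp, "LG", 20, seed = 3,
                                       sf = 0.3))
  expect_true(all(s1 >= 0 & s1 <= 2.8))
  gt_bad <- gt
  gt_bad$lock_targets["LG"] <- 1.4
  expect_error(simulate_spikes(gt_bad, lfp, "LG", 20, seed = 1),
               "\\[0, 1\\]")
})

test_that("laminar sessions are ordered, recoverable and deterministic", {
  gt <- fx_gt("laminar")
  s <- simulate_laminar_session(gt, n_channels = 24, spacing = 0.1,
                                seed = 2)
  expect_equal(nrow(s$channels), 24)
  expect_true(all(diff(s$channels$depth_mm) > 0))
  expect_identical(s, simulate_laminar_session(gt, n_channels = 24,
                                               spacing = 0.1, seed = 2))
  # noiseless recovery: profile peaks land on the nearest grid ReD
  s0 <- simulate_laminar_session(gt, n_channels = 24, spacing = 0.1,
                                 seed = 1, noise_sd = 0)
  prof <- band_power_profile(s0)
  for (b in c("LG", "MG", "HG")) {
    truth <- gt$laminar_profiles[[b]]$peak_red
    nearest <- prof$red[which.min(abs(prof$red - truth))]
    expect_equal(peak_red(prof, b)$red, nearest)
  }
  expect_error(
    simulate_laminar_session(fx_gt("laminar", 1), n_channels = 6),
    "n_channels")
})

test_that("edge/surface datasets are balanced with the set effect signs", {
  gt <- fx_gt("edge_surface")
  ds <- simulate_edge_surface(gt, n_sites = 2, n_trials = 400, seed = 4)
  expect_equal(sum(ds$gamma$y == 1), 200)
  expect_equal(sum(ds$gamma$y == 0), 200)
  expect_identical(ds$gamma$y, ds$mua$y)
  expect_equal(ncol(ds$gamma$X), 6)
  # LG mean higher on edge, MG/HG lower
  edge <- ds$gamma$y == 1
  expect_gt(mean(ds$gamma$X[edge, 1]), mean(ds$gamma$X[!edge, 1]))
  expect_lt(mean(ds$gamma$X[edge, 2]), mean(ds$gamma$X[!edge, 2]))
  expect_lt(mean(ds$gamma$X[edge, 3]), mean(ds$gamma$X[!edge, 3]))
  expect_identical(ds$gamma$X,
                   simulate_edge_surface(gt, 2, 400, seed = 4)$gamma$X)
  expect_error(simulate_edge_surface(gt, 1, 401, seed = 1))
})
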