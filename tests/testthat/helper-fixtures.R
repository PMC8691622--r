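# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_gt <- function(preset = "three_gamma_default", seed = 1, ...) {
  key <- paste(preset, seed, ..., sep = "_")
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_ground_truth(preset, seed = seed, ...)
  .fx[[key]]
}

# Trial-sampled spectrum grid at modest size, cached.
fx_noisy_grid <- function(n_trials = 30, seed = 42) {
  key <- paste("grid", n_trials, seed, sep = "_")
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_spectrum_grid(fx_gt(), n_trials = n_trials,
                                         seed = seed)
  .fx[[key]]
}

# Light fit control for tests that do many fits.
fx_fit_control <- function() {
  minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-10, ptol = 1e-10)
}

# Ground-truth tuning metrics of a component, from the true weight curve.
fx_truth_metrics <- function(gt, band) {
  sfs <- exp(seq(log(min(gt$sfs)), log(max(gt$sfs)), length.out = 50))
  w <- eval_weight(gt$model_params$components[[band]], sfs)
  tuning_metrics(tuning_curve(sfs, w, source = band))
}
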