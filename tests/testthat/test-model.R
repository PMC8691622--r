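test_that("baseline evaluates the ratio form and decreases with frequency", {
  p <- baseline_params(k = 1000, a = 2, b = 0, c = 1)
  expect_equal(eval_baseline(p, 10), 11)
  # floor-only case: zero scale leaves the additive constant
  expect_equal(eval_baseline(baseline_params(0, 1, 0, 5), 37), 5)
  for (seed in 1:20) {
    q <- withr::with_seed(seed, baseline_params(runif(1, 1, 500),
                                                runif(1, 0.2, 3),
                                                runif(1, 0, 10),
                                                runif(1, 0, 2)))
    expect_gt(eval_baseline(q, 20), eval_baseline(q, 120))
  }
  expect_error(eval_baseline(p, c(10, 0)))
})

test_that("peak-frequency sigmoid hits its anchor points", {
  comp <- component_params("LG", 3, K0 = 35, K = -10, n = 2, A1 = 1,
                           sigma1 = 0.5, A2 = 0, sigma2 = 0.1)
  expect_equal(eval_mu(comp, 0.3, 0), 35)
  expect_equal(eval_mu(comp, 0.3, 0.3), 35 - 5)  # half saturation
  expect_equal(eval_mu(comp, 0.3, 1000 * 0.3), 25, tolerance = 1e-3)
})

test_that("weight profile is a floored difference of Gaussians", {
  lp <- component_params("HG", 5, 72, 6, 2, A1 = 3, sigma1 = 0.25,
                         A2 = 1, sigma2 = 0.1)
  expect_equal(eval_weight(lp, 0), 3 - 1)
  # pure Gaussian: half maximum at sigma1 * sqrt(2 ln 2)
  pg <- component_params("HG", 5, 72, 6, 2, A1 = 2, sigma1 = 0.25,
                         A2 = 0, sigma2 = 0.1)
  expect_equal(eval_weight(pg, 0.25 * sqrt(2 * log(2))), 1)
  # band-pass DoG: dense-grid argmax strictly above zero SF
  bp <- component_params("LG", 3, 35, -10, 2, A1 = 10, sigma1 = 0.5,
                         A2 = 8, sigma2 = 0.1)
  g <- seq(0, 3, length.out = 20000)
  expect_gt(g[which.max(eval_weight(bp, g))], 0)
  # flooring: raw value can be negative, evaluated value never
  neg <- component_params("LG", 3, 35, -10, 2, A1 = 1, sigma1 = 0.1,
                          A2 = 2, sigma2 = 0.5)
  expect_true(any(eval_weight(neg, g, floor = FALSE) < 0))
  expect_true(all(eval_weight(neg, g) >= 0))
})

test_that("full model is baseline plus Gaussian bumps", {
  gt <- fx_gt()
  p <- gt$model_params
  f <- seq(20, 120, by = 1)
  # zero-amplitude model equals the baseline exactly
  p0 <- fx_gt("no_gamma")$model_params
  expect_equal(as.numeric(eval_model(p0, 0.5, f)),
               eval_baseline(p0$baseline, f))
  # at a component's peak frequency the model is baseline + weight
  lg <- p$components$LG
  sf <- 0.3
  mu <- eval_mu(lg, p$sf0, sf)
  one <- model_params(p$baseline, list(lg, p$components$MG,
                                       p$components$HG), p$sf0)
  w <- eval_weight(lg, sf)
  other <- sum(vapply(p$components[c("MG", "HG")], function(cp)
    eval_weight(cp, sf) *
      exp(-(mu - eval_mu(cp, p$sf0, sf))^2 / (2 * cp$sigma^2)),
    numeric(1)))
  expect_equal(as.numeric(eval_model(one, sf, mu)),
               eval_baseline(p$baseline, mu) + w + other)
  # model evaluation non-negative everywhere
  m <- eval_model(p, gt$sfs, f)
  expect_true(all(m >= 0))
})

test_that("goodness of fit matches its closed form", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(goodness_of_fit(c(1, 2, 3), rep(2, 3)), 0)
  # direct evaluation: SS_res = 1, SS_tot = 2
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_lte(goodness_of_fit(c(1, 2, 3), c(9, 9, 9)), 1)
})

test_that("component SNR divides max weight by mean blank band power", {
  gt <- fx_gt()
  f <- seq(20, 120, by = 0.5)
  blank <- rep(4, length(f))
  p <- gt$model_params
  # scale one component so its peak weight over the SF grid is exactly 12
  lg <- p$components$LG
  peak <- max(eval_weight(lg, gt$sfs))
  sc <- 12 / peak
  p2 <- model_params(p$baseline,
                     list(component_params("LG", lg$sigma, lg$K0, lg$K,
                                           lg$n, lg$A1 * sc, lg$sigma1,
                                           lg$A2 * sc, lg$sigma2),
                          p$components$MG, p$components$HG), p$sf0)
  snr <- component_snr(p2, blank, f, gt$sfs)
  expect_equal(unname(snr[["LG"]]), 3)
  # zero-amplitude components have zero SNR
  p0 <- fx_gt("no_gamma")$model_params
  expect_equal(unname(component_snr(p0, blank, f, gt$sfs)), c(0, 0, 0))
})

test_that("component counting uses a strict threshold and is monotone", {
  expect_equal(count_components(c(5, 4, 3.5)), 3)
  expect_equal(count_components(c(3, 3, 3)), 0)  # exactly 3 not counted
  expect_equal(count_components(c(10, 1, 0)), 1)
  for (seed in 1:20) {
    snrs <- withr::with_seed(seed, runif(3, 0, 8))
    counts <- vapply(c(0, 1, 2, 3, 4, 6), function(th)
      count_components(snrs, th), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("site SNR is an SD ratio with a degenerate guard", {
  set.seed(11)
  blank <- rnorm(50, 10, 1)
  stim <- rnorm(50, 10, 3 * sd(blank))
  r <- site_snr(stim, blank)
  expect_equal(r$snr, sd(stim) / sd(blank))
  # same-distribution null: ratio near 1
  r0 <- site_snr(rnorm(50, 5, 2), rnorm(50, 5, 2))
  expect_lt(abs(r0$snr - 1), 0.3)
  expect_false(r0$included)
  rd <- site_snr(rnorm(5), rep(1, 5))
  expect_true(rd$degenerate)
  expect_false(rd$included)
})
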