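test_that("anchor channels follow the stated SNR-run rules", {
  depth <- (0:7) * 0.1
  sel <- c(0.9, 0.8, 0.7, 0.3, 0.5, 0.6, 0.7, 0.9)
  a <- find_anchors(c(1, 1, 5, 6, 7, 8, 8, 2), sel, depth)
  expect_equal(a$cha2, 3)
  expect_equal(a$cha3, 7)
  expect_equal(a$surface_mm, depth[3] - 0.05)
  expect_equal(a$white_mm, depth[7] + 0.05)
  # all channels driven: first and last
  sel2 <- c(0.9, 0.8, 0.7, 0.3, 0.5, 0.6, 0.7, 0.95)
  a2 <- find_anchors(rep(5, 8), sel2, depth)
  expect_equal(a2$cha2, 1)
  expect_equal(a2$cha3, 8)
  # selectivity ties resolve to the shallower channel
  a3 <- find_anchors(rep(5, 8), c(1, 1, 0.2, 0.2, 0.2, 1, 1, 1), depth)
  expect_equal(a3$cha1, 3)
  # no qualifying run
  expect_error(find_anchors(c(1, 5, 5, 1, 5, 5, 1, 5),
                            sel, depth), "4-consecutive")
  # lowest-selectivity channel outside the driven span
  expect_error(find_anchors(c(1, 1, 5, 6, 7, 8, 8, 2),
                            c(0.1, rep(0.9, 7)), depth), "rejected")
})

test_that("find_anchors matches a brute-force scan on random vectors", {
  brute <- function(snr) {
    n <- length(snr)
    ok <- snr > 3
    c2 <- c3 <- NA
    for (i in 1:(n - 3)) if (all(ok[i:(i + 3)])) { c2 <- i; break }
    for (i in n:4) if (all(ok[(i - 3):i])) { c3 <- i; break }
    c(c2, c3)
  }
  set.seed(101)
  for (r in 1:300) {
    n <- sample(8:24, 1)
    snr <- runif(n, 0, 8)
    sel <- runif(n)
    depth <- (seq_len(n) - 1) * 0.1
    b <- brute(snr)
    got <- tryCatch(find_anchors(snr, sel, depth),
                    error = function(e) "rejected")
    if (is.na(b[1])) {
      expect_identical(got, "rejected")
    } else if (identical(got, "rejected")) {
      c1 <- which.min(sel)
      expect_true(c1 <= b[1] || c1 >= b[2])
    } else {
      expect_equal(got$cha2, b[1])
      expect_equal(got$cha3, b[2])
      expect_equal(got$cha1, which.min(sel))
    }
  }
  # appending sub-threshold channels above/below leaves anchors fixed
  snr <- c(1, 1, 5, 6, 7, 8, 8, 2)
  sel <- c(0.9, 0.8, 0.7, 0.3, 0.5, 0.6, 0.7, 0.9)
  a <- find_anchors(snr, sel, (0:7) * 0.1)
  snr2 <- c(2, snr, 1, 1)
  sel2 <- c(0.95, sel, 0.95, 0.99)
  a2 <- find_anchors(snr2, sel2, (0:10) * 0.1 - 0.1)
  expect_equal(a2$cha2, a$cha2 + 1)
  expect_equal(a2$surface_mm, a$surface_mm)
  expect_equal(a2$white_mm, a$white_mm)
})

test_that("relative depth honors the three anchors exactly", {
  anchors <- list(surface_mm = 0.05, cha1_mm = 1.1, white_mm = 2.25)
  r <- assign_red(c(0.05, 1.1, 2.25), anchors)
  expect_equal(r$red, c(0, 0.5, 1))
  # midway between surface and input layer: 0.25, by linear interpolation
  expect_equal(assign_red((0.05 + 1.1) / 2, anchors)$red, 0.25)
  # channels outside the span are clipped and flagged
  rc <- assign_red(c(-0.2, 2.5), anchors)
  expect_equal(rc$red, c(0, 1))
  expect_true(all(rc$clipped))
  expect_error(assign_red(1, list(surface_mm = 2, cha1_mm = 1,
                                  white_mm = 3)), "anchor depths")
  # affine on each segment
  d <- seq(0.05, 1.1, length.out = 7)
  red <- assign_red(d, anchors)$red
  expect_equal(red, seq(0, 0.5, length.out = 7), tolerance = 1e-12)
})

test_that("peak localization breaks ties shallow and flags boundaries", {
  gt <- fx_gt("laminar")
  s <- simulate_laminar_session(gt, 24, 0.1, seed = 3, noise_sd = 0)
  prof <- band_power_profile(s)
  p <- peak_red(prof, "LG")
  expect_false(p$degenerate)
  # tie: duplicate the maximum deeper; shallower one must win
  prof2 <- prof
  i <- which.max(prof2$LG)
  prof2$LG[i + 5] <- prof2$LG[i]
  expect_equal(peak_red(prof2, "LG")$channel, i)
  # monotone profile peaks at a boundary channel
  prof3 <- prof
  prof3$MG <- seq(2, 1, length.out = nrow(prof3))
  pb <- peak_red(prof3, "MG")
  expect_true(pb$boundary)
  expect_equal(pb$channel, 1)
  # additive offset leaves the argmax unchanged
  prof4 <- prof
  prof4$HG <- prof4$HG + 3
  expect_equal(peak_red(prof4, "HG")$channel,
               peak_red(prof, "HG")$channel)
})

test_that("session bootstrap separates distinct depths and is seeded", {
  set.seed(12)
  peaks <- cbind(LG = rnorm(12, 0.2, 0.05), MG = rnorm(12, 0.4, 0.05),
                 HG = rnorm(12, 0.5, 0.05))
  bp <- bootstrap_peak_locations(peaks, n_boot = 2000, seed = 7)
  expect_true(all(bp$p >= 0 & bp$p <= 1))
  expect_lt(bp$p[["LG>MG"]], 0.01)
  expect_lt(bp$p[["MG>HG"]], 0.05)
  expect_gt(bp$p[["HG>LG"]], 0.99)
  bp2 <- bootstrap_peak_locations(peaks, n_boot = 2000, seed = 7)
  expect_identical(bp$p, bp2$p)
  # exact ties give p = 0 under the strict inequality
  tied <- cbind(A = rep(0.3, 5), B = rep(0.3, 5))
  expect_equal(unname(bootstrap_peak_locations(tied, 200, 1)$p[["A>B"]]),
               0)
})
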