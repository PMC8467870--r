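test_that("DPSS tapers are unit-energy, orthogonal and ordered by nodes", {
  tb <- default_tapers()
  expect_equal(dim(tb$h), c(400L, 8L))
  expect_equal(colSums(tb$h^2), rep(1, 8), tolerance = 1e-10)
  xp <- crossprod(tb$h) - diag(8)
  expect_lt(max(abs(xp)), 1e-8)
  # classical Slepian property: taper i has exactly i sign changes
  nodes <- vapply(1:8, function(i) sum(diff(sign(tb$h[, i])) != 0),
                  numeric(1))
  expect_equal(nodes, 0:7)
  expect_true(all(tb$eigenvalues > 0.9 & tb$eigenvalues <= 1 + 1e-12))
  expect_warning(compute_dpss(64L, 12L, 2), "concentrated")
  expect_error(compute_dpss(8L, 10L, 2))
})

test_that("DPSS tapers match an independent implementation", {
  # reference values from scipy.signal.windows.dpss(400, 4.5, 8, norm=2)
  tb <- default_tapers()
  expect_equal(tb$h[c(1, 100, 200), 1],
               c(1.22101350e-06, 1.68335415e-02, 1.02251630e-01),
               tolerance = 1e-6)
  expect_equal(tb$h[c(1, 100, 200), 8],
               c(0.05508521, -0.01876374, -0.00150111), tolerance = 1e-6)
  expect_equal(sum(abs(tb$h[, 1])), 13.6352548, tolerance = 1e-6)
})

test_that("framing yields 29 half-overlapping 2-s frames", {
  x <- seq_len(6000)
  fr <- frame_segment(x)
  expect_equal(dim(fr), c(400L, 29L))
  expect_equal(fr[, 1], 1:400)
  expect_equal(fr[, 29], 5601:6000)
  # 50% overlap: frame m starts at 200 (m - 1)
  expect_equal(fr[1, ], 200 * (0:28) + 1)
  expect_true(all(seq_len(6000) %in% as.vector(fr)))
  expect_error(frame_segment(seq_len(5999)), "frame")
})

test_that("multitaper PSD averages tapered periodograms and conserves power", {
  tb <- default_tapers()
  expect_equal(multitaper_psd(numeric(400), tb), rep(0, 201))
  # oracle: mean of the 8 single-taper one-sided periodograms
  set.seed(1)
  x <- rnorm(400)
  per <- sapply(1:8, function(i) {
    X <- fft(x * tb$h[, i])
    p <- Mod(X[1:201])^2 / 400
    p * c(1, rep(2, 199), 1)
  })
  expect_equal(multitaper_psd(x, tb), rowMeans(per), tolerance = 1e-12)
  # Parseval: unit-variance white noise, power approximately 1
  set.seed(2)
  expect_equal(sum(multitaper_psd(rnorm(400), tb)), 1, tolerance = 0.1)
  tot <- mean(replicate(200, sum(multitaper_psd(rnorm(400), tb))))
  expect_equal(tot, 1, tolerance = 0.01)
  # a 10 Hz tone lands in bin 21 (k = 20, 0.5 Hz spacing)
  tone <- sin(2 * pi * 10 * (0:399) / 200)
  expect_equal(which.max(multitaper_psd(tone, tb)), 21L)
  expect_equal(which.max(multitaper_psd(sin(2 * pi * 7 * (0:399) / 200), tb)),
               15L)
  expect_error(multitaper_psd(numeric(399), tb), "length")
})

test_that("multitaper averaging reduces periodogram variance about 8-fold", {
  tb <- default_tapers()
  tb1 <- compute_dpss(400L, 1L, 4.5)
  set.seed(3)
  bin <- 50
  v8 <- var(replicate(300, multitaper_psd(rnorm(400), tb)[bin]))
  v1 <- var(replicate(300, multitaper_psd(rnorm(400), tb1)[bin]))
  expect_lt(v8 / v1, 0.3)  # expected ratio about 1/8
})

test_that("band powers integrate the documented bin ranges", {
  bb <- band_bins()
  expect_equal(bb$lo_bin, c(1L, 10L, 18L, 30L, 1L))
  expect_equal(bb$hi_bin, c(9L, 17L, 25L, 61L, 81L))
  # constant PSD: composite Simpson (with 3/8 correction) is exact
  for (i in seq_len(nrow(bb))) {
    width <- (bb$hi_bin[i] - bb$lo_bin[i]) * 0.5
    expect_equal(band_power(rep(2, 201), bb$band[i]), 2 * width,
                 tolerance = 1e-9)
  }
  # an impulse outside the band contributes nothing
  psd <- rep(0, 201); psd[28] <- 5  # 13.5 Hz: between alpha and beta
  expect_equal(band_power(psd, "alpha"), 0)
  expect_equal(band_power(psd, "beta"), 0)
  expect_gt(band_power(psd, "full"), 0)
  expect_error(band_power(rep(1, 201), "sigma"), "unknown band")
  # alpha tone: alpha power dominates the full band.  The taper bank's
  # resolution bandwidth is NW/N x fs = 2.25 Hz, so a 10 Hz tone smears
  # a little past the 8.5 Hz alpha edge; most but not all power is in band
  tone <- sin(2 * pi * 10 * (0:5999) / 200)
  bm <- band_matrix(tone)
  expect_gt(mean(bm[, "alpha"] / bm[, "full"]), 0.75)
  expect_true(all(bm[, "alpha"] > bm[, "delta"] + bm[, "beta"]))
})

test_that("the band matrix is 29 x 8 with quadratic power scaling", {
  set.seed(4)
  x <- rnorm(6000)
  bm <- band_matrix(x)
  expect_equal(dim(bm), c(29L, 8L))
  expect_equal(colnames(bm), band_feature_names())
  expect_true(all(bm >= 0))
  bm2 <- band_matrix(2 * x)
  expect_equal(bm2[, 1:5], 4 * bm[, 1:5], tolerance = 1e-9)
  expect_equal(bm2[, 6:8], bm[, 6:8], tolerance = 1e-9)
  # zero segment: zero powers, 0/0 ratios resolve to 0
  bm0 <- band_matrix(numeric(6000))
  expect_true(all(bm0 == 0))
  # full-band power bounds each sub-band power
  expect_true(all(bm[, "full"] >= bm[, "delta"]))
  expect_true(all(bm[, "full"] >= bm[, "beta"]))
})
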