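test_that("low-pass design honors the printed order and edges", {
  filt <- design_filter(filter_spec(), fs = 200)
  expect_length(filt$b, 128L)  # order 127 FIR
  H <- filter_response(filt, c(0, 60))
  expect_equal(Mod(H[1]), 1, tolerance = 0.01)       # DC gain 0 dB
  expect_lte(20 * log10(Mod(H[2])), -30)             # mains strongly cut
  # passband essentially flat, stopband uniformly attenuated
  Hp <- Mod(filter_response(filt, seq(1, 38, by = 1)))
  expect_true(all(abs(Hp - 1) < 0.05))
  Hs <- Mod(filter_response(filt, seq(50, 99, by = 1)))
  expect_true(all(20 * log10(Hs) < -30))
  expect_error(design_filter(filter_spec(stopband_edge = 120), fs = 200),
               "Nyquist")
  expect_error(filter_spec(passband_edge = 42, stopband_edge = 40))
})

test_that("filtering removes mains, passes EEG bands, and is linear", {
  filt <- design_filter(filter_spec(), fs = 200)
  tt <- (0:119999) / 200
  x60 <- sin(2 * pi * 60 * tt)
  x10 <- sin(2 * pi * 10 * tt)
  rms <- function(v) sqrt(mean(v^2))
  expect_lte(rms(apply_filter(x60, filt)) / rms(x60), 0.05)
  expect_equal(rms(apply_filter(x10, filt)) / rms(x10), 1, tolerance = 0.05)
  expect_equal(apply_filter(numeric(1000), filt), numeric(1000))
  # linearity: filter(a x + b y) = a filter(x) + b filter(y)
  set.seed(5)
  xa <- rnorm(5000); xb <- rnorm(5000)
  lhs <- apply_filter(2.5 * xa - 1.3 * xb, filt)
  rhs <- 2.5 * apply_filter(xa, filt) - 1.3 * apply_filter(xb, filt)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # records keep labels and length
  rec <- eeg_record(rnorm(4000), c(rep(0L, 2000), rep(1L, 2000)))
  out <- apply_filter(rec, filt)
  expect_length(out$samples, 4000)
  expect_identical(out$labels, rec$labels)
  expect_error(apply_filter(eeg_record(numeric(0)), filt), "empty")
})

test_that("group-delay compensation keeps the filtered signal aligned", {
  filt <- design_filter(filter_spec(), fs = 200)
  tt <- (0:19999) / 200
  x <- sin(2 * pi * 5 * tt)
  y <- apply_filter(x, filt)
  mid <- 2000:18000
  # the rounded 64-sample shift leaves a residual half-sample delay,
  # i.e. at most sin(2 pi f / (2 fs)) ~ 0.079 amplitude deviation at 5 Hz
  expect_lt(max(abs(y[mid] - x[mid])), 0.1)
  expect_gt(cor(y[mid], x[mid]), 0.995)
})

test_that("segmentation discards edges and partial windows", {
  rec6h <- eeg_record(numeric(6 * 3600 * 200))
  expect_length(segment_record(rec6h), 480)
  rec2h <- eeg_record(numeric(2 * 3600 * 200))
  expect_length(segment_record(rec2h), 0)
  rec4h10 <- eeg_record(numeric((4 * 3600 + 10) * 200))
  expect_length(segment_record(rec4h10), 240)  # 10-s remainder dropped
  # partition: consecutive disjoint 30-s windows starting at hour one
  segs <- segment_record(eeg_record(numeric(2.5 * 3600 * 200)))
  offs <- vapply(segs, function(s) s$start_offset, numeric(1))
  expect_equal(offs, 3600 + 30 * (seq_along(segs) - 1))
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) ==
                    6000L))
})

test_that("segment labeling needs a contiguous 3-s arousal run", {
  expect_identical(label_segment(integer(6000)), 0L)
  expect_identical(label_segment(rep(1L, 6000)), 1L)
  lab500 <- integer(6000); lab500[1001:1500] <- 1L  # 2.5 s
  expect_identical(label_segment(lab500), 0L)
  lab600 <- integer(6000); lab600[1001:1600] <- 1L  # 3.0 s
  expect_identical(label_segment(lab600), 1L)
  # two short runs do not add up
  lab2x <- integer(6000); lab2x[1:400] <- 1L; lab2x[801:1200] <- 1L
  expect_identical(label_segment(lab2x), 0L)
  expect_error(label_segment(integer(100)), "6000")
})

test_that("segment labels agree with a brute-force recount", {
  set.seed(42)
  n <- 40 * 30 * 200
  labels <- integer(n)
  starts <- sort(sample.int(n - 4000, 25))
  for (s in starts) labels[s:(s + sample(200:3000, 1))] <- 1L
  rec <- eeg_record(rnorm(n), pmin(labels[1:n], 1L))
  segs <- segment_record(rec, discard_edges = 0)
  for (sg in segs) {
    r <- rle(sg$sample_labels)
    longest <- if (any(r$values == 1)) max(r$lengths[r$values == 1]) else 0
    expect_identical(sg$label, as.integer(longest >= 600))
  }
})

test_that("the IIR realization also suppresses mains", {
  filt <- design_filter(filter_spec(realization = "iir"), fs = 200)
  tt <- (0:39999) / 200
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(apply_filter(sin(2 * pi * 60 * tt), filt)), 0.1)
  expect_equal(rms(apply_filter(sin(2 * pi * 10 * tt), filt)), sqrt(0.5),
               tolerance = 0.05)
})
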