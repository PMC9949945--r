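test_that("hz_to_mel follows the stated map and inverts cleanly", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_equal(hz_to_mel(2450), 2595 * log10(2450 / 700 + 1))
  expect_error(hz_to_mel(-1), "nonnegative")

  f <- seq(0, 2500, by = 10)
  m <- hz_to_mel(f)
  expect_true(all(diff(m) > 0))                      # strictly monotone
  expect_equal(mel_to_hz(m), f, tolerance = 1e-6)
})

test_that("mel filterbank geometry", {
  fb <- mel_filterbank(40, 8192, 5000, 50, 2450)
  expect_equal(dim(fb), c(40, 4097))
  centers <- attr(fb, "centers_hz")
  expect_equal(diff(hz_to_mel(centers)),
               rep(diff(hz_to_mel(centers))[1], 39), tolerance = 1e-6)
  expect_true(all(fb >= 0))
  bin_hz <- (0:4096) * 5000 / 8192
  inside <- bin_hz > 55 & bin_hz < 2445
  expect_true(all(colSums(fb)[inside] > 0))          # coverage
  # peak at the bin nearest each center
  peak_bin <- apply(fb, 1, which.max)
  nearest <- vapply(centers, function(c) which.min(abs(bin_hz - c)), integer(1))
  expect_equal(peak_bin, nearest)
  expect_error(mel_filterbank(40, 8192, 5000, 2450, 50), "infeasible")
})

test_that("mel_spectrogram frame count and silent-clip floor", {
  cl <- as_clip(rnorm(60 * 5000) * 0.1, 5000)
  lm <- mel_spectrogram(cl)
  expect_equal(dim(lm), c(40, 119))                  # floor((60-1)/0.5)+1
  expect_equal(attr(lm, "frame_times")[1:3], c(0, 0.5, 1.0))

  z <- mel_spectrogram(as_clip(rep(0, 60 * 5000), 5000))
  expect_true(all(z == log(1e-10)))
})

test_that("mfcc of a silent clip is the DCT of a constant", {
  m <- mfcc(as_clip(rep(0, 60 * 5000), 5000))
  expect_equal(dim(m), c(13, 119))
  expect_equal(unique(round(m[1, ], 9)), sqrt(40) * log(1e-10))
  expect_true(all(abs(m[-1, ]) < 1e-9))
})

test_that("mfcc is deterministic and separates spectral classes", {
  set.seed(11)
  cl <- as_clip(rnorm(60 * 5000) * 0.05, 5000)
  expect_identical(mfcc(cl), mfcc(cl))

  set.seed(12); w1 <- clip_feature(mfcc(as_clip(rnorm(3e5) * 0.05, 5000)))
  set.seed(13); w2 <- clip_feature(mfcc(as_clip(rnorm(3e5) * 0.05, 5000)))
  set.seed(14)
  t <- (0:(3e5 - 1)) / 5000
  harm <- 0.05 * (sin(2 * pi * 150 * t) + 0.5 * sin(2 * pi * 300 * t)) *
    (0.5 + 0.5 * sign(sin(2 * pi * t / 4)))          # gated harmonic bursts
  h <- clip_feature(mfcc(as_clip(harm + 1e-3 * rnorm(3e5), 5000)))
  expect_gt(euclidean_distance(w1, h), euclidean_distance(w1, w2))
})

test_that("clip_feature averages rows", {
  m <- matrix(rep(c(1, 5, -2), 4), nrow = 3)
  expect_equal(clip_feature(m), c(1, 5, -2))
  expect_equal(clip_feature(matrix(c(0, 2, 2, 0), 2)), c(1, 1))
  set.seed(3)
  M <- matrix(rnorm(13 * 119), 13)
  brute <- vapply(1:13, function(i) sum(M[i, ]) / 119, numeric(1))
  expect_equal(clip_feature(M), brute)
  expect_error(clip_feature(matrix(nrow = 3, ncol = 0)), "frame")
})

test_that("euclidean distance matches the coordinate-wise definition", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(4)
  p <- rnorm(13); q <- rnorm(13)
  brute <- 0
  for (i in 1:13) brute <- brute + (p[i] - q[i])^2
  expect_equal(euclidean_distance(p, q), sqrt(brute))
  expect_error(euclidean_distance(1:3, 1:4), "mismatch")
})

test_that("distance matrix satisfies the metric axioms", {
  set.seed(5)
  feats <- lapply(1:20, function(i) rnorm(13))
  d <- distance_matrix(feats)
  expect_equal(dim(d), c(20, 20))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
  # spot-check against the scalar op
  expect_equal(d[3, 7], euclidean_distance(feats[[3]], feats[[7]]))

  expect_equal(max(abs(distance_matrix(list(c(1, 2), c(1, 2), c(1, 2))))), 0)
  expect_error(distance_matrix(list(c(1, 2))), "at least 2")
})
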