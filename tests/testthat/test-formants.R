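test_that("LPC recovers AR(2) coefficients and whitens noise", {
  set.seed(31)
  r <- 0.95; th <- 2 * pi * 500 / 5000
  a_true <- c(1, -2 * r * cos(th), r^2)
  x <- as.numeric(stats::filter(rnorm(4096), -a_true[2:3], method = "recursive"))
  fit <- lpc_coefficients(x, 2)
  expect_equal(fit$a[2:3], a_true[2:3], tolerance = 0.05)

  for (s in 1:5) {
    set.seed(s)
    w <- lpc_coefficients(rnorm(4096), 14)
    expect_true(all(abs(w$a[-1]) < 0.2))
  }
  expect_error(lpc_coefficients(rnorm(10), 14), "longer than")
  expect_null(lpc_coefficients(rep(0, 100), 14))     # unvoiced flag
})

test_that("Levinson-Durbin equals the direct Yule-Walker solve", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(256)
    p <- sample(2:14, 1)
    fit <- lpc_coefficients(x, p)
    n <- length(x)
    rv <- vapply(0:p, function(k) sum(x[1:(n - k)] * x[(k + 1):n]) / n,
                 numeric(1))
    direct <- solve(toeplitz(rv[1:p]), -rv[2:(p + 1)])
    expect_equal(fit$a[-1], direct, tolerance = 1e-8)
    expect_true(all(diff(fit$err) <= 1e-12))         # residual non-increasing
  }
})

test_that("vectorized Levinson agrees with the scalar recursion", {
  set.seed(32)
  X <- matrix(rnorm(100 * 8), 100)
  r <- t(sapply(0:14, function(k)
    colSums(X[1:(100 - k), ] * X[(k + 1):100, ]) / 100))
  A <- snorevol:::levinson_frames(r, 14)
  for (j in 1:8)
    expect_equal(A[, j], lpc_coefficients(X[, j], 14)$a, tolerance = 1e-10)
})

test_that("formants_from_lpc finds constructed resonances", {
  f1 <- formants_from_lpc(resonator_poly(400, 5000), 5000)
  expect_equal(unname(f1["F1"]), 400, tolerance = 30 / 400)
  f2 <- formants_from_lpc(resonator_poly(c(400, 1200), 5000), 5000)
  expect_lt(abs(f2["F1"] - 400), 30)
  expect_lt(abs(f2["F2"] - 1200), 30)
  # all-real roots: no complex pole pair, no formants
  none <- formants_from_lpc(c(1, -0.8, 0.15), 5000)  # roots 0.5, 0.3
  expect_true(all(is.na(none)))
  expect_true(all(is.na(formants_from_lpc(NULL, 5000))))
})

test_that("episode detector finds bursts, silence, and continuous tone", {
  onsets <- seq(2, 56, by = 6)
  ep <- detect_snore_episodes(burst_clip(onsets, 1.0, seed = 33))
  expect_equal(nrow(ep), length(onsets))
  expect_true(all(abs(ep$onset_s - onsets) <= 0.2))

  expect_equal(nrow(detect_snore_episodes(as_clip(rep(0, 3e5), 5000))), 0)

  tone <- as_clip(0.2 * sin(2 * pi * 400 * (0:(3e5 - 1)) / 5000), 5000)
  ept <- detect_snore_episodes(tone)
  expect_equal(nrow(ept), 1)
  expect_equal(ept$onset_s, 0)
  expect_equal(ept$offset_s, 60)
})

test_that("snore_features implements the population-sd definition", {
  ep <- data.frame(onset_s = c(0, 4, 8), offset_s = c(1, 5, 9),
                   f1_hz = c(400, 400, 400))
  sf <- snore_features(ep)
  expect_equal(sf$std_f1_hz, 0)
  expect_equal(sf$std_f1_interval_s, 0)
  expect_false(sf$low_evidence)

  few <- snore_features(ep[1:2, ])
  expect_true(few$low_evidence)
  expect_equal(few$std_f1_hz, 0)

  ep2 <- data.frame(onset_s = c(0, 4, 12), offset_s = c(1, 5, 13),
                    f1_hz = c(450, 450, 450))
  sf2 <- snore_features(ep2)
  expect_equal(sf2$std_f1_hz, 0)
  expect_equal(sf2$std_f1_interval_s, 2.0)           # pop sd of {4, 8}
})

test_that("K-means typing separates the two snore regimes", {
  set.seed(34)
  blob <- function(n, f, i, sf, si)
    data.frame(std_f1_hz = rnorm(n, f, sf), std_f1_interval_s = rnorm(n, i, si))
  feats <- rbind(blob(10, 20, 0.3, 5, 0.05), blob(10, 120, 4, 10, 0.5))
  lab <- classify_snore_type(feats)
  expect_equal(lab, rep(c("simple", "apneic"), each = 10))
  # invariant to input order
  perm <- sample(20)
  expect_equal(classify_snore_type(feats[perm, ]), lab[perm])
  # degenerate paths
  same <- data.frame(std_f1_hz = rep(10, 5), std_f1_interval_s = rep(1, 5))
  expect_equal(classify_snore_type(same), rep("simple", 5))
  expect_warning(one <- classify_snore_type(feats[1, , drop = FALSE]),
                 "fewer than 2")
  expect_equal(one, "simple")
})

test_that("the F1-threshold baseline applies the literature cutoff", {
  expect_equal(classify_snore_type_f1(c(400, 500, 470, NA)),
               c("simple", "apneic", "simple", "simple"))
})
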