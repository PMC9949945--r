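test_that("generators are deterministic under seed", {
  expect_identical(gen_normal_minute(5)$samples, gen_normal_minute(5)$samples)
  expect_identical(gen_simple_snore_minute(5)$samples,
                   gen_simple_snore_minute(5)$samples)
  expect_identical(gen_apneic_snore_minute(5, pause_s = 12)$samples,
                   gen_apneic_snore_minute(5, pause_s = 12)$samples)
  expect_identical(gen_uncertain_minute(5)$samples,
                   gen_uncertain_minute(5)$samples)
  expect_false(identical(gen_normal_minute(5)$samples,
                         gen_normal_minute(6)$samples))
})

test_that("normal minutes look like 3-6 s period broadband breathing", {
  for (s in 1:5) {
    cl <- gen_normal_minute(s)
    n_ev <- nrow(detect_breath_events(cl))
    expect_gte(n_ev, 10); expect_lte(n_ev, 20)
  }
  cl <- gen_normal_minute(1)
  P <- Mod(fft(cl$samples))^2
  f <- (seq_along(P) - 1) * cl$rate / length(P)
  half <- f <= cl$rate / 2
  tot <- sum(P[half])
  for (lo in seq(0, 2450, by = 50)) {
    band <- half & f >= lo & f < lo + 50
    expect_lt(sum(P[band]) / tot, 0.30)              # no dominant narrow band
  }
})

test_that("simple-snore minutes carry the stated F1 and regular spacing", {
  ep <- detect_snore_episodes(gen_simple_snore_minute(3, f1_jitter_hz = 0))
  expect_gte(nrow(ep), 13); expect_lte(nrow(ep), 16)
  expect_true(all(abs(ep$f1_hz - 400) <= 30))
  sf0 <- snore_features(detect_snore_episodes(
    gen_simple_snore_minute(4, interval_jitter_s = 0)))
  expect_lt(sf0$std_f1_interval_s, 0.1)
  sf <- snore_features(detect_snore_episodes(gen_simple_snore_minute(5)))
  expect_equal(sf$std_f1_interval_s, 0.2, tolerance = 0.6)
})

test_that("apneic minutes recover the inserted pause through MBPI", {
  cl <- gen_apneic_snore_minute(6, pause_s = 12)
  m <- mbpi(detect_breath_events(cl))
  expect_gte(m, 11); expect_lte(m, 13)
  lv <- function(p, s) {
    c <- gen_apneic_snore_minute(s, pause_s = p)
    tidal_level("snoring", "apneic",
                mbpi_s = mbpi(detect_breath_events(c)))
  }
  expect_equal(lv(5, 7), "medium")
  expect_equal(lv(12, 8), "low")
})

test_that("uncertain minutes are ~1% of normal loudness", {
  cu <- gen_uncertain_minute(9)
  cn <- gen_normal_minute(9)
  expect_lt(rms(cu$samples), 0.01 * rms(cn$samples))
  ep <- detect_snore_episodes(cu)
  sf <- snore_features(ep)
  expect_true(sf$low_evidence || nrow(ep) == 0)
})

test_that("gen_spo2 places per-minute minima inside the stated bands", {
  all_norm <- scenario_plan(rep("normal", 5))
  tr <- gen_spo2(all_norm)
  expect_true(all(tr$values == 97))

  plan <- scenario_plan(
    c("normal", "apneic_snoring", "apneic_snoring",
      rep("simple_snoring", 5), "uncertain"),
    pause_s = c(NA, 12, 6, rep(NA, 6)))
  tr2 <- gen_spo2(plan)
  mins <- sapply(0:8, function(m) loo2(tr2, m * 60, (m + 1) * 60))
  expect_equal(loo2_level(mins[2]), "low")           # pause > 10 s
  expect_equal(loo2_level(mins[3]), "medium")        # pause <= 10 s
  expect_equal(loo2_level(mins[4:6]), rep("high", 3))  # SS positions 1-3
  expect_equal(loo2_level(mins[7:8]), rep("medium", 2))  # SS positions 4-5
  expect_equal(mins[9], 97)                          # uncertain at baseline

  # generator consistency: a perfect predictor scores accuracy 1
  truth <- snorevol:::plan_truth(plan)
  refs <- loo2_level(mins[truth$level != "uncertain"])
  expect_equal(accuracy(truth$level[truth$level != "uncertain"], refs), 1)
})

test_that("scenario assembly is coherent and byte-reproducible", {
  plan <- scenario_plan(c("normal", "simple_snoring", "apneic_snoring",
                          "uncertain"), pause_s = c(NA, NA, 15, NA),
                        seed = 11)
  sc <- gen_scenario(plan)
  expect_equal(length(sc$audio$samples), 4 * 60 * 5000)
  expect_equal(length(sc$spo2$values), 4 * 60)
  expect_equal(nrow(sc$truth), 4)
  expect_equal(sc$truth$level, c("high", "high", "low", "uncertain"))
  expect_length(segment(sc$audio), 4)

  f1 <- withr::local_tempfile(fileext = ".wav")
  f2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(gen_scenario(plan)$audio, f1)
  write_wav(gen_scenario(plan)$audio, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("plan validation", {
  expect_error(scenario_plan(c("normal", "loud")), "labels must be")
  expect_error(scenario_plan("apneic_snoring"), "pause_s")
  expect_error(scenario_plan("apneic_snoring", pause_s = 75), "pause_s")
  p <- random_plan(3, 4, 3, 2, seed = 1)
  expect_equal(table(p$labels)[["normal"]], 3)
  expect_equal(table(p$labels)[["apneic_snoring"]], 3)
  expect_true(all(is.finite(p$pause_s[p$labels == "apneic_snoring"])))
})
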