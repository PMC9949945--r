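# Synthetic tracheal-sound scenarios with consistent SpO2 traces.
#
# The generator states a world and the rest of the package is tested
# against it: normal breathing is broadband noise bursts with a 3-6 s
# period; simple snoring is a regular train of harmonic bursts resonating
# near F1 = 400 Hz; apneic snoring is an irregular train near 600 Hz with
# one inserted silent pause; uncertain minutes are near-silent noise.
# Amplitudes are fixed once at realistic relative levels (snore bursts are
# the loudest events, breathing is moderate, uncertain is ~1% of normal).

.syn <- list(
  snore_burst_rms = 0.18,   # within-burst RMS of snore events
  breath_rms      = 0.05,   # inspiratory burst RMS, normal breathing
  exp_frac        = 0.35,   # expiration loudness relative to inspiration
  floor_rms       = 0.002,  # sensor noise floor under voiced minutes
  uncertain_rms   = 2e-04,  # near-silent minutes (<1% of normal clip RMS)
  f0_hz           = 100,    # snore source fundamental
  resonator_bw_hz = 80      # snore resonator bandwidth
)

# 2nd-order resonator at f_hz, output rescaled afterwards by the caller
resonate <- function(x, f_hz, rate, bw_hz = .syn$resonator_bw_hz) {
  r <- exp(-pi * bw_hz / rate)
  a <- c(-2 * r * cos(2 * pi * f_hz / rate), r^2)
  as.numeric(stats::filter(x, -a, method = "recursive"))
}

# harmonic snore burst: impulse train at f0 through a resonator, raised-
# cosine envelope, 5% additive noise, scaled to the target RMS
snore_burst <- function(dur_s, f1_hz, rate, target_rms = .syn$snore_burst_rms) {
  n <- as.integer(round(dur_s * rate))
  x <- numeric(n)
  x[seq(1L, n, by = max(2L, as.integer(round(rate / .syn$f0_hz))))] <- 1
  y <- resonate(x, f1_hz, rate)
  y <- y + 0.05 * stats::sd(y) * stats::rnorm(n)
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  y <- y * env
  y * target_rms / sqrt(mean(y^2))
}

# broadband 50-2000 Hz noise burst with a raised-cosine envelope
noise_burst <- function(dur_s, rate, target_rms) {
  n <- as.integer(round(dur_s * rate))
  y <- stats::rnorm(n)
  sos <- butter_bandpass_sos(50, min(2000, 0.45 * rate), rate, 2L)
  y <- sosfilt(sos, y)
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  y <- y * env
  y * target_rms / sqrt(mean(y^2))
}

add_at <- function(x, burst, onset_s, rate) {
  i0 <- as.integer(round(onset_s * rate)) + 1L
  i1 <- min(length(x), i0 + length(burst) - 1L)
  if (i0 <= length(x)) x[i0:i1] <- x[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
  x
}

new_minute_clip <- function(samples, rate) {
  structure(list(index = 0L, samples = samples, rate = rate,
                 start_s = 0, end_s = 60), class = "clip")
}

#' Generate one minute of normal breathing
#'
#' Breath cycles with period drawn uniformly from 3-6 s: a broadband
#' inspiratory noise burst plus a quieter expiratory one, over a small
#' sensor noise floor.
#'
#' @param seed RNG seed (deterministic output).
#' @param rate sampling rate in Hz (>= 5000).
#' @return a 60 s `clip`.
#' @export
gen_normal_minute <- function(seed, rate = 5000) {
  stopifnot(rate >= 5000)
  set.seed(as.integer(seed))
  n <- 60L * rate
  x <- stats::rnorm(n) * .syn$floor_rms
  t <- stats::runif(1, 0.2, 0.8)
  while (TRUE) {
    period <- stats::runif(1, 3, 6)
    insp <- 0.4 * period
    if (t + period > 60) break
    x <- add_at(x, noise_burst(insp, rate, .syn$breath_rms), t, rate)
    x <- add_at(x, noise_burst(0.3 * period, rate,
                               .syn$exp_frac * .syn$breath_rms),
                t + insp + 0.05 * period, rate)
    t <- t + period
  }
  new_minute_clip(x, rate)
}

#' Generate one minute of simple snoring
#'
#' Inspiratory harmonic bursts (F0 = 100 Hz source through a resonator at
#' `f1_hz`, per-episode F1 jitter sigma `f1_jitter_hz`) with onsets every
#' 4 s plus Gaussian jitter.
#'
#' @param seed RNG seed.
#' @param rate sampling rate in Hz.
#' @param f1_hz resonator center (default 400 Hz, the low-F1 simple-snore
#'   regime).
#' @param interval_jitter_s onset jitter sigma in seconds (default 0.2).
#' @param f1_jitter_hz per-episode F1 jitter sigma (default 15).
#' @param interval_s nominal onset-to-onset spacing (default 4 s).
#' @return a 60 s `clip`.
#' @export
gen_simple_snore_minute <- function(seed, rate = 5000, f1_hz = 400,
                                    interval_jitter_s = 0.2,
                                    f1_jitter_hz = 15, interval_s = 4) {
  set.seed(as.integer(seed))
  n <- 60L * rate
  x <- stats::rnorm(n) * .syn$floor_rms
  t <- 1.0
  while (t < 60 - 1.5) {
    dur <- stats::runif(1, 0.8, 1.1)
    f1 <- max(150, min(2300, f1_hz + stats::rnorm(1, 0, f1_jitter_hz)))
    x <- add_at(x, snore_burst(dur, f1, rate), t, rate)
    t <- t + max(dur + 0.4, interval_s + stats::rnorm(1, 0, interval_jitter_s))
  }
  new_minute_clip(x, rate)
}

#' Generate one minute of apneic snoring with an inserted pause
#'
#' Irregular snore bursts (resonator near `f1_hz` with sigma
#' `f1_jitter_hz` jitter; inter-onset intervals `4 + N(0,
#' interval_jitter_s)` truncated to \[1.5, 5\] s) with exactly one silent
#' pause of `pause_s` seconds. The truncation plus a final burst anchored
#' near the clip end make the inserted pause the maximum breathing gap by
#' construction, so MBPI recovery is well-posed even for short pauses.
#'
#' @param seed RNG seed.
#' @param rate sampling rate in Hz.
#' @param f1_hz resonator center (default 600 Hz, the high-F1 apneic
#'   regime).
#' @param pause_s inserted pause length in seconds, `2 < pause_s <= 45`.
#' @param f1_jitter_hz per-episode F1 jitter sigma (default 100).
#' @param interval_jitter_s nominal onset jitter sigma (default 3; draws
#'   are truncated as described).
#' @return a 60 s `clip`.
#' @export
gen_apneic_snore_minute <- function(seed, rate = 5000, f1_hz = 600, pause_s,
                                    f1_jitter_hz = 100,
                                    interval_jitter_s = 3) {
  stopifnot(pause_s > 2, pause_s <= 45)
  set.seed(as.integer(seed))
  n <- 60L * rate
  x <- stats::rnorm(n) * .syn$floor_rms      # sensor floor, same as all voiced minutes
  pause_start <- stats::runif(1, 6, min(20, 57 - pause_s - 3))
  draw_gap <- function() min(5, max(1.5, 4 + stats::rnorm(1, 0, interval_jitter_s)))
  place <- function(x, t) {
    dur <- stats::runif(1, 0.7, 1.0)
    f1 <- max(200, min(2300, f1_hz + stats::rnorm(1, 0, f1_jitter_hz)))
    list(x = add_at(x, snore_burst(dur, f1, rate), t, rate), offset = t + dur)
  }
  t <- stats::runif(1, 0.3, 0.6)
  last_offset <- 0
  while (t < pause_start - 1.0) {            # bursts before the pause
    p <- place(x, t); x <- p$x; last_offset <- p$offset
    t <- p$offset + draw_gap() - 0.9
  }
  t <- last_offset + pause_s                 # the pause itself
  while (t < 58.2 - 1.0) {                   # bursts after the pause
    p <- place(x, t); x <- p$x
    t <- p$offset + draw_gap() - 0.9
  }
  p <- place(x, 58.2); x <- p$x              # anchor burst near the end
  new_minute_clip(x, rate)
}

#' Generate one near-silent ("uncertain") minute
#'
#' Broadband noise at about 1% of the normal-breathing clip RMS: too weak
#' for any spectral or episode analysis.
#'
#' @param seed RNG seed.
#' @param rate sampling rate in Hz.
#' @return a 60 s `clip`.
#' @export
gen_uncertain_minute <- function(seed, rate = 5000) {
  set.seed(as.integer(seed))
  new_minute_clip(stats::rnorm(60L * rate) * .syn$uncertain_rms, rate)
}

#' Build a scenario plan
#'
#' @param labels per-minute ground-truth labels, each one of `"normal"`,
#'   `"simple_snoring"`, `"apneic_snoring"`, `"uncertain"`.
#' @param pause_s per-minute inserted pause lengths (seconds); required
#'   (finite, < 60) exactly at apneic minutes, ignored elsewhere.
#' @param seed base RNG seed for the scenario.
#' @param rate audio sampling rate.
#' @return object of class `scenario_plan`.
#' @export
scenario_plan <- function(labels, pause_s = NULL, seed = 0L, rate = 5000) {
  ok <- c("normal", "simple_snoring", "apneic_snoring", "uncertain")
  if (!all(labels %in% ok))
    stop("labels must be in: ", paste(ok, collapse = ", "))
  n <- length(labels)
  if (is.null(pause_s)) pause_s <- rep(NA_real_, n)
  if (length(pause_s) != n) stop("pause_s must align with labels")
  as_ <- labels == "apneic_snoring"
  if (any(as_ & (!is.finite(pause_s) | pause_s >= 60)))
    stop("every apneic minute needs a finite pause_s < 60")
  structure(list(labels = labels, pause_s = ifelse(as_, pause_s, NA_real_),
                 seed = as.integer(seed), rate = rate),
            class = "scenario_plan")
}

#' Random mixed scenario plan
#'
#' Shuffles runs of each class into a plan with the requested composition.
#' Apneic pauses are drawn half from U(4, 9) (medium regime) and half from
#' U(12, 30) (low regime).
#'
#' @param n_normal,n_ss,n_as,n_unc minutes per class.
#' @param seed RNG seed.
#' @param rate audio sampling rate.
#' @return a [scenario_plan()].
#' @export
random_plan <- function(n_normal = 20, n_ss = 60, n_as = 30, n_unc = 10,
                        seed = 0L, rate = 5000) {
  set.seed(as.integer(seed))
  chop <- function(total, max_run) {       # split a class into runs
    runs <- integer(0)
    while (total > 0) {
      r <- min(total, sample.int(max_run, 1))
      runs <- c(runs, r); total <- total - r
    }
    runs
  }
  blocks <- c(lapply(chop(n_normal, 6), function(r) rep("normal", r)),
              lapply(chop(n_ss, 8), function(r) rep("simple_snoring", r)),
              lapply(chop(n_as, 6), function(r) rep("apneic_snoring", r)),
              lapply(chop(n_unc, 3), function(r) rep("uncertain", r)))
  labels <- unlist(blocks[sample.int(length(blocks))])
  pauses <- rep(NA_real_, length(labels))
  as_idx <- which(labels == "apneic_snoring")
  half <- length(as_idx) %/% 2
  regimes <- sample(c(rep(TRUE, half), rep(FALSE, length(as_idx) - half)))
  pauses[as_idx] <- ifelse(regimes, stats::runif(length(as_idx), 12, 30),
                           stats::runif(length(as_idx), 4, 9))
  scenario_plan(labels, pauses, seed = seed, rate = rate)
}

# ground-truth tidal levels implied by a plan (same rule table the
# pipeline applies, driven by the generating parameters)
plan_truth <- function(plan) {
  elapsed <- simple_snoring_elapsed(plan$labels)
  level <- character(length(plan$labels))
  for (i in seq_along(plan$labels)) {
    level[i] <- switch(plan$labels[i],
      normal = "high",
      uncertain = "uncertain",
      simple_snoring = if (elapsed[i] >= 4) "medium" else "high",
      apneic_snoring = if (plan$pause_s[i] > 10) "low" else "medium")
  }
  data.frame(minute = seq_along(plan$labels) - 1L, label = plan$labels,
             pause_s = plan$pause_s, elapsed_min = elapsed, level = level)
}

#' Generate the SpO2 trace implied by a plan
#'
#' Baseline 97%. Apneic minutes dip to 92% (pause <= 10 s) or 88%
#' (pause > 10 s); simple-snoring minutes at run position >= 4 dip to 93%;
#' uncertain and normal minutes stay at baseline. Each dip is a trapezoid
#' contained in its minute with 15 s linear transitions, so the per-minute
#' minimum equals the dip value and neighbouring minutes are untouched.
#'
#' @param plan a [scenario_plan()].
#' @return an [spo2_trace()] of `60 * length(plan$labels)` seconds.
#' @export
gen_spo2 <- function(plan) {
  stopifnot(inherits(plan, "scenario_plan"))
  truth <- plan_truth(plan)
  base <- 97
  target <- rep(base, nrow(truth))
  as_ <- truth$label == "apneic_snoring"
  target[as_] <- ifelse(truth$pause_s[as_] > 10, 88, 92)
  ss <- truth$label == "simple_snoring" & truth$elapsed_min >= 4
  target[ss] <- 93
  vals <- rep(base, 60L * nrow(truth))
  for (i in which(target < base)) {
    o <- (i - 1L) * 60L
    ramp <- seq(base, target[i], length.out = 16)[-1]
    vals[o + 1:15] <- ramp
    vals[o + 16:45] <- target[i]
    vals[o + 46:60] <- rev(ramp)
  }
  spo2_trace(vals)
}

#' Generate a full labelled scenario
#'
#' Concatenates per-minute audio (each minute seeded deterministically from
#' the plan seed) and pairs it with the consistent SpO2 trace and the
#' ground-truth table.
#'
#' @param plan a [scenario_plan()].
#' @return list with `audio` ([audio_recording()]), `spo2`
#'   ([spo2_trace()]) and `truth` (data.frame: minute, label, pause_s,
#'   elapsed_min, level).
#' @export
gen_scenario <- function(plan) {
  stopifnot(inherits(plan, "scenario_plan"))
  minutes <- lapply(seq_along(plan$labels), function(i) {
    s <- plan$seed + 1009L * i
    switch(plan$labels[i],
      normal = gen_normal_minute(s, plan$rate),
      simple_snoring = gen_simple_snore_minute(s, plan$rate),
      apneic_snoring = gen_apneic_snore_minute(s, plan$rate,
                                               pause_s = plan$pause_s[i]),
      uncertain = gen_uncertain_minute(s, plan$rate))
  })
  audio <- audio_recording(unlist(lapply(minutes, `[[`, "samples")), plan$rate)
  list(audio = audio, spo2 = gen_spo2(plan), truth = plan_truth(plan))
}
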