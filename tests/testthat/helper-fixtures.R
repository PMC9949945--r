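# Shared fixture builders. Everything is generated in code; no binary files.

# pure tone recording
tone_rec <- function(f_hz, rate, dur_s = 1) {
  t <- (0:(rate * dur_s - 1)) / rate
  audio_recording(sin(2 * pi * f_hz * t), rate)
}

rms <- function(x) sqrt(mean(x^2))

# a clip object straight from samples (bypasses segment())
as_clip <- function(samples, rate, index = 0L) {
  structure(list(index = index, samples = samples, rate = rate,
                 start_s = index * length(samples) / rate,
                 end_s = (index + 1) * length(samples) / rate),
            class = "clip")
}

# noise-burst clip with known event onsets (for detector tests)
burst_clip <- function(onsets_s, dur_s, rate = 5000, len_s = 60,
                       amp = 0.2, seed = 1) {
  set.seed(seed)
  x <- rnorm(len_s * rate) * 1e-3
  for (o in onsets_s) {
    n <- round(dur_s * rate)
    i0 <- round(o * rate) + 1
    ramp <- round(0.05 * rate)                       # 50 ms attack/release
    env <- pmin(1, pmin(seq_len(n), rev(seq_len(n))) / ramp)
    x[i0:(i0 + n - 1)] <- x[i0:(i0 + n - 1)] + amp * env * rnorm(n)
  }
  as_clip(x, rate)
}

# LPC polynomial of cascaded 2nd-order resonators (exact coefficients)
resonator_poly <- function(freqs_hz, rate, r = 0.97) {
  a <- 1
  for (f in freqs_hz) {
    sec <- c(1, -2 * r * cos(2 * pi * f / rate), r^2)
    a <- stats::convolve(a, rev(sec), type = "open")
  }
  a
}

# impulse-excited resonator frame with mild noise (all-pole fixture)
resonator_frame <- function(freqs_hz, rate = 5000, n = 512, r = 0.97,
                            noise = 0.003, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[sample(1:20, 1)] <- 1
  for (f in freqs_hz)
    x <- as.numeric(stats::filter(x, c(2 * r * cos(2 * pi * f / rate), -r^2),
                                  method = "recursive"))
  x <- x + noise * sd(x) * rnorm(n)
  x * (0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# independent O(n^3) average-linkage agglomeration (oracle)
naive_average_linkage_cut <- function(d, k) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  ids <- integer(n)
  for (g in seq_along(groups)) ids[groups[[g]]] <- g
  ids
}

# partitions equal up to relabeling?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# cross-file cache so the acceptance blocks can share one heavy scenario
acc_cache <- new.env(parent = emptyenv())
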