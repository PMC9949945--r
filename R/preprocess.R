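# Preprocessing: bandpass filtering, downsampling, fixed 60 s segmentation.
#
# The Butterworth bandpass is designed from the analog prototype via the
# bilinear transform and applied as a cascade of biquads (transfer-function
# form is ill-conditioned for a 50 Hz edge at 48 kHz), forward-backward so
# that event timing is phase-exact for the pause analysis downstream.

# Analog-prototype -> digital biquad cascade for an order-n bandpass.
butter_bandpass_sos <- function(low_hz, high_hz, rate, order = 4L) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < rate / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))   # LHP Butterworth poles
  w1 <- 2 * rate * tan(pi * low_hz / rate)                    # prewarped edges
  w2 <- 2 * rate * tan(pi * high_hz / rate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass->bandpass: each prototype pole spawns two analog poles
  ph <- proto * bw / 2
  s_poles <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
  z_poles <- (1 + s_poles / (2 * rate)) / (1 - s_poles / (2 * rate))  # bilinear

  # pair conjugates into biquads (all complex for any usable band)
  tol <- 1e-9
  cplx <- z_poles[Im(z_poles) > tol]
  reals <- sort(Re(z_poles[abs(Im(z_poles)) <= tol]))
  sec_a <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(reals) > 0) {
    for (i in seq(1, length(reals), by = 2))
      sec_a[[length(sec_a) + 1L]] <- c(1, -(reals[i] + reals[i + 1]),
                                       reals[i] * reals[i + 1])
  }
  n_sec <- length(sec_a)
  # zeros: `order` at z=1 and at z=-1 -> one (z-1)(z+1) pair per section
  sos <- lapply(sec_a, function(a) list(b = c(1, 0, -1), a = a))
  # unity gain at the (warped) center frequency
  z0 <- exp(1i * 2 * atan(w0 / (2 * rate)))
  h <- vapply(sos, function(s)
    (z0^2 * s$b[1] + z0 * s$b[2] + s$b[3]) /
    (z0^2 * s$a[1] + z0 * s$a[2] + s$a[3]), complex(1))
  g <- (1 / Mod(prod(h)))^(1 / n_sec)
  for (i in seq_len(n_sec)) sos[[i]]$b <- sos[[i]]$b * g
  sos
}

sos_as_matrix <- function(sos) {
  do.call(rbind, lapply(sos, function(s) c(s$b, s$a)))
}

sosfilt <- function(sos, x) {
  .sosfilt_c(sos_as_matrix(sos), as.numeric(x))
}

# zero-phase filtering with odd-reflection padding; the forward and
# backward passes run in compiled code without reversal copies
filtfilt_sos <- function(sos, x, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, as.integer(padlen))
  if (padlen > 0) {
    pre  <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xt <- c(pre, x, post)
  } else xt <- x
  y <- .filtfilt_sos_c(sos_as_matrix(sos), as.numeric(xt))
  if (padlen > 0) y[(padlen + 1):(padlen + n)] else y
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth applied forward-backward (zero phase), so the timing
#' of respiratory events is preserved for the pause analysis.
#'
#' @param rec an [audio_recording()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < rate/2`.
#' @param order filter order of the one-way design (default 4).
#' @return A filtered [audio_recording()] of identical length and rate.
#' @export
bandpass <- function(rec, low_hz = 50, high_hz = 2450, order = 4L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= rec$rate / 2)
    stop("high_hz must be below the Nyquist frequency ", rec$rate / 2, " Hz")
  sos <- butter_bandpass_sos(low_hz, high_hz, rec$rate, order)
  padlen <- max(30L, round(3 * rec$rate / low_hz))
  audio_recording(filtfilt_sos(sos, rec$samples, padlen), rec$rate, rec$t0)
}

#' Downsample a recording
#'
#' Linear interpolation onto the target sampling grid. The caller must have
#' band-limited the signal first ([bandpass()] with `high_hz` below the
#' target Nyquist guarantees anti-aliasing); at the oversampling ratios in
#' play (48 kHz to 5 kHz with content below 2.45 kHz) interpolation error is
#' negligible.
#'
#' @param rec an [audio_recording()].
#' @param target_hz target rate in Hz, strictly below `rec$rate`.
#' @return An [audio_recording()] at `target_hz`, duration preserved to
#'   within one sample.
#' @export
downsample <- function(rec, target_hz = 5000) {
  stopifnot(inherits(rec, "audio_recording"))
  if (target_hz >= rec$rate) stop("target_hz must be below the source rate")
  n_in <- length(rec$samples)
  n_out <- floor(n_in * target_hz / rec$rate)
  t_in <- (seq_len(n_in) - 1) / rec$rate
  t_out <- (seq_len(n_out) - 1) / target_hz
  y <- stats::approx(t_in, rec$samples, xout = t_out, rule = 2)$y
  audio_recording(y, target_hz, rec$t0)
}

#' Segment a recording into fixed-length clips
#'
#' Clips tile `[0, N*clip_len_s)` half-open without overlap; a trailing
#' partial clip is discarded.
#'
#' @param rec an [audio_recording()].
#' @param clip_len_s clip length in seconds (default 60).
#' @return A list of `clip` objects (`index` 0-based, `samples`, `rate`,
#'   `start_s`, `end_s`); empty when the recording is shorter than one clip.
#' @export
segment <- function(rec, clip_len_s = 60) {
  stopifnot(inherits(rec, "audio_recording"), clip_len_s > 0)
  spc <- as.integer(round(clip_len_s * rec$rate))
  n_clips <- length(rec$samples) %/% spc
  if (n_clips == 0L) return(list())
  lapply(seq_len(n_clips) - 1L, function(i) {
    structure(list(index = i,
                   samples = rec$samples[(i * spc + 1L):((i + 1L) * spc)],
                   rate = rec$rate,
                   start_s = rec$t0 + i * clip_len_s,
                   end_s = rec$t0 + (i + 1) * clip_len_s),
              class = "clip")
  })
}

#' @export
print.clip <- function(x, ...) {
  cat(sprintf("<clip #%d> [%g, %g) s @ %g Hz\n", x$index, x$start_s, x$end_s, x$rate))
  invisible(x)
}

clip_rms <- function(clip) sqrt(mean(clip$samples^2))
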