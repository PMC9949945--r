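# MFCC features: mel scale, triangular filterbank, log-mel spectrogram,
# DCT-II cepstra, frame-averaged per-clip feature vectors and the pairwise
# Euclidean distance matrix that feeds the hierarchical clustering.

#' Hertz to mel
#'
#' `mel = 2595 * log10(f/700 + 1)`; strictly increasing.
#'
#' @param f frequency in Hz, `f >= 0` (vectorized).
#' @return mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be nonnegative")
  2595 * log10(f / 700 + 1)
}

#' Mel to hertz (inverse of [hz_to_mel()])
#' @param m mel value(s), `m >= 0`.
#' @return frequency in Hz.
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel value must be nonnegative")
  700 * (10^(m / 2595) - 1)
}

#' Triangular mel filterbank
#'
#' Filter centers are equally spaced on the mel axis between
#' `hz_to_mel(f_lo)` and `hz_to_mel(f_hi)`; each filter is max-normalized
#' to peak 1.
#'
#' @param n_filters number of filters (>= 2).
#' @param n_fft FFT length; the filterbank covers bins `0..n_fft/2`.
#' @param rate sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz, `f_lo < f_hi <= rate/2`.
#' @return matrix `(n_filters, n_fft/2 + 1)` of nonnegative weights, with
#'   attribute `centers_hz`.
#' @export
mel_filterbank <- function(n_filters, n_fft, rate, f_lo = 50, f_hi = 2450) {
  if (n_filters < 2) stop("need at least 2 filters")
  if (!(f_lo < f_hi && f_hi <= rate / 2)) stop("infeasible band")
  mel_pts <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_hz <- (0:(n_fft %/% 2)) * rate / n_fft
  fb <- matrix(0, n_filters, length(bin_hz))
  for (k in seq_len(n_filters)) {
    l <- hz_pts[k]; c <- hz_pts[k + 1]; r <- hz_pts[k + 2]
    tri <- pmax(0, pmin((bin_hz - l) / (c - l), (r - bin_hz) / (r - c)))
    mx <- max(tri)
    fb[k, ] <- if (mx > 0) tri / mx else tri
  }
  attr(fb, "centers_hz") <- hz_pts[2:(n_filters + 1L)]
  fb
}

# frame a signal into a (win x n_frames) matrix, no padding, drop remainder
frame_signal <- function(x, win, hop) {
  n_frames <- floor((length(x) - win) / hop) + 1L
  if (n_frames < 1L) stop("signal shorter than one analysis window")
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], nrow = win)
}

#' Log-mel spectrogram of a clip
#'
#' Hann-windowed power STFT projected onto the mel filterbank, with a floor
#' before the log so silent frames stay finite.
#'
#' @param clip a `clip` from [segment()].
#' @param win_s,hop_s STFT window and hop in seconds (defaults 1.0 / 0.5).
#' @param n_filters number of mel filters (default 40).
#' @param f_lo,f_hi filterbank band in Hz.
#' @param eps floor applied to mel power before `log` (default 1e-10).
#' @return matrix `(n_filters, n_frames)` of natural-log mel power, with
#'   attribute `frame_times` (window-start seconds within the clip);
#'   `n_frames = floor((len - win)/hop) + 1`.
#' @export
mel_spectrogram <- function(clip, win_s = 1.0, hop_s = 0.5, n_filters = 40,
                            f_lo = 50, f_hi = 2450, eps = 1e-10) {
  stopifnot(inherits(clip, "clip"))
  if (length(clip$samples) == 0L) stop("empty clip")
  win <- as.integer(round(win_s * clip$rate))
  hop <- as.integer(round(hop_s * clip$rate))
  if (win > length(clip$samples)) stop("window longer than clip")
  n_fft <- 2^ceiling(log2(win))
  frames <- frame_signal(clip$samples, win, hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))  # Hann
  frames <- frames * w
  if (n_fft > win) frames <- rbind(frames, matrix(0, n_fft - win, ncol(frames)))
  spec <- stats::mvfft(frames)[1:(n_fft %/% 2 + 1L), , drop = FALSE]
  pow <- Mod(spec)^2
  fb <- mel_filterbank(n_filters, n_fft, clip$rate, f_lo, f_hi)
  out <- log(pmax(fb %*% pow, eps))
  attr(out, "frame_times") <- (seq_len(ncol(out)) - 1) * hop_s
  out
}

#' MFCC matrix of a clip
#'
#' Orthonormal DCT-II along the filter axis of the log-mel spectrogram;
#' the first `n_mfcc` coefficients (including the 0th) are retained.
#'
#' @inheritParams mel_spectrogram
#' @param n_mfcc number of cepstral coefficients kept (default 13).
#' @return matrix `(n_mfcc, n_frames)` with attribute `frame_times`.
#' @export
mfcc <- function(clip, n_mfcc = 13, win_s = 1.0, hop_s = 0.5, n_filters = 40,
                 f_lo = 50, f_hi = 2450, eps = 1e-10) {
  lm <- mel_spectrogram(clip, win_s, hop_s, n_filters, f_lo, f_hi, eps)
  D <- dct2_matrix(n_filters)[seq_len(n_mfcc), , drop = FALSE]
  out <- D %*% lm
  attr(out, "frame_times") <- attr(lm, "frame_times")
  out
}

# orthonormal DCT-II matrix (N x N)
dct2_matrix <- function(N) {
  k <- 0:(N - 1)
  D <- sqrt(2 / N) * cos(pi * outer(k, k + 0.5) / N)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Frame-averaged MFCC feature vector
#'
#' Collapses an MFCC matrix to one point in cepstral space by averaging
#' each coefficient across frames.
#'
#' @param m an MFCC matrix (coefficients in rows, frames in columns).
#' @return numeric vector of length `nrow(m)`.
#' @export
clip_feature <- function(m) {
  if (!is.matrix(m) || ncol(m) < 1L) stop("need a matrix with >= 1 frame")
  rowMeans(m)
}

#' Euclidean distance between two feature vectors
#' @param p,q numeric vectors of equal length.
#' @return `sqrt(sum((p - q)^2))`.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q)) stop("feature length mismatch")
  sqrt(sum((p - q)^2))
}

#' Pairwise Euclidean distance matrix over clip features
#'
#' @param features list of feature vectors, or a matrix with one feature
#'   per row.
#' @return symmetric `n x n` matrix with zero diagonal.
#' @export
distance_matrix <- function(features) {
  X <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 features")
  if (any(!is.finite(X))) stop("features must be finite")
  as.matrix(stats::dist(X, method = "euclidean"))
}
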