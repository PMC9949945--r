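# Rule table: maximum breathing pause interval (MBPI) for apneic snoring,
# elapsed time for simple snoring, and the mapping to tidal volume levels.

#' Detect breathing events in a clip
#'
#' Same envelope-relative detector as [detect_snore_episodes()] but with a
#' 200 ms minimum event duration, so single breaths count as events.
#'
#' @param clip a preprocessed `clip`.
#' @param min_ms minimum event duration in ms (default 200).
#' @return data.frame with `onset_s`, `offset_s`, sorted, non-overlapping;
#'   zero rows for a silent clip.
#' @export
detect_breath_events <- function(clip, min_ms = 200) {
  stopifnot(inherits(clip, "clip"))
  detect_envelope_events(clip$samples, clip$rate, min_ms)
}

#' Maximum breathing pause interval
#'
#' The longest stretch without any detected respiratory event, including
#' the boundary gaps before the first and after the last event (an apnea
#' spanning a clip edge still suppresses breathing). With no events at all
#' the whole clip is one pause.
#'
#' @param events data.frame with `onset_s`, `offset_s` (sorted,
#'   non-overlapping).
#' @param clip_len_s clip length in seconds (default 60).
#' @return MBPI in seconds.
#' @export
mbpi <- function(events, clip_len_s = 60) {
  if (nrow(events) == 0L) return(clip_len_s)
  gaps <- c(events$onset_s[1],
            events$onset_s[-1] - events$offset_s[-nrow(events)],
            clip_len_s - events$offset_s[nrow(events)])
  max(0, gaps)
}

#' Elapsed simple-snoring time per clip
#'
#' Within each maximal run of consecutive simple-snoring clips, the clip at
#' 1-based position k has been snoring for k minutes (60 s clips). Runs
#' reset on any other label.
#'
#' @param labels chronologically ordered per-clip labels; simple snoring is
#'   recognised as `"simple_snoring"` (or `"simple"`).
#' @return numeric vector: elapsed minutes for simple-snoring clips, `NA`
#'   elsewhere.
#' @export
simple_snoring_elapsed <- function(labels) {
  is_ss <- labels %in% c("simple_snoring", "simple")
  out <- rep(NA_real_, length(labels))
  r <- rle(is_ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values))
    out[starts[i]:ends[i]] <- seq_len(r$lengths[i])
  out
}

#' Tidal volume level of one clip
#'
#' The decision table:
#' \itemize{
#'   \item apneic snoring, MBPI <= 10 s: medium; MBPI > 10 s: low
#'   \item simple snoring, elapsed < 4 min: high; elapsed >= 4 min: medium
#'   \item normal respiration: high
#'   \item uncertain: uncertain
#' }
#'
#' @param semantic one of `"snoring"`, `"normal"`, `"uncertain"`.
#' @param snore_type for snoring clips, `"simple"` or `"apneic"`.
#' @param mbpi_s MBPI in seconds (required for apneic clips).
#' @param elapsed_min elapsed simple-snoring minutes (required for simple
#'   clips).
#' @param mbpi_threshold_s,elapsed_threshold_min rule thresholds
#'   (defaults 10 s and 4 min).
#' @return one of `"high"`, `"medium"`, `"low"`, `"uncertain"`.
#' @export
tidal_level <- function(semantic, snore_type = NULL, mbpi_s = NULL,
                        elapsed_min = NULL, mbpi_threshold_s = 10,
                        elapsed_threshold_min = 4) {
  switch(semantic,
    uncertain = "uncertain",
    normal = "high",
    snoring = {
      if (is.null(snore_type) || !snore_type %in% c("simple", "apneic"))
        stop("snoring clips need snore_type 'simple' or 'apneic'")
      if (snore_type == "apneic") {
        if (is.null(mbpi_s) || !is.finite(mbpi_s))
          stop("apneic clips need a finite mbpi_s")
        if (mbpi_s > mbpi_threshold_s) "low" else "medium"
      } else {
        if (is.null(elapsed_min) || !is.finite(elapsed_min))
          stop("simple-snoring clips need a finite elapsed_min")
        if (elapsed_min >= elapsed_threshold_min) "medium" else "high"
      }
    },
    stop("unknown semantic label: ", semantic))
}
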