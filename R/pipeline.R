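# End-to-end orchestration: preprocess -> MFCC features -> AHC -> formant
# K-means -> rule table -> (optional) SpO2 evaluation.

#' Pipeline configuration
#'
#' All defaults are the method's stated parameters, so
#' `run_pipeline(audio, spo2)` with no further arguments reproduces the
#' method as described.
#'
#' @param ... named overrides of any default listed below.
#' @return a validated named list of class `snorevol_config`.
#' @export
snorevol_config <- function(...) {
  cfg <- list(
    band_low_hz = 50, band_high_hz = 2450, target_rate_hz = 5000,
    clip_len_s = 60,
    n_mels = 40, n_mfcc = 13, stft_win_ms = 1000, stft_hop_ms = 500,
    fmin_hz = 50, fmax_hz = 2450,
    linkage = "average", n_clusters = 3,
    lpc_order = 14, lpc_win_ms = 20, lpc_overlap = 0.5,
    episode_min_ms = 300, formant_bw_max_hz = 400,
    event_min_ms = 200,
    mbpi_threshold_s = 10, ss_elapsed_threshold_min = 4,
    kmeans_seed = 0)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(band_low_hz > 0, band_low_hz < band_high_hz,
              band_high_hz < target_rate_hz / 2 + 51,  # 2450 < 2500 by design
              clip_len_s > 0, n_mels >= 2, n_mfcc >= 1, n_mfcc <= n_mels,
              lpc_order >= 2, n_clusters == 3)
  })
  structure(cfg, class = "snorevol_config")
}

#' Run the full tidal-volume-level pipeline
#'
#' Filters and downsamples the recording, segments it into one-minute
#' clips, clusters frame-averaged MFCC features into snoring / normal /
#' uncertain, splits snoring clips into simple vs apneic by K-means on the
#' formant feature, applies the rule table, and (when an SpO2 trace is
#' given) grades each clip's LoO2 and scores the uncertain-excluding
#' accuracy.
#'
#' @param audio an [audio_recording()] or a WAV path.
#' @param spo2 an [spo2_trace()], a CSV path, or `NULL` for
#'   predictions-only mode.
#' @param config a [snorevol_config()].
#' @param out_dir if non-NULL, `results.csv`, `summary.json` and
#'   `summary.png` are written there.
#' @param label_map optional manual semantic override: named character
#'   vector mapping cluster id (`"1"`..`"3"`) to
#'   `"snoring"`/`"normal"`/`"uncertain"`.
#' @param verbose log each stage with `message()` (default TRUE).
#' @return a `snorevol_report` (see [evaluation_report()]) with extra
#'   fields `assignment` (the cluster/semantic structure) and `config`.
#' @export
run_pipeline <- function(audio, spo2 = NULL, config = snorevol_config(),
                         out_dir = NULL, label_map = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(audio)) audio <- read_wav(audio)
  if (is.character(spo2)) spo2 <- read_spo2_csv(spo2)
  stopifnot(inherits(audio, "audio_recording"))

  say("[preprocess] bandpass %g-%g Hz at %g Hz",
      config$band_low_hz, config$band_high_hz, audio$rate)
  rec <- bandpass(audio, config$band_low_hz,
                  min(config$band_high_hz, 0.49 * audio$rate))
  if (rec$rate > config$target_rate_hz) {
    say("[preprocess] downsample %g -> %g Hz", rec$rate, config$target_rate_hz)
    rec <- downsample(rec, config$target_rate_hz)
  }
  clips <- segment(rec, config$clip_len_s)
  say("[preprocess] %d clips of %g s", length(clips), config$clip_len_s)
  if (length(clips) == 0L) {
    warning("recording shorter than one clip; empty prediction set")
    return(evaluation_report(data.frame(
      clip_index = integer(0), label = character(0), mbpi_s = numeric(0),
      elapsed_min = numeric(0), pred_level = character(0),
      loo2 = numeric(0), ref_level = character(0))))
  }

  say("[mfcc] %d mel filters, %d coefficients, %g/%g ms frames",
      config$n_mels, config$n_mfcc, config$stft_win_ms, config$stft_hop_ms)
  feats <- lapply(clips, function(cl)
    clip_feature(mfcc(cl, config$n_mfcc, config$stft_win_ms / 1000,
                      config$stft_hop_ms / 1000, config$n_mels,
                      config$fmin_hz, config$fmax_hz)))
  d <- distance_matrix(feats)

  say("[ahc] %s linkage, cut at k = %d", config$linkage, config$n_clusters)
  tree <- ahc_linkage(d, config$linkage)
  ids <- cut_tree(tree, config$n_clusters)
  if (!is.null(label_map)) {
    if (!setequal(label_map, c("snoring", "normal", "uncertain")))
      stop("label_map must assign snoring/normal/uncertain exactly once")
    assign <- list(labels = unname(label_map[as.character(ids)]),
                   semantic = label_map, cluster_rms = NULL)
  } else {
    assign <- assign_semantics(ids, clips)
  }
  n_clips <- length(clips)
  label <- assign$labels                     # snoring/normal/uncertain

  say("[formants] LPC order %d on %d snoring clips",
      config$lpc_order, sum(label == "snoring"))
  snore_idx <- which(label == "snoring")
  snore_type <- rep(NA_character_, n_clips)
  if (length(snore_idx) > 0L) {
    sf <- do.call(rbind, lapply(snore_idx, function(i) {
      ep <- detect_snore_episodes(clips[[i]], config$episode_min_ms,
                                  config$lpc_order, config$lpc_win_ms,
                                  config$lpc_overlap,
                                  config$formant_bw_max_hz)
      as.data.frame(snore_features(ep))
    }))
    snore_type[snore_idx] <- classify_snore_type(sf, config$kmeans_seed)
  }

  full_label <- ifelse(label == "snoring",
                       ifelse(snore_type == "apneic",
                              "apneic_snoring", "simple_snoring"),
                       label)

  say("[rules] MBPI threshold %g s, elapsed threshold %g min",
      config$mbpi_threshold_s, config$ss_elapsed_threshold_min)
  mbpi_s <- rep(NA_real_, n_clips)
  for (i in which(full_label == "apneic_snoring"))
    mbpi_s[i] <- mbpi(detect_breath_events(clips[[i]], config$event_min_ms),
                      config$clip_len_s)
  elapsed <- simple_snoring_elapsed(full_label)
  pred <- vapply(seq_len(n_clips), function(i)
    tidal_level(label[i],
                snore_type = snore_type[i],
                mbpi_s = mbpi_s[i], elapsed_min = elapsed[i],
                mbpi_threshold_s = config$mbpi_threshold_s,
                elapsed_threshold_min = config$ss_elapsed_threshold_min),
    character(1))

  loo2_v <- rep(NA_real_, n_clips)
  ref <- rep(NA_character_, n_clips)
  if (!is.null(spo2)) {
    say("[evaluation] LoO2 per clip window")
    for (i in seq_len(n_clips)) {
      loo2_v[i] <- loo2(spo2, clips[[i]]$start_s, clips[[i]]$end_s)
      ref[i] <- loo2_level(loo2_v[i])
    }
  }

  results <- data.frame(
    clip_index = vapply(clips, `[[`, integer(1), "index"),
    label = full_label, mbpi_s = mbpi_s, elapsed_min = elapsed,
    pred_level = pred, loo2 = loo2_v, ref_level = ref,
    stringsAsFactors = FALSE)
  report <- evaluation_report(results)
  report$assignment <- assign
  report$config <- config
  if (is.finite(report$accuracy))
    say("[evaluation] accuracy %.3f (%d/%d, %d uncertain excluded)",
        report$accuracy, report$correct, report$total - report$uncertain,
        report$uncertain)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(results, file.path(out_dir, "results.csv"))
    jsonlite::write_json(
      list(accuracy = report$accuracy, total = report$total,
           uncertain = report$uncertain, correct = report$correct),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    tryCatch({
      grDevices::png(file.path(out_dir, "summary.png"), 900, 700)
      plot_report(report, spo2)
      grDevices::dev.off()
    }, error = function(e) warning("could not write summary plot: ",
                                   conditionMessage(e)))
    say("[io] wrote results to %s", out_dir)
  }
  report
}
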