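# Evaluation against the SpO2 reference: per-window lowest saturation
# (LoO2), its three-level grading, and the uncertain-excluding accuracy.

#' Lowest oxygen saturation in a time window
#'
#' Minimum of the 1 Hz SpO2 samples whose timestamps fall in
#' `[start_s, end_s)`.
#'
#' @param trace an [spo2_trace()].
#' @param start_s,end_s window in seconds (half-open).
#' @return LoO2 in percent.
#' @export
loo2 <- function(trace, start_s, end_s) {
  stopifnot(inherits(trace, "spo2_trace"))
  t <- trace$t0 + seq_along(trace$values) - 1
  idx <- t >= start_s & t < end_s
  if (!any(idx)) stop("empty SpO2 window [", start_s, ", ", end_s, ")")
  min(trace$values[idx])
}

#' Grade a LoO2 value into high / medium / low
#'
#' Above 95% is high; 90-95% (inclusive) is medium (mild hypoxemia); below
#' 90% is low (hypoxemia).
#'
#' @param value LoO2 in percent, within \[0, 100\] (vectorized).
#' @return character vector in `c("high", "medium", "low")`.
#' @export
loo2_level <- function(value) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 100))
    stop("LoO2 values must be within [0, 100]")
  ifelse(value > 95, "high", ifelse(value >= 90, "medium", "low"))
}

#' Prediction accuracy with uncertain clips excluded
#'
#' `accuracy = correct / (total - uncertain)`: clips the pipeline flagged
#' uncertain are excluded from both numerator and denominator.
#'
#' @param preds predicted levels, may contain `"uncertain"`.
#' @param refs reference levels (never uncertain).
#' @return fraction in \[0, 1\], or `NA` (with a warning) when every clip
#'   is uncertain.
#' @export
accuracy <- function(preds, refs) {
  if (length(preds) != length(refs)) stop("preds and refs length mismatch")
  unc <- preds == "uncertain"
  denom <- length(preds) - sum(unc)
  if (denom == 0L) {
    warning("all clips uncertain; accuracy undefined")
    return(NA_real_)
  }
  sum(preds[!unc] == refs[!unc]) / denom
}

#' Build an evaluation report from a results table
#'
#' @param results data.frame with at least `clip_index`, `label`,
#'   `pred_level` and (when a reference exists) `loo2`, `ref_level`.
#' @return object of class `snorevol_report`: the results plus `accuracy`
#'   and the `total` / `uncertain` / `correct` counts.
#' @export
evaluation_report <- function(results) {
  unc <- results$pred_level == "uncertain"
  has_ref <- "ref_level" %in% names(results) && !all(is.na(results$ref_level))
  acc <- NA_real_
  correct <- NA_integer_
  if (has_ref) {
    correct <- sum(results$pred_level[!unc] == results$ref_level[!unc])
    acc <- if (sum(!unc) > 0) correct / sum(!unc) else NA_real_
  }
  structure(list(results = results, accuracy = acc,
                 total = nrow(results), uncertain = sum(unc),
                 correct = correct),
            class = "snorevol_report")
}

#' @export
print.snorevol_report <- function(x, ...) {
  cat(sprintf("<snorevol_report> %d clips (%d uncertain)\n", x$total, x$uncertain))
  cat("  labels: ",
      paste(sprintf("%s=%d", names(table(x$results$label)), table(x$results$label)),
            collapse = ", "), "\n")
  if (is.finite(x$accuracy))
    cat(sprintf("  accuracy (uncertain excluded): %.3f (%d/%d)\n",
                x$accuracy, x$correct, x$total - x$uncertain))
  invisible(x)
}

#' Four-panel summary plot
#'
#' Clip labels, predicted tidal levels, reference LoO2 levels and the raw
#' SpO2 trace, stacked against the minute index.
#'
#' @param report a `snorevol_report`.
#' @param spo2 optionally, the [spo2_trace()] for the bottom panel.
#' @return `report`, invisibly.
#' @export
plot_report <- function(report, spo2 = NULL) {
  res <- report$results
  lab_lv <- c(apneic_snoring = 4, simple_snoring = 3, normal = 2, uncertain = 1)
  lev_lv <- c(high = 3, medium = 2, low = 1, uncertain = 0)
  op <- graphics::par(mfrow = c(if (is.null(spo2)) 3 else 4, 1),
                      mar = c(2.5, 9, 1.5, 1), mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(op))
  step_plot <- function(y, map, main) {
    graphics::plot(res$clip_index, map[y], type = "s", yaxt = "n",
                   xlab = "clip index (min)", ylab = "", main = main,
                   ylim = range(map), col = "steelblue", lwd = 2)
    graphics::axis(2, at = map, labels = names(map), las = 1, cex.axis = 0.8)
  }
  step_plot(res$label, lab_lv, "clip class")
  step_plot(res$pred_level, lev_lv, "predicted tidal level")
  if ("ref_level" %in% names(res) && !all(is.na(res$ref_level))) {
    ref <- ifelse(is.na(res$ref_level), "uncertain", res$ref_level)
    step_plot(ref, lev_lv, "LoO2 level")
  }
  if (!is.null(spo2)) {
    t <- (spo2$t0 + seq_along(spo2$values) - 1) / 60
    graphics::plot(t, spo2$values, type = "l", xlab = "time (min)",
                   ylab = "SpO2 (%)", main = "SpO2", col = "firebrick")
    graphics::abline(h = c(90, 95), lty = 3)
  }
  invisible(report)
}
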