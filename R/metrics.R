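# Recommendation-quality metrics.

#' Recommendation metrics
#'
#' Aggregates per-recommendation confusion counts into:
#' accuracy `A = mean((tp + tn) / (tp + tn + fp + fn))`,
#' precision `P = mean(tp / (tp + fp))`,
#' `R_paper = mean(tp / (tp + tn + fp + fn))` — the model's printed
#' recall, whose denominator duplicates accuracy's — and the
#' conventional recall `R_standard = mean(tp / (tp + fn))`, reported
#' alongside and clearly labelled (neither is silently "corrected").
#' The delay `d = mean(ts_complete - ts_start)` in seconds is
#' hardware-dependent and is reported, never used as an acceptance
#' statistic.
#'
#' A term with a zero denominator is skipped for that metric with a
#' warning; if every term of a metric is skipped an error is raised.
#'
#' @param outcomes Data frame with integer columns `tp`, `tn`, `fp`,
#'   `fn` and numeric `ts_start`, `ts_complete` (seconds), one row per
#'   recommendation.
#' @return A list with `A`, `P`, `R_paper`, `R_standard`, `d` and the
#'   recommendation count `n`.
#' @examples
#' rec_metrics(data.frame(
#'   tp = 3, tn = 2, fp = 1, fn = 2, ts_start = 0, ts_complete = 2
#' ))
#' @export
rec_metrics <- function(outcomes) {
  need <- c("tp", "tn", "fp", "fn", "ts_start", "ts_complete")
  if (!all(need %in% names(outcomes))) {
    stop_fmt("rec_metrics: outcomes must have columns %s", paste(need, collapse = ", "))
  }
  if (!nrow(outcomes)) stop_fmt("rec_metrics: need at least one outcome")
  cnt <- c("tp", "tn", "fp", "fn")
  if (any(outcomes[cnt] < 0)) stop_fmt("rec_metrics: negative counts")
  if (any(outcomes$ts_complete < outcomes$ts_start)) {
    stop_fmt("rec_metrics: ts_complete before ts_start")
  }
  mean_skipping <- function(num, den, label) {
    ok <- den != 0
    if (!any(ok)) stop_fmt("rec_metrics: all %s terms have zero denominator", label)
    if (!all(ok)) warn_fmt("rec_metrics: %d %s term(s) skipped (zero denominator)", sum(!ok), label)
    mean(num[ok] / den[ok])
  }
  tot <- outcomes$tp + outcomes$tn + outcomes$fp + outcomes$fn
  list(
    A = mean_skipping(outcomes$tp + outcomes$tn, tot, "accuracy"),
    P = mean_skipping(outcomes$tp, outcomes$tp + outcomes$fp, "precision"),
    R_paper = mean_skipping(outcomes$tp, tot, "paper-recall"),
    R_standard = mean_skipping(outcomes$tp, outcomes$tp + outcomes$fn, "recall"),
    d = mean(outcomes$ts_complete - outcomes$ts_start),
    n = nrow(outcomes)
  )
}
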