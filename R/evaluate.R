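# Classification metrics (MCC, precision, recall), confusion bookkeeping,
# the probability-score threshold sweep, and test-set model ranking.

#' Confusion counts at a probability-score threshold
#'
#' A compound is predicted active iff `PS > t` (strict inequality: a PS
#' exactly at the threshold is predicted inactive).
#'
#' @param ps numeric probability scores in `[0, 1]`.
#' @param labels `"active"` / `"inactive"`, aligned with `ps`.
#' @param t threshold in `[0, 1]`.
#' @return a `cs_confusion` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_at_threshold <- function(ps, labels, t = 0.5) {
  if (length(ps) != length(labels))
    stop("predictions and labels have different lengths")
  stopifnot(t >= 0, t <= 1, all(labels %in% c("active", "inactive")))
  pred_active <- ps > t
  act <- labels == "active"
  structure(list(TP = sum(pred_active & act),
                 TN = sum(!pred_active & !act),
                 FP = sum(pred_active & !act),
                 FN = sum(!pred_active & act)), class = "cs_confusion")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`; defined as 0 when any denominator factor is zero.
#'
#' @param c a `cs_confusion` (or list with TP, TN, FP, FN).
#' @return numeric scalar.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Precision and recall
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; both defined as 0
#' when the denominator is 0.
#'
#' @inheritParams mcc
#' @return numeric scalar.
#' @export
precision_score <- function(c) {
  if (c$TP + c$FP == 0) return(0)
  c$TP / (c$TP + c$FP)
}

#' @rdname precision_score
#' @export
recall_score <- function(c) {
  if (c$TP + c$FN == 0) return(0)
  c$TP / (c$TP + c$FN)
}

#' Full metrics report at a threshold
#'
#' @inheritParams confusion_at_threshold
#' @return list with `mcc`, `precision`, `recall`, `counts`.
#' @export
metrics_report <- function(ps, labels, t = 0.5) {
  cnt <- confusion_at_threshold(ps, labels, t)
  list(mcc = mcc(cnt), precision = precision_score(cnt),
       recall = recall_score(cnt), counts = cnt)
}

#' Probability-score threshold sweep
#'
#' Evaluates precision, recall and MCC along a threshold grid (default 0.50
#' to 0.90 in steps of 0.05, the hit-prioritization range) and reports the
#' smallest threshold achieving perfect precision, if any. Recall is
#' non-increasing along the sweep.
#'
#' @inheritParams confusion_at_threshold
#' @param grid increasing numeric vector of thresholds.
#' @return list with `curve` (data.frame `threshold`, `precision`, `recall`,
#'   `mcc`, `n_selected`) and `perfect_precision_threshold` (`NA` if never
#'   reached).
#' @export
sweep_thresholds <- function(ps, labels, grid = seq(0.5, 0.9, by = 0.05)) {
  stopifnot(!is.unsorted(grid))
  rows <- lapply(grid, function(t) {
    cnt <- confusion_at_threshold(ps, labels, t)
    data.frame(threshold = t, precision = precision_score(cnt),
               recall = recall_score(cnt), mcc = mcc(cnt),
               n_selected = cnt$TP + cnt$FP)
  })
  curve <- do.call(rbind, rows)
  perfect <- curve$threshold[curve$precision == 1 & curve$n_selected > 0]
  list(curve = curve,
       perfect_precision_threshold = if (length(perfect)) min(perfect) else NA_real_)
}

#' Rank models by test-set MCC
#'
#' @param reports data.frame with columns `algorithm`, `representation`,
#'   `scheme`, `mcc`, `precision`, `recall` (one row per model).
#' @return the same rows sorted by MCC descending, ties broken by precision,
#'   then recall, then the lexicographic model name; adds a `rank` column.
#' @export
rank_models <- function(reports) {
  stopifnot(all(c("algorithm", "representation", "mcc", "precision",
                  "recall") %in% names(reports)))
  nm <- paste(reports$algorithm, reports$representation)
  o <- order(-reports$mcc, -reports$precision, -reports$recall, nm)
  out <- reports[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
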