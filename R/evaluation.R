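#' Contingency table with a suspension row
#'
#' Counts of true/false positives/negatives plus, at well level, decisions
#' suspended by the tie rule, split by their true label. Suspended cases are
#' never counted as TP/FN/FP/TN.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @param suspended_pos,suspended_neg suspended decisions whose truth was
#'   positive / negative.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(tp = 0, fn = 0, fp = 0, tn = 0,
                              suspended_pos = 0, suspended_neg = 0) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn,
         suspended_pos = suspended_pos, suspended_neg = suspended_neg)
  if (any(v < 0) || any(v != round(v))) {
    stop_validation("contingency counts must be non-negative integers")
  }
  structure(as.list(v), total = sum(v), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> tp=%d fn=%d fp=%d tn=%d suspended=%d+%d (n=%d)\n",
              x$tp, x$fn, x$fp, x$tn, x$suspended_pos, x$suspended_neg,
              attr(x, "total")))
  invisible(x)
}

#' Tabulate decisions against truth
#'
#' @param truth character vector of true labels (positive/negative).
#' @param decisions character vector of decisions (positive/negative/
#'   suspended), same length.
#' @return a [contingency_table()].
#' @export
tabulate_decisions <- function(truth, decisions) {
  if (length(truth) != length(decisions)) {
    stop_validation("truth and decisions differ in length (%d vs %d)",
                    length(truth), length(decisions))
  }
  truth <- parse_label(truth, "true label")
  ok <- decisions %in% c(.clift_labels, "suspended")
  if (any(!ok)) {
    stop_validation("invalid decision '%s'", decisions[!ok][1])
  }
  contingency_table(
    tp = sum(truth == "positive" & decisions == "positive"),
    fn = sum(truth == "positive" & decisions == "negative"),
    fp = sum(truth == "negative" & decisions == "positive"),
    tn = sum(truth == "negative" & decisions == "negative"),
    suspended_pos = sum(truth == "positive" & decisions == "suspended"),
    suspended_neg = sum(truth == "negative" & decisions == "suspended"))
}

#' Performance metrics from a contingency table
#'
#' Accuracy, sensitivity, specificity and precision as percentages rounded
#' half-up to one decimal, computed from the integer counts (never chained
#' from rounded values). Suspended decisions count in the denominators of
#' accuracy (all cases) and sensitivity/specificity (their true class) but
#' never in the numerators, and do not touch precision: a suspended well is
#' a well the system declined to score, which costs accuracy and the
#' corresponding recall but does not create a false call. A metric whose
#' denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param table a [contingency_table()].
#' @return list with `accuracy`, `sensitivity`, `specificity`, `precision`
#'   (percent, one decimal, `NA` when undefined).
#' @export
metrics_report <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  total <- attr(table, "total")
  list(accuracy = pct(table$tp + table$tn, total),
       sensitivity = pct(table$tp, table$tp + table$fn + table$suspended_pos),
       specificity = pct(table$tn, table$tn + table$fp + table$suspended_neg),
       precision = pct(table$tp, table$tp + table$fp))
}

#' Contingency report of the threshold-based pre-screening step
#'
#' Splits true-positive and true-negative images by the pre-screen outcome
#' (candidate-positive vs presumed-negative), with row percentages to one
#' decimal, mirroring the standard presentation of a screening step: all
#' stained images should land in the candidate-positive column, while some
#' unstained images leak there through artifacts and distractors.
#'
#' @param truth character vector of true image labels.
#' @param prescreen_labels character vector of `"candidate_positive"` /
#'   `"presumed_negative"` from [prescreen_image()].
#' @return list with `table` (a [contingency_table()]; candidate_positive is
#'   the hypothesized positive) and `rows`, a data.frame of counts and row
#'   percentages.
#' @export
threshold_step_report <- function(truth, prescreen_labels) {
  if (length(truth) != length(prescreen_labels)) {
    stop_validation("truth and prescreen labels differ in length")
  }
  ok <- prescreen_labels %in% c("candidate_positive", "presumed_negative")
  if (any(!ok)) stop_validation("invalid prescreen label '%s'",
                                prescreen_labels[!ok][1])
  dec <- ifelse(prescreen_labels == "candidate_positive", "positive", "negative")
  tab <- tabulate_decisions(truth, dec)
  rowp <- function(a, b) {
    n <- a + b
    if (n == 0) c(NA_real_, NA_real_)
    else c(round_half_up(100 * a / n, 1), round_half_up(100 * b / n, 1))
  }
  pos <- rowp(tab$tp, tab$fn)
  neg <- rowp(tab$fp, tab$tn)
  rows <- data.frame(
    true_class = c("positive", "negative"),
    candidate_positive = c(tab$tp, tab$fp),
    presumed_negative = c(tab$fn, tab$tn),
    pct_candidate_positive = c(pos[1], neg[1]),
    pct_presumed_negative = c(pos[2], neg[2]))
  list(table = tab, rows = rows)
}
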