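# Site-recognition performance measures: Sn, Sp, AC and the Matthews-style
# correlation coefficient computed from confusion counts.

#' Construct confusion counts
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return an object of class `promcnn_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_data("confusion counts must be nonnegative integers")
  structure(as.list(counts), class = "promcnn_confusion")
}

#' @export
print.promcnn_confusion <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Tally predictions against labels
#'
#' @param labels,predictions equal-length vectors of classes; anything
#'   equal to `positive` counts as the positive (promoter) class.
#' @param positive value denoting the positive class (default
#'   `"promoter"`; use `TRUE` for logical vectors).
#' @return a `promcnn_confusion`.
#' @examples
#' tally(c("promoter", "nonpromoter"), c("promoter", "promoter"))
#' @export
tally <- function(labels, predictions, positive = "promoter") {
  if (length(labels) != length(predictions))
    stop_data("labels (%d) and predictions (%d) differ in length",
              length(labels), length(predictions))
  if (length(labels) == 0L)
    stop_data("cannot tally empty inputs")
  lab <- labels == positive
  pred <- predictions == positive
  confusion_counts(tp = sum(lab & pred), fp = sum(!lab & pred),
                   tn = sum(!lab & !pred), fn = sum(lab & !pred))
}

#' Sensitivity, specificity, accuracy and correlation coefficient
#'
#' The standard measures of site-recognition accuracy, computed from
#' confusion counts: sensitivity (true positive rate) Sn = TP/(TP+FN),
#' specificity (true negative rate) Sp = TN/(TN+FP), accuracy
#' AC = (TP+TN)/(TP+TN+FP+FN), and the correlation coefficient
#'
#' \deqn{CC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#'
#' which accounts for unequal positive/negative set sizes. All four are
#' computed in double precision with no rounding.
#'
#' @param c a `promcnn_confusion`.
#' @param degenerate for `correlation_coefficient`: `"error"` (default)
#'   raises an error when any marginal sum is zero; `"zero"` returns 0
#'   instead, flagged with attribute `degenerate = TRUE`.
#' @return a numeric scalar.
#' @name performance_measures
NULL

#' @rdname performance_measures
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "promcnn_confusion"))
  if (c$TP + c$FN == 0)
    stop_data("sensitivity undefined: no positive examples (TP+FN = 0)")
  c$TP / (c$TP + c$FN)
}

#' @rdname performance_measures
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "promcnn_confusion"))
  if (c$TN + c$FP == 0)
    stop_data("specificity undefined: no negative examples (TN+FP = 0)")
  c$TN / (c$TN + c$FP)
}

#' @rdname performance_measures
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "promcnn_confusion"))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop_data("accuracy undefined: no examples")
  (c$TP + c$TN) / total
}

#' @rdname performance_measures
#' @export
correlation_coefficient <- function(c, degenerate = c("error", "zero")) {
  stopifnot(inherits(c, "promcnn_confusion"))
  degenerate <- match.arg(degenerate)
  margins <- c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, c$TN + c$FN)
  if (any(margins == 0)) {
    if (degenerate == "zero")
      return(structure(0, degenerate = TRUE))
    stop_data("correlation coefficient undefined: zero marginal sum(s) %s",
              paste(c("TP+FP", "TP+FN", "TN+FP", "TN+FN")[margins == 0],
                    collapse = ", "))
  }
  # product of four counts can overflow integers; work in doubles
  (as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN) /
    sqrt(prod(as.numeric(margins)))
}

#' Assemble a full evaluation report
#'
#' @param c a `promcnn_confusion`.
#' @return a `promcnn_report`: the counts plus Sn, Sp, AC, CC.
#' @export
metrics_report <- function(c) {
  stopifnot(inherits(c, "promcnn_confusion"))
  structure(list(counts = c,
                 Sn = sensitivity(c), Sp = specificity(c),
                 AC = accuracy(c),
                 CC = correlation_coefficient(c, degenerate = "zero")),
            class = "promcnn_report")
}

#' @export
print.promcnn_report <- function(x, digits = 2, ...) {
  print(x$counts)
  cat(sprintf("Sn = %.*f  Sp = %.*f  AC = %.*f  CC = %.*f\n",
              digits, x$Sn, digits, x$Sp, digits, x$AC, digits, x$CC))
  invisible(x)
}

#' Write an evaluation report as key/value text
#'
#' @param report a `promcnn_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  c <- report$counts
  lines <- c(sprintf("TP\t%d", c$TP), sprintf("FP\t%d", c$FP),
             sprintf("TN\t%d", c$TN), sprintf("FN\t%d", c$FN),
             sprintf("Sn\t%.6f", report$Sn), sprintf("Sp\t%.6f", report$Sp),
             sprintf("AC\t%.6f", report$AC), sprintf("CC\t%.6f", report$CC))
  writeLines(lines, path)
  invisible(path)
}
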