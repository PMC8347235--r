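#' Confusion-matrix classification metrics
#'
#' The nine validation statistics reported for every filter of the
#' screening workflow: sensitivity, specificity, precision, fall-out,
#' false negative rate, false discovery rate, accuracy, F1 score and the
#' Matthews correlation coefficient. Ratios with a zero denominator are
#' returned as `NaN` rather than silently coerced to 0, so degenerate
#' validation folds stay visible in reports.
#'
#' @param tp,fp,tn,fn confusion-matrix counts (non-negative).
#' @return Object of class `classifier_metrics`: a named numeric vector
#'   of the nine statistics.
#' @examples
#' compute_metrics(tp = 9, fp = 1, tn = 9, fn = 1)  # MCC = 0.8
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) stop("all-zero confusion matrix")
  div <- function(num, den) if (den == 0) NaN else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  acc <- div(tp + tn, tp + fp + tn + fn)
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mden == 0) NaN else (tp * tn - fp * fn) / mden
  structure(c(sensitivity = sens, specificity = spec, precision = prec,
              fall_out = 1 - spec, false_negative_rate = 1 - sens,
              false_discovery_rate = 1 - prec, accuracy = acc,
              f1_score = f1, matthews_cc = mcc),
            class = c("classifier_metrics", "numeric"))
}

#' @export
print.classifier_metrics <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Average metrics across folds
#'
#' @param metrics_list list of `classifier_metrics`.
#' @return `classifier_metrics` of element-wise means (`NaN`-propagating).
#' @export
mean_metrics <- function(metrics_list) {
  m <- do.call(rbind, lapply(metrics_list, unclass))
  structure(colMeans(m), class = c("classifier_metrics", "numeric"))
}

#' Write metrics rows as a TSV report
#'
#' Columns follow the standard report order (sensitivity ... MCC), one
#' row per named entry.
#'
#' @param metrics named list of `classifier_metrics`.
#' @param path output path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  m <- do.call(rbind, lapply(metrics, unclass))
  df <- data.frame(model = names(metrics), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
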