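#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted vectors of class labels (coerced to a common
#'   factor).
#' @param levels optional explicit class levels.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusionCounts <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- union(levels(factor(truth)),
                                       levels(factor(predicted)))
  t <- factor(truth, levels = levels)
  p <- factor(predicted, levels = levels)
  m <- table(truth = t, predicted = p)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(truth = levels, predicted = levels))
}

#' Macro-averaged classification metrics from a confusion matrix
#'
#' One-vs-rest TP/TN/FP/FN per class feed the standard definitions:
#' accuracy \eqn{(TP+TN)/(TP+FN+FP+TN)} computed micro (trace/total, which
#' coincides with the one-vs-rest form for the multiclass trace);
#' sensitivity \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)}, precision
#' \eqn{TP/(TP+FP)}, F-measure (harmonic mean of precision and
#' sensitivity) and G-mean \eqn{\sqrt{sensitivity \times specificity}}
#' computed per class and then averaged (macro). A class with a zero
#' denominator contributes 0 to the mean and is reported in `flagged` with
#' a warning.
#'
#' @param cm K x K count matrix, rows = true class, columns = predicted,
#'   total > 0.
#' @return a [MetricReport-class].
#' @examples
#' cm <- diag(4) * 180
#' computeMetrics(cm)   # all metrics 1
#' @export
computeMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be >= 0")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(K))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  g <- sqrt(sens * spec)
  flagged <- classes[tp + fp == 0]
  if (length(flagged))
    warning("no predictions for class(es) ", paste(flagged, collapse = ", "),
            "; precision contributes 0")
  per <- data.frame(class = classes, TP = tp, TN = tn, FP = fp, FN = fn,
                    sensitivity = sens, specificity = spec, precision = prec,
                    fMeasure = f, gMean = g, row.names = NULL)
  new("MetricReport", accuracy = sum(tp) / total, sensitivity = mean(sens),
      specificity = mean(spec), precision = mean(prec), fMeasure = mean(f),
      gMean = mean(g), perClass = per, flagged = flagged)
}

#' Write a MetricReport to disk
#'
#' @param report a [MetricReport-class].
#' @param path output path.
#' @param format `"json"` (includes the per-class table) or `"csv"` (one row
#'   in the conventional column order Accuracy, Sensitivity, Specificity,
#'   Precision, F-Measure, G-Mean).
#' @return invisibly, `path`.
#' @export
writeMetricReport <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(accuracy = report@accuracy, sensitivity = report@sensitivity,
           specificity = report@specificity, precision = report@precision,
           f_measure = report@fMeasure, g_mean = report@gMean,
           per_class = report@perClass, flagged = report@flagged),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
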