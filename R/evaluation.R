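#' Construct confusion counts from the four cells
#'
#' @param tp,tn,fp,fn non-negative counts; reals are accepted so cells
#'   reconstructed from published rates are represented exactly.
#' @return a [ConfusionCounts].
#' @export
confusionCountsFromCells <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

#' Tally a prediction against the truth
#'
#' Element-wise confusion counts over two equal-length label vectors (or
#' [ResidueLabelTrack] pairs, whose residue identities must agree).
#'
#' @param predicted,truth vectors coded 0/1 or -1/+1, or two
#'   [ResidueLabelTrack] objects.
#' @return a [ConfusionCounts].
#' @export
confusionCounts <- function(predicted, truth) {
  if (is(predicted, "ResidueLabelTrack") && is(truth, "ResidueLabelTrack")) {
    .stop_if(!identical(predicted@residues[, c("resno", "insert")],
                        truth@residues[, c("resno", "insert")]),
             "residue identities of the two tracks do not match")
    predicted <- siteLabels(predicted)
    truth <- siteLabels(truth)
  }
  .stop_if(length(predicted) != length(truth),
           "predicted and truth must have equal length")
  p <- .as_pm1(predicted)
  t <- .as_pm1(truth)
  confusionCountsFromCells(sum(p == 1L & t == 1L), sum(p == -1L & t == -1L),
                           sum(p == 1L & t == -1L), sum(p == -1L & t == 1L))
}

#' @describeIn confusionCountsFromCells the four cells as a named vector.
#' @param x a [ConfusionCounts].
#' @export
countCells <- function(x) c(TP = x@tp, TN = x@tn, FP = x@fp, FN = x@fn)

setMethod("show", "ConfusionCounts", function(object) {
  v <- countCells(object)
  cat("ConfusionCounts:",
      paste(names(v), format(v), sep = "=", collapse = " "), "\n")
})

#' The six performance measures from confusion counts
#'
#' accuracy = (TP+TN)/total; sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP); strength = (sensitivity+specificity)/2
#' (the fair balance measure on imbalanced residue data);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN));
#' F-measure = 2 * precision * sensitivity / (precision + sensitivity)
#' with precision = TP/(TP+FP). A measure whose denominator is zero is
#' reported as NA with its \code{defined} flag FALSE -- never coerced to 0.
#'
#' @param counts a [ConfusionCounts] with positive total.
#' @return a [MetricSet].
#' @export
computeMetrics <- function(counts) {
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  .stop_if(total <= 0, "all-zero confusion counts")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  prec <- sdiv(tp, tp + fp)
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  v <- c(
    accuracy = (tp + tn) / total,
    sensitivity = sens,
    specificity = spec,
    strength = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    mcc = if (mcc_den2 > 0) (tp * tn - fp * fn) / sqrt(mcc_den2) else NA_real_,
    f_measure = if (is.na(prec) || is.na(sens) || (prec + sens) == 0)
      NA_real_ else 2 * prec * sens / (prec + sens))
  new("MetricSet", values = v, defined = !is.na(v))
}

#' @describeIn computeMetrics the named measure vector of a [MetricSet].
#' @param x a [MetricSet].
#' @export
metricValues <- function(x) x@values

#' @describeIn computeMetrics which measures were defined (non-zero
#'   denominator).
#' @export
metricDefined <- function(x) x@defined

setMethod("show", "MetricSet", function(object) {
  v <- object@values
  s <- ifelse(object@defined, sprintf("%.4f", v), "undef")
  cat("MetricSet:", paste(names(v), s, sep = "=", collapse = " "), "\n")
})

#' Reconstruct confusion counts from published rates
#'
#' Given a method's published sensitivity and specificity and the class
#' totals of the benchmark (e.g. 5342 binding and 67396 non-binding
#' residues), recovers the real-valued confusion cells:
#' TP = sensitivity * P, FN = P - TP, TN = specificity * N, FP = N - TN.
#' This makes published summary tables checkable: [computeMetrics()] on
#' the result reproduces the remaining printed columns.
#'
#' @param sensitivity,specificity rates in [0, 1].
#' @param positives,negatives class totals (> 0).
#' @return a [ConfusionCounts] (real-valued cells).
#' @export
reconstructCounts <- function(sensitivity, specificity, positives, negatives) {
  .stop_if(sensitivity < 0 || sensitivity > 1 ||
             specificity < 0 || specificity > 1,
           "rates must lie in [0, 1]")
  .stop_if(positives <= 0 || negatives <= 0, "class totals must be > 0")
  tp <- sensitivity * positives
  tn <- specificity * negatives
  confusionCountsFromCells(tp, tn, negatives - tn, positives - tp)
}

#' Published benchmark rates of the stacked predictor and its six bases
#'
#' Reported 10-fold cross-validation results on the PDNA-316 benchmark
#' (316 non-redundant protein-DNA complexes; 5342 binding and 67396
#' non-binding residues under the 3.5 A any-atom distance definition):
#' the stacked meta-predictor and the six sequence-based base predictors
#' it integrates. Values are as printed (2 decimals).
#'
#' @return list with \code{positives}, \code{negatives} and \code{table}
#'   (data.frame: method, accuracy, sensitivity, specificity, strength,
#'   mcc, f_measure).
#' @export
publishedBenchmark <- function() {
  tab <- data.frame(
    method = c("meta", "bindn", "bindn_rf", "dbs_pred", "disis",
               "dnabindr", "dpbind"),
    accuracy    = c(0.77, 0.78, 0.82, 0.75, 0.92, 0.73, 0.78),
    sensitivity = c(0.77, 0.54, 0.67, 0.53, 0.19, 0.66, 0.69),
    specificity = c(0.77, 0.80, 0.83, 0.76, 0.98, 0.74, 0.79),
    strength    = c(0.77, 0.67, 0.75, 0.65, 0.59, 0.70, 0.74),
    mcc         = c(0.32, 0.21, 0.32, 0.17, 0.25, 0.23, 0.29),
    f_measure   = c(0.33, 0.26, 0.34, 0.23, 0.27, 0.26, 0.31),
    stringsAsFactors = FALSE)
  list(positives = 5342, negatives = 67396, table = tab)
}

#' Check the published benchmark table by count reconstruction
#'
#' For every row of [publishedBenchmark()], reconstructs the confusion
#' cells from the printed sensitivity/specificity and the class totals,
#' recomputes all six measures, rounds half-up to 2 decimals, and compares
#' against the printed cells. The printed rates are themselves rounded, so
#' derived cells can disagree in the last decimal; the returned grid
#' reports each comparison rather than asserting any.
#'
#' @param benchmark list as returned by [publishedBenchmark()].
#' @return data.frame with one row per (method, measure): \code{printed},
#'   \code{reconstructed} (half-up, 2 dp), \code{exact} (unrounded), and
#'   \code{match}.
#' @export
checkBenchmarkTable <- function(benchmark = publishedBenchmark()) {
  tab <- benchmark$table
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cc <- reconstructCounts(tab$sensitivity[i], tab$specificity[i],
                            benchmark$positives, benchmark$negatives)
    v <- metricValues(computeMetrics(cc))
    out[[i]] <- data.frame(
      method = tab$method[i], measure = .metric_names,
      printed = as.numeric(tab[i, .metric_names]),
      exact = as.numeric(v[.metric_names]),
      reconstructed = roundHalfUp(as.numeric(v[.metric_names]), 2L),
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  grid$match <- grid$reconstructed == grid$printed
  grid
}

#' Write a metrics report TSV
#'
#' One row per method with the six measures, in the conventional column
#' order: method, accuracy, sensitivity, specificity, strength, MCC,
#' F-measure.
#'
#' @param metricList named list of [MetricSet] objects (names = methods).
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeMetricsReport <- function(metricList, file) {
  rows <- do.call(rbind, lapply(names(metricList), function(m) {
    v <- metricValues(metricList[[m]])
    data.frame(method = m, t(v), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
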