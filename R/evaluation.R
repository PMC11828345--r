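# Confusion matrices and multiclass metrics.
#
# All metrics derive from the K x K confusion matrix (rows = true class,
# columns = predicted class) through the one-vs-rest reduction: for class k,
# TP is the diagonal entry, FN the rest of row k, FP the rest of column k and
# TN everything else. Precision = TP/(TP+FP), recall = TP/(TP+FN),
# F1 = 2PR/(P+R) with 0/0 defined as 0, per-class accuracy =
# (TP+TN)/total, overall accuracy = trace/total and error rate its
# complement. Published per-class tables in this field mix conventions (a
# "per-class accuracy" column is often one-vs-rest recall), so the report
# always carries per-class values plus all three aggregations -- micro,
# macro and support-weighted -- explicitly labelled.

#' Build a confusion matrix from label vectors
#'
#' @param true_labels,predicted_labels Equal-length vectors; either factors/
#'   character drawn from `labels`, or integers in 1..K.
#' @param labels Class vocabulary (defaults to [hrem_classes()] for character
#'   input, or `1..max` for integer input).
#' @return A K x K integer matrix with `dimnames`, rows = true classes.
#' @export
#' @examples
#' build_confusion(c("Normal", "DES"), c("Normal", "Normal"),
#'                 labels = hrem_classes())
build_confusion <- function(true_labels, predicted_labels, labels = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (is.numeric(true_labels)) {
      as.character(seq_len(max(c(true_labels, predicted_labels, 1))))
    } else {
      hrem_classes()
    }
  }
  to_idx <- function(x, what) {
    if (is.numeric(x)) {
      if (length(x) && (any(x < 1) || any(x > length(labels)) ||
                        any(x != round(x)))) {
        stop(sprintf("%s out of range 1..%d", what, length(labels)),
             call. = FALSE)
      }
      as.integer(x)
    } else {
      i <- match(as.character(x), labels)
      if (anyNA(i)) {
        stop(sprintf("%s contains labels outside the vocabulary: %s", what,
                     paste(unique(x[is.na(i)]), collapse = ", ")),
             call. = FALSE)
      }
      i
    }
  }
  ti <- to_idx(true_labels, "true_labels")
  pi_ <- to_idx(predicted_labels, "predicted_labels")
  K <- length(labels)
  cm <- matrix(0L, K, K, dimnames = list(true = labels, predicted = labels))
  for (i in seq_along(ti)) cm[ti[i], pi_[i]] <- cm[ti[i], pi_[i]] + 1L
  cm
}

#' Metrics from a confusion matrix
#'
#' @param cm K x K count matrix, rows = true class; total must be positive.
#' @return An object of class `"mae_metrics"`: a list with
#'   \describe{
#'     \item{overall}{`accuracy`, `error_rate` (= 1 - accuracy) and `n`.}
#'     \item{per_class}{data.frame with support, TP/FP/FN/TN, precision,
#'       recall, f1 and one-vs-rest accuracy per class.}
#'     \item{aggregate}{data.frame with micro, macro and support-weighted
#'       precision/recall/f1.}
#'   }
#'   All values are fractions in \[0, 1\].
#' @export
metrics_from_confusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("`cm` must be a square matrix", call. = FALSE)
  }
  if (any(cm < 0)) stop("negative counts in confusion matrix", call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  K <- nrow(cm)
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(K))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  if (any(support == 0)) {
    warning(sprintf("zero-support class(es): %s; their precision/recall are 0",
                    paste(labels[support == 0], collapse = ", ")))
  }
  per_class <- data.frame(
    class = labels, support = support, tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / total, # one-vs-rest accuracy
    row.names = NULL, stringsAsFactors = FALSE
  )
  micro_p <- sum(tp) / sum(tp + fp) # = trace/total for single-label data
  micro_r <- sum(tp) / sum(tp + fn)
  micro_f <- safe_div(2 * micro_p * micro_r, micro_p + micro_r)
  wts <- support / total
  aggregate <- data.frame(
    average = c("micro", "macro", "weighted"),
    precision = c(micro_p, mean(precision), sum(wts * precision)),
    recall = c(micro_r, mean(recall), sum(wts * recall)),
    f1 = c(micro_f, mean(f1), sum(wts * f1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      overall = list(accuracy = sum(tp) / total,
                     error_rate = 1 - sum(tp) / total, n = total),
      per_class = per_class,
      aggregate = aggregate,
      confusion = cm
    ),
    class = "mae_metrics"
  )
}

#' @export
print.mae_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("Multiclass metrics on %d samples\n", x$overall$n))
  cat(sprintf("  accuracy: %.*f   error rate: %.*f\n",
              digits, x$overall$accuracy, digits, x$overall$error_rate))
  cat("\nPer class:\n")
  pc <- x$per_class[c("class", "support", "precision", "recall", "f1")]
  pc[3:5] <- lapply(pc[3:5], round, digits)
  print(pc, row.names = FALSE)
  cat("\nAggregated:\n")
  ag <- x$aggregate
  ag[2:4] <- lapply(ag[2:4], round, digits)
  print(ag, row.names = FALSE)
  invisible(x)
}

#' Write metrics to JSON / CSV
#'
#' @param metrics An object from [metrics_from_confusion()].
#' @param json_path,csv_path,confusion_csv_path Optional output paths; only
#'   non-`NULL` ones are written.
#' @return `metrics`, invisibly.
#' @export
write_metrics <- function(metrics, json_path = NULL, csv_path = NULL,
                          confusion_csv_path = NULL) {
  stopifnot(inherits(metrics, "mae_metrics"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(overall = metrics$overall, per_class = metrics$per_class,
           aggregate = metrics$aggregate),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    write.csv(metrics$per_class, csv_path, row.names = FALSE)
  }
  if (!is.null(confusion_csv_path)) {
    write.csv(as.data.frame(metrics$confusion), confusion_csv_path)
  }
  invisible(metrics)
}
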