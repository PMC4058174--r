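#' Confusion counts for two-class predictions
#'
#' TP counts positives classified correctly, FP negatives classified as
#' positive, TN negatives classified correctly, FN positives classified
#' as negative.
#'
#' @param truth,pred Vectors of labels in `{-1, +1}`, equal length.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("'truth' and 'pred' must have the same length")
  if (length(truth) < 1L) stop("need at least one sample")
  if (!all(truth %in% c(-1, 1)) || !all(pred %in% c(-1, 1)))
    stop("labels must be -1 or +1")
  c(TP = sum(truth == 1 & pred == 1),
    FP = sum(truth == -1 & pred == 1),
    TN = sum(truth == -1 & pred == -1),
    FN = sum(truth == 1 & pred == -1))
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `SE = TP/(TP+FN)`, specificity
#' `SP = TN/(TN+FP)`, accuracy `ACC = (TP+TN)/total`, Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`,
#' precision `P = TP/(TP+FP)`, recall `R = SE` and
#' `F1 = 2*P*R/(P+R)`.  SE, SP and ACC are reported as percentages;
#' MCC, P, R and F1 as fractions.  Any metric whose denominator is zero
#' is reported as 0 and its name recorded in the `degenerate` field.
#'
#' @param TP,FP,TN,FN Non-negative confusion counts, or `TP` may be a
#'   named vector as returned by [confusion_counts()].
#' @return An object of class `"dbp_metrics"`: a list with the counts,
#'   `SE`, `SP`, `ACC` (percent), `MCC`, `P`, `R`, `F1` (fractions) and
#'   `degenerate` (character vector of zero-denominator metrics).
#' @examples
#' classification_metrics(3, 1, 4, 2)
#' @export
classification_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4L && !is.null(names(TP))) {
    cc <- TP
    TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  }
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total < 1) stop("need at least one evaluated sample")
  degenerate <- character(0)
  frac <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  SE <- frac(TP, TP + FN, "SE")
  SP <- frac(TN, TN + FP, "SP")
  P <- frac(TP, TP + FP, "P")
  R <- SE
  F1 <- frac(2 * P * R, P + R, "F1")
  mcc_den <- sqrt(prod(c(TP + FN, TP + FP, TN + FP, TN + FN)))
  MCC <- frac(TP * TN - FP * FN, mcc_den, "MCC")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 SE = 100 * SE, SP = 100 * SP,
                 ACC = 100 * (TP + TN) / total,
                 MCC = MCC, P = P, R = R, F1 = F1,
                 degenerate = degenerate),
            class = "dbp_metrics")
}

#' @export
print.dbp_metrics <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("ACC %.2f%%  SE %.2f%%  SP %.2f%%  F1 %.2f%%  MCC %.2f\n",
              x$ACC, x$SE, x$SP, 100 * x$F1, x$MCC))
  if (length(x$degenerate))
    cat("zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a metrics report to a one-row data frame
#'
#' @param x A `"dbp_metrics"` object.
#' @param ... Unused.
#' @return One-row `data.frame` with the counts and metric columns.
#' @export
as.data.frame.dbp_metrics <- function(x, ...) {
  data.frame(TP = x$TP, FP = x$FP, TN = x$TN, FN = x$FN,
             ACC = x$ACC, MCC = x$MCC, SE = x$SE, SP = x$SP,
             P = x$P, R = x$R, F1 = x$F1)
}

#' Evaluate a trained ensemble on a labelled test set
#'
#' @param model A fitted [unbalanced_adaboost()] model.
#' @param x Test feature matrix (training-time layout).
#' @param y True labels in `{-1, +1}`.
#' @param ids Optional record identifiers for the prediction table.
#' @return A list with `metrics` (a `"dbp_metrics"` report) and
#'   `predictions` (a `data.frame` with `id`, `true`, `pred`, `score`).
#' @export
evaluate_model <- function(model, x, y, ids = NULL) {
  if (nrow(x) != length(y)) stop("'x' and 'y' sizes differ")
  pr <- predict(model, x)
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  preds <- data.frame(id = ids, true = as.integer(y),
                      pred = as.integer(pr$label), score = pr$score,
                      stringsAsFactors = FALSE)
  list(metrics = classification_metrics(confusion_counts(y, pr$label)),
       predictions = preds)
}
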