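## Confusion matrices and recall / PPV / F1 evaluation.

#' Build a confusion matrix from label sequences
#'
#' Rows are gold-standard classes, columns the automated classification:
#' `counts[i, j]` is the number of items with gold class i predicted as j.
#'
#' @param gold character vector of gold-standard labels.
#' @param predicted character vector of predicted labels, same length.
#' @param classOrder class labels fixing row/column order; defaults to the
#'   canonical order of the labels present.
#' @return a [ConfusionMatrix-class].
#' @export
#' @examples
#' cm <- confusionMatrix(c("a", "a", "b"), c("a", "b", "b"),
#'                       classOrder = c("a", "b"))
#' confusionCounts(cm)
confusionMatrix <- function(gold, predicted, classOrder = NULL) {
  if (length(gold) != length(predicted))
    stopValidation("gold and predicted must have equal length")
  if (is.null(classOrder)) {
    present <- unique(c(gold, predicted))
    classOrder <- if (all(present %in% classLabels()))
      intersect(classLabels(), present) else sort(present)
  }
  bad <- setdiff(unique(c(gold, predicted)), classOrder)
  if (length(bad))
    stopValidation("label(s) outside classOrder: ", paste(bad, collapse = ", "))
  counts <- table(factor(gold, levels = classOrder),
                  factor(predicted, levels = classOrder))
  counts <- matrix(as.integer(counts), nrow = length(classOrder),
                   dimnames = list(gold = classOrder,
                                   predicted = classOrder))
  new("ConfusionMatrix", counts = counts, classOrder = classOrder)
}

#' Wrap an existing count matrix as a ConfusionMatrix
#'
#' @param counts K x K matrix, gold rows x predicted columns; dimnames
#'   supply the class order unless `classOrder` is given.
#' @param classOrder optional class labels.
#' @return a [ConfusionMatrix-class].
#' @export
asConfusionMatrix <- function(counts, classOrder = NULL) {
  counts <- as.matrix(counts)
  if (is.null(classOrder)) classOrder <- rownames(counts)
  if (is.null(classOrder))
    stopValidation("classOrder required when counts has no rownames")
  dimnames(counts) <- list(gold = classOrder, predicted = classOrder)
  new("ConfusionMatrix", counts = counts, classOrder = classOrder)
}

#' Per-class recall, PPV and F1
#'
#' `recall = diag / row total`, `ppv = diag / column total`, and F1 is the
#' harmonic mean of the unrounded recall and PPV.  Reported two-decimal
#' values use truncation, not rounding (see [truncate2()]); full-precision
#' values are retained alongside.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return data.frame with columns `class`, `recall`, `ppv`, `f1` (full
#'   precision) and `recall_2`, `ppv_2`, `f1_2` (truncated); attributes
#'   `macro_recall`, `macro_ppv`, `macro_f1` hold unweighted means of the
#'   unrounded per-class values.
#' @export
classMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  counts <- cm@counts
  rowTot <- rowSums(counts)
  colTot <- colSums(counts)
  if (any(rowTot == 0))
    stopValidation("recall undefined: gold class(es) with zero total: ",
                   paste(cm@classOrder[rowTot == 0], collapse = ", "))
  if (any(colTot == 0))
    stopValidation("ppv undefined: no predictions for class(es): ",
                   paste(cm@classOrder[colTot == 0], collapse = ", "))
  d <- diag(counts)
  recall <- d / rowTot
  ppv <- d / colTot
  f1 <- ifelse(recall + ppv > 0, 2 * recall * ppv / (recall + ppv), 0)
  out <- data.frame(class = cm@classOrder, recall = recall, ppv = ppv,
                    f1 = f1, recall_2 = truncate2(recall),
                    ppv_2 = truncate2(ppv), f1_2 = truncate2(f1),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "macro_recall") <- mean(recall)
  attr(out, "macro_ppv") <- mean(ppv)
  attr(out, "macro_f1") <- mean(f1)
  out
}

#' Macro-averaged F1
#'
#' Unweighted mean of the unrounded per-class F1 scores.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param truncated if TRUE (default) truncate the result to two decimals,
#'   the reporting convention; FALSE returns full precision.
#' @return macro F1 in \[0, 1\].
#' @export
macroF1 <- function(cm, truncated = TRUE) {
  m <- attr(classMetrics(cm), "macro_f1")
  if (truncated) truncate2(m) else m
}

#' Example confusion matrices of a generalized and a specialized model
#'
#' Two confusion matrices shipped with the package as worked evaluation
#' examples: a 3-class generalized iEEG model tested across acquisition
#' systems, and a 4-class specialized model (adding a 60 Hz line-noise
#' class) produced by transfer learning.
#'
#' @param which "generalized" or "specialized".
#' @return a [ConfusionMatrix-class].
#' @export
#' @examples
#' macroF1(exampleConfusionMatrix("generalized"))  # 0.81
exampleConfusionMatrix <- function(which = c("generalized", "specialized")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("confusion_", which, ".tsv"),
                      package = "ieegnoise", mustWork = TRUE)
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  asConfusionMatrix(as.matrix(tab), classOrder = rownames(tab))
}
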