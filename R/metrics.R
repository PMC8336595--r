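#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic from midranks; tied scores count one half.
#'
#' @param y_true Binary labels (both classes must be present).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics at a threshold
#'
#' Computes the confusion counts at \code{score > threshold} (strict) and the
#' standard rates: accuracy, precision, sensitivity, specificity, F1, the
#' Matthews correlation coefficient and rank-statistic AUC. Rates with a zero
#' denominator are reported as 0 and listed in \code{degenerate}.
#'
#' @param y_true Binary labels.
#' @param scores Scores in \[0, 1\].
#' @param threshold Call threshold (default 0.5, strict inequality).
#' @return A \code{metric_report} list with fields \code{TP, FP, FN, TN},
#'   the seven metrics and \code{degenerate}.
#' @export
evaluate_binary <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  stopifnot(all(y %in% c(0L, 1L)))
  call <- as.integer(scores > threshold)
  TP <- sum(call == 1L & y == 1L); FP <- sum(call == 1L & y == 0L)
  FN <- sum(call == 0L & y == 1L); TN <- sum(call == 0L & y == 0L)
  degenerate <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  prec <- rate(TP, TP + FP, "precision")
  sens <- rate(TP, TP + FN, "sensitivity")
  spec <- rate(TN, TN + FP, "specificity")
  f1 <- if (prec + sens == 0) { degenerate <- c(degenerate, "f1"); 0 }
        else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 }
         else (TP * TN - FP * FN) / mcc_den
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 accuracy = (TP + TN) / length(y),
                 precision = prec, sensitivity = sens, specificity = spec,
                 f1 = f1, mcc = mcc,
                 auc = auc_rank(y, scores),
                 degenerate = degenerate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  for (m in c("accuracy", "precision", "sensitivity", "specificity", "f1", "mcc", "auc"))
    cat(sprintf("%-12s %.4f\n", m, x[[m]]))
  if (length(x$degenerate))
    cat("zero-denominator (reported as 0):", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
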