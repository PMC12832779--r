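# Classification metrics with bootstrap confidence intervals.

#' Rank-statistic AUC
#'
#' Wilcoxon/Mann-Whitney form with mid-ranks for ties; equals the probability
#' that a random positive scores above a random negative (+ half the tie
#' probability).
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 vector.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a threshold
#'
#' @param scores numeric scores (probability of class 1).
#' @param labels binary 0/1 vector.
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  c(TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' Accuracy from confusion counts: (TP + TN) / (TP + TN + FP + FN)
#' @param counts named vector from [confusion_counts()] (or TP, TN, FP, FN).
#' @export
accuracy_from_counts <- function(counts) {
  unname((counts["TP"] + counts["TN"]) / sum(counts[c("TP", "TN", "FP", "FN")]))
}

#' F1 score from confusion counts: 2 TP / (2 TP + FP + FN)
#' @param counts named vector from [confusion_counts()].
#' @export
f1_from_counts <- function(counts) {
  unname(2 * counts["TP"] / (2 * counts["TP"] + counts["FP"] + counts["FN"]))
}

# percentile bootstrap over subjects for one task's metrics
boot_metrics <- function(scores, labels, n_boot, conf = 0.95) {
  point <- c(AUC = auc_rank(scores, labels),
             ACC = accuracy_from_counts(confusion_counts(scores, labels)),
             F1 = f1_from_counts(confusion_counts(scores, labels)))
  n <- length(scores)
  bs <- matrix(NA_real_, n_boot, 3L,
               dimnames = list(NULL, c("AUC", "ACC", "F1")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cc <- confusion_counts(scores[idx], labels[idx])
    bs[b, ] <- c(auc_rank(scores[idx], labels[idx]),
                 accuracy_from_counts(cc), f1_from_counts(cc))
  }
  a <- (1 - conf) / 2
  lo <- apply(bs, 2L, stats::quantile, probs = a, na.rm = TRUE, names = FALSE)
  hi <- apply(bs, 2L, stats::quantile, probs = 1 - a, na.rm = TRUE,
              names = FALSE)
  list(point = point, lower = stats::setNames(lo, names(point)),
       upper = stats::setNames(hi, names(point)),
       counts = confusion_counts(scores, labels))
}
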