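#' ROC curve, AUC and the Youden-index optimal cutoff
#'
#' Sweeps the decision rule "positive when score >= cutoff" over every
#' distinct score value (plus a cutoff above the maximum, giving the
#' all-negative corner) and records sensitivity and specificity at each.
#' The AUC is the area under the resulting curve by trapezoidal integration,
#' which equals the Mann-Whitney statistic — the probability that a random
#' positive outscores a random negative, ties counted one half. The optimal
#' cutoff maximizes the Youden index J = sensitivity + specificity - 1; ties
#' are broken toward the smallest cutoff, which keeps sensitivity maximal at
#' equal J.
#'
#' @param scores numeric vector of per-patient scores or probabilities
#'   (higher = more SSI-like).
#' @param labels binary 0/1 reference labels, same length.
#' @return an object of class `ssi_roc`: data frame `points` with columns
#'   `cutoff`, `sensitivity`, `specificity`; `auc`; `youden_cutoff`;
#'   `youden_j`.
#' @examples
#' r <- roc_and_youden(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
#' r$auc       # 1: perfect separation
#' r$youden_j  # 1
#' @export
roc_and_youden <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  cutoffs <- sort(unique(scores))
  sens <- vapply(cutoffs, function(c) sum(scores >= c & labels == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(cutoffs, function(c) sum(scores < c & labels == 0L) / n_neg,
                 numeric(1))
  points <- data.frame(
    cutoff = c(cutoffs, Inf),
    sensitivity = c(sens, 0),
    specificity = c(spec, 1)
  )
  # trapezoid over (FPR, TPR); points ordered by rising cutoff = falling FPR
  fpr <- 1 - points$specificity
  tpr <- points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  j <- points$sensitivity + points$specificity - 1
  best <- which.max(j)  # first maximum = smallest cutoff among exact ties
  structure(list(points = points, auc = auc,
                 youden_cutoff = points$cutoff[best], youden_j = j[best]),
            class = "ssi_roc")
}

#' @export
print.ssi_roc <- function(x, ...) {
  cat(sprintf("<ssi_roc> %d cutoffs, AUC %.4f, Youden cutoff %.4g (J = %.4f)\n",
              nrow(x$points), x$auc, x$youden_cutoff, x$youden_j))
  invisible(x)
}
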