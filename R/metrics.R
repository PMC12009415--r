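#' One-vs-rest confusion counts for multi-class predictions
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param labels Label universe (default the four relation labels).
#' @return A data.frame with one row per label: `TP`, `FP`, `FN`, `TN`,
#'   `support`.
#' @export
confusion_counts <- function(truth, pred, labels = RELATION_LABELS) {
  stopifnot(length(truth) == length(pred))
  n <- length(truth)
  out <- do.call(rbind, lapply(labels, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    data.frame(class = l, TP = tp, FP = fp, FN = fn, TN = n - tp - fp - fn,
               support = tp + fn, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 per class
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R). Vanishing denominators
#' yield 0 by convention.
#'
#' @param counts A data.frame from [confusion_counts()].
#' @return The same data.frame with `precision`, `recall`, `f1` appended.
#' @export
prf <- function(counts) {
  div0 <- function(a, b) ifelse(b > 0, a / b, 0)
  counts$precision <- div0(counts$TP, counts$TP + counts$FP)
  counts$recall <- div0(counts$TP, counts$TP + counts$FN)
  counts$f1 <- div0(2 * counts$precision * counts$recall,
                    counts$precision + counts$recall)
  counts
}

#' Aggregate per-class metrics into a "Total" row
#'
#' The primary aggregate is the support-weighted mean of the per-class
#' values (so aggregated P, R and F1 may all differ); the micro average
#' (which collapses them to accuracy for single-label classification) is
#' also returned.
#'
#' @param per_class Data.frame from [prf()] with a `support` column.
#' @return A list with `weighted` (named numeric P/R/F1) and `micro`.
#' @export
aggregate_prf <- function(per_class) {
  w <- per_class$support / sum(per_class$support)
  weighted <- c(P = sum(w * per_class$precision),
                R = sum(w * per_class$recall),
                F1 = sum(w * per_class$f1))
  tp <- sum(per_class$TP); fp <- sum(per_class$FP); fn <- sum(per_class$FN)
  micro_p <- if (tp + fp > 0) tp / (tp + fp) else 0
  micro_r <- if (tp + fn > 0) tp / (tp + fn) else 0
  micro_f <- if (micro_p + micro_r > 0)
    2 * micro_p * micro_r / (micro_p + micro_r) else 0
  list(weighted = weighted, micro = c(P = micro_p, R = micro_r,
                                      F1 = micro_f))
}

# one-vs-rest ROC area by the rank (Mann-Whitney) statistic; ties get
# average ranks
auc_binary <- function(pos, scores) {
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# step-function (average precision) area under the PR curve, computed over
# the distinct score thresholds so tied scores are handled exactly
aupr_binary <- function(pos, scores) {
  n_pos <- sum(pos)
  if (n_pos == 0 || all(pos)) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (th in thr) {
    sel <- scores >= th
    tp <- sum(pos & sel)
    p <- tp / sum(sel)
    r <- tp / n_pos
    ap <- ap + (r - prev_recall) * p
    prev_recall <- r
  }
  ap
}

#' One-vs-rest AUC per class
#'
#' @param truth Character vector of true labels.
#' @param probs Matrix of class probabilities, columns ordered as `labels`.
#' @param labels Label universe.
#' @return Named numeric vector (NA for labels absent from `truth`), with
#'   attribute `weighted` = support-weighted mean over defined classes.
#' @export
auc_ovr <- function(truth, probs, labels = RELATION_LABELS) {
  per <- vapply(seq_along(labels), function(j)
    auc_binary(truth == labels[j], probs[, j]), numeric(1))
  names(per) <- labels
  support <- vapply(labels, function(l) sum(truth == l), numeric(1))
  ok <- !is.na(per)
  attr(per, "weighted") <- if (any(ok))
    sum(per[ok] * support[ok]) / sum(support[ok]) else NA_real_
  per
}

#' One-vs-rest area under the precision-recall curve per class
#'
#' @inheritParams auc_ovr
#' @return Named numeric vector with attribute `weighted`.
#' @export
aupr_ovr <- function(truth, probs, labels = RELATION_LABELS) {
  per <- vapply(seq_along(labels), function(j)
    aupr_binary(truth == labels[j], probs[, j]), numeric(1))
  names(per) <- labels
  support <- vapply(labels, function(l) sum(truth == l), numeric(1))
  ok <- !is.na(per)
  attr(per, "weighted") <- if (any(ok))
    sum(per[ok] * support[ok]) / sum(support[ok]) else NA_real_
  per
}

#' Full per-class and aggregate metric report
#'
#' One row per relation label plus a `Total` row carrying the
#' support-weighted aggregates (micro averages are attached as the
#' `"micro"` attribute).
#'
#' @param truth,pred Character label vectors.
#' @param probs Optional probability matrix (needed for AUC / AUPR).
#' @param labels Label universe.
#' @return Data.frame with columns `class`, `support`, `precision`,
#'   `recall`, `f1`, `aupr`, `auc`.
#' @export
metric_report <- function(truth, pred, probs = NULL,
                          labels = RELATION_LABELS) {
  pc <- prf(confusion_counts(truth, pred, labels))
  agg <- aggregate_prf(pc)
  if (!is.null(probs)) {
    auc <- auc_ovr(truth, probs, labels)
    aupr <- aupr_ovr(truth, probs, labels)
    pc$aupr <- as.numeric(aupr)
    pc$auc <- as.numeric(auc)
    tot_aupr <- attr(aupr, "weighted")
    tot_auc <- attr(auc, "weighted")
  } else {
    pc$aupr <- NA_real_; pc$auc <- NA_real_
    tot_aupr <- NA_real_; tot_auc <- NA_real_
  }
  total <- data.frame(class = "Total", TP = sum(pc$TP), FP = sum(pc$FP),
                      FN = sum(pc$FN), TN = sum(pc$TN),
                      support = sum(pc$support),
                      precision = agg$weighted["P"],
                      recall = agg$weighted["R"], f1 = agg$weighted["F1"],
                      aupr = tot_aupr, auc = tot_auc,
                      stringsAsFactors = FALSE)
  out <- rbind(pc, total)[, c("class", "support", "precision", "recall",
                              "f1", "aupr", "auc")]
  rownames(out) <- NULL
  attr(out, "micro") <- agg$micro
  out
}
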