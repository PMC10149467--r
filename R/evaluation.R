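#' Two-sample Kolmogorov-Smirnov statistic
#'
#' \eqn{D = \sup_t |F_x(t) - F_y(t)|} between the empirical distribution
#' functions of the two samples, evaluated exactly over all pooled sample
#' points (right-continuous ECDF convention). Used here as an
#' alignment-quality score, lower meaning a better fit between the two
#' retention-time distributions; no p-value is computed.
#'
#' @param x,y non-empty numeric samples.
#' @return D in \code{[0, 1]}.
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("Kolmogorov-Smirnov statistic needs two non-empty samples",
         call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pooled) - stats::ecdf(y)(pooled)))
}

#' K-S statistic per chromatographic dimension
#'
#' Compares the rt1 distributions and the rt2 distributions of two peak
#' tables.
#'
#' @param ref,other non-empty \code{peak_table}s.
#' @return list with elements \code{d1}, \code{d2}.
#' @export
ks_per_dimension <- function(ref, other) {
  if (nrow(ref) == 0L || nrow(other) == 0L)
    stop("both peak tables must be non-empty", call. = FALSE)
  list(d1 = ks_statistic(ref$rt1, other$rt1),
       d2 = ks_statistic(ref$rt2, other$rt2))
}

#' Confusion counts of an anchor set against ground truth
#'
#' Audits a predicted matching against a known correspondence. For each
#' reference peak with a true partner: a prediction agreeing with the truth
#' is a true positive, a contradicting prediction a false positive, and no
#' prediction a false negative. Reference peaks truly absent from the
#' aligned table count as true negatives when unmatched and false positives
#' when matched.
#'
#' @param predicted an \code{anchor_set}.
#' @param truth integer vector indexed by reference peak: the true aligned
#'   index, or NA when the compound is absent from the aligned table.
#' @return list of class \code{"confusion_counts"} with \code{TP},
#'   \code{FP}, \code{FN}, \code{TN}.
#' @export
confusion_counts <- function(predicted, truth) {
  pairs <- anchor_pairs(predicted)
  pred <- rep(NA_integer_, length(truth))
  pred[pairs$ref_index] <- pairs$aln_index
  present <- !is.na(truth)
  matched <- !is.na(pred)
  structure(list(
    TP = sum(present & matched & pred == truth, na.rm = TRUE),
    FP = sum(matched & (!present | pred != truth), na.rm = TRUE),
    FN = sum(present & !matched),
    TN = sum(!present & !matched)),
    class = "confusion_counts")
}

#' Precision, recall and F1 score
#'
#' \deqn{F_1 = \frac{TP}{TP + (FN + FP)/2}}
#' which equals the harmonic mean of precision and recall whenever both are
#' defined. Undefined ratios (zero denominators) are reported as NA, not 0.
#'
#' @param c a [confusion_counts()] object or a list with \code{TP},
#'   \code{FP}, \code{FN}.
#' @return list with \code{precision}, \code{recall}, \code{f1}.
#' @export
precision_recall_f1 <- function(c) {
  precision <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  recall <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  f1 <- if (c$TP + (c$FN + c$FP) / 2 > 0)
    c$TP / (c$TP + (c$FN + c$FP) / 2) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' F1 score from precision and recall
#'
#' The count-based F1 score reduces algebraically to the harmonic mean
#' \eqn{2PR/(P+R)}, which lets the score be recomputed from reported
#' precision/recall pairs.
#'
#' @param precision,recall values in \code{[0, 1]}, not both 0.
#' @return F1 in \code{[0, 1]}.
#' @export
f1_from_precision_recall <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}
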