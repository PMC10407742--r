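#' Spearman rank correlation with average-rank ties
#'
#' Pairs with a missing value in either vector are removed first. With fewer
#' than three complete pairs, or when either ranked vector is constant, the
#' correlation is undefined and `NA` is returned (never 0): downstream
#' tournament code drops such comparisons rather than scoring them.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (max(rx) == min(rx) || max(ry) == min(ry)) return(NA_real_)
  stats::cor(rx, ry)
}

#' Orient scores so that higher always means more damaging
#'
#' Scales declared `higher_benign` (e.g. DMS fitness scores, where high
#' fitness marks tolerated variants) are negated so that ordering flips;
#' `higher_damaging` passes through unchanged. Because every metric in this
#' package is rank-based, any order-reversing map is equivalent; negation is
#' used as the canonical one. See [modified_score()] for the shift-based
#' rescaling sometimes used to put inverted scales on a comparable footing.
#'
#' @param scores Numeric vector.
#' @param orientation `"higher_damaging"` or `"higher_benign"`.
#' @return Numeric vector under the higher-is-more-damaging convention.
#' @export
orient <- function(scores, orientation = c("higher_damaging", "higher_benign")) {
  orientation <- match.arg(orientation)
  if (orientation == "higher_benign") -scores else scores
}

#' Shift-rescaled score for inverted scales
#'
#' Computes `score - max(score)`, mapping an inverted scale onto a
#' non-positive range. The shift is order-preserving, so for rank-based
#' metrics it is interchangeable with the raw scores; it is provided for
#' exact reproduction of the rescaling convention, while orientation
#' handling in this package uses [orient()] (order reversal).
#'
#' @param scores Numeric vector.
#' @return `scores - max(scores)`.
#' @export
modified_score <- function(scores) scores - max(scores)

#' Area under the ROC curve by concordant-pair counting
#'
#' Pathogenic variants are the positive class. The AUROC equals the
#' Mann--Whitney statistic: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties receiving half credit.
#' Scores must already be oriented (higher = more damaging).
#'
#' @param pos_scores Oriented scores of the positive (pathogenic) class.
#' @param neg_scores Oriented scores of the negative (putatively benign)
#'   class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np < 1L || nn < 1L) stopf("auroc needs at least one score per class")
  if (any(!is.finite(c(pos_scores, neg_scores))))
    stopf("auroc: non-finite scores")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision (area under the precision-recall curve)
#'
#' Summarises the precision-recall curve as the recall-weighted mean of
#' precision over a descending-score threshold sweep: sum over thresholds of
#' (change in recall) x (precision at that threshold). Tied scores are
#' processed as a single threshold. Scores must be oriented
#' (higher = more damaging).
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`.
#' @export
average_precision <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np < 1L || nn < 1L)
    stopf("average_precision needs at least one score per class")
  s <- c(pos_scores, neg_scores)
  if (any(!is.finite(s))) stopf("average_precision: non-finite scores")
  y <- rep(c(1, 0), c(np, nn))
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # one point per threshold
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Balanced precision-recall AUC
#'
#' Rebalances an average-precision value to a 50/50 class prior:
#' \deqn{AUBPRC = \frac{AUPRC (1 - prior)}{AUPRC (1 - prior) + (1 - AUPRC)\, prior}}
#' where the prior is the proportion of positive (pathogenic) samples. The
#' result can be read as the precision-recall AUC the classifier would
#' attain on balanced classes, making values comparable across proteins
#' with very different pathogenic/benign ratios.
#'
#' @param auprc Average precision in `[0, 1]`.
#' @param prior Proportion of positives in `(0, 1)`.
#' @return AUBPRC in `[0, 1]`.
#' @examples
#' aubprc(0.8, 0.2)  # 0.64 / 0.68
#' @export
aubprc <- function(auprc, prior) {
  if (any(auprc < 0 | auprc > 1)) stopf("auprc must lie in [0, 1]")
  if (any(prior <= 0 | prior >= 1)) stopf("prior must lie in (0, 1)")
  auprc * (1 - prior) / (auprc * (1 - prior) + (1 - auprc) * prior)
}

#' Classification metric of an oriented score split
#'
#' Convenience wrapper computing AUROC or AUBPRC (average precision
#' rebalanced at the observed prior) from oriented positive/negative scores.
#'
#' @inheritParams auroc
#' @param metric `"auroc"` or `"aubprc"`.
#' @return The metric value.
#' @export
class_metric <- function(pos_scores, neg_scores,
                         metric = c("auroc", "aubprc")) {
  metric <- match.arg(metric)
  if (metric == "auroc") return(auroc(pos_scores, neg_scores))
  prior <- length(pos_scores) / (length(pos_scores) + length(neg_scores))
  aubprc(average_precision(pos_scores, neg_scores), prior)
}
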