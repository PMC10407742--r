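# Bootstrap outranking significance: resample the data with replacement,
# recompute the full tournament and overall rank scores each time, and count
# how often each entry outranks each other entry. With B = 1000, a count of
# 950 corresponds to a one-sided P-value of 0.05.

#' One-sided outranking P-value
#'
#' @param count Number of bootstrap replicates in which one entry outranked
#'   the other.
#' @param B Number of replicates.
#' @return `p = 1 - count / B`.
#' @examples
#' outrank_pvalue(950, 1000)  # 0.05
#' @export
outrank_pvalue <- function(count, B) {
  if (any(count < 0) || any(count > B)) stopf("count must lie in [0, B]")
  1 - count / B
}

new_bootstrap_summary <- function(overall_mat, entry_names, B, seed) {
  k <- length(entry_names)
  counts <- matrix(0L, k, k, dimnames = list(entry_names, entry_names))
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b)
    counts[a, b] <- sum(overall_mat[, a] > overall_mat[, b], na.rm = TRUE)
  structure(list(B = B, seed = seed,
                 outrank_counts = counts,
                 p_values = 1 - counts / B,
                 rank_score_mean = colMeans(overall_mat, na.rm = TRUE),
                 rank_score_sd = apply(overall_mat, 2, stats::sd, na.rm = TRUE)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> B=%d seed=%d entries=%d\n",
              x$B, x$seed, ncol(x$outrank_counts)))
  cat("mean rank scores over replicates:\n")
  print(round(sort(x$rank_score_mean, decreasing = TRUE), 3))
  invisible(x)
}

#' Long-format table of a bootstrap summary
#'
#' @param x A `bootstrap_summary`.
#' @param alpha Significance threshold on the one-sided P-value.
#' @return Data frame `a`, `b`, `count`, `B`, `p`, `significant` for every
#'   ordered entry pair.
#' @export
bootstrap_table <- function(x, alpha = 0.05) {
  nms <- colnames(x$outrank_counts)
  pairs <- expand.grid(b = nms, a = nms, stringsAsFactors = FALSE)[2:1]
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  cnt <- x$outrank_counts[cbind(pairs$a, pairs$b)]
  data.frame(a = pairs$a, b = pairs$b, count = cnt, B = x$B,
             p = outrank_pvalue(cnt, x$B),
             significant = outrank_pvalue(cnt, x$B) <= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap significance of the correlation-benchmark ranking
#'
#' Per replicate, the variant rows of every protein's DMS-joined panel are
#' resampled with replacement (within each protein, keeping the per-protein
#' comparison structure), the full pairwise Spearman tournament is re-run
#' and overall rank scores recomputed. Degenerate resamples (constant
#' ranks) make that pairwise correlation undefined and the comparison is
#' skipped for the replicate, as in the main tournament. Deterministic
#' given `seed`; per-replicate RNG streams are derived independently, so a
#' parallel execution would reproduce serial results.
#'
#' @param dms A DMS [score_set()] (representative assay per protein).
#' @param predictors List of predictor [score_set()]s.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param min_shared Minimum shared variants per pairwise comparison.
#' @return A `bootstrap_summary`.
#' @export
bootstrap_corr_ranking <- function(dms, predictors, B = 1000L, seed = 1L,
                                   min_shared = 10L) {
  stopifnot(B >= 1L)
  proteins <- sort(unique(dms$protein))
  panels <- Filter(Negate(is.null),
                   lapply(proteins, function(pr)
                     build_corr_panel(dms, predictors, pr)))
  if (!length(panels)) stopf("no protein with DMS scores")
  nms <- vapply(predictors, set_name, "")
  overall <- matrix(NA_real_, B, length(nms), dimnames = list(NULL, nms))
  for (b in seq_len(B)) {
    rows <- with_seed(derive_seed(seed, "corr-boot", b), {
      lapply(panels, function(pl) {
        idx <- sample.int(length(pl$dms), replace = TRUE)
        corr_tournament_panel(pl, min_shared, idx = idx)
      })
    })
    ov <- overall_rank_scores(do.call(rbind, rows))
    overall[b, ov$predictor] <- ov$rank_score
  }
  new_bootstrap_summary(overall, nms, B, as.integer(seed))
}

#' Bootstrap significance of the classification-benchmark ranking
#'
#' Per replicate, the pathogenic and putatively benign label sets of every
#' protein are resampled with replacement independently of each other — so
#' neither class can ever be emptied — and the pairwise classification
#' tournament and overall rank scores are recomputed. Deterministic given
#' `seed`.
#'
#' @param entries List of [score_set()]s (predictors and DMS sets).
#' @param labels_by_protein List of [clinical_labels()] for eligible
#'   proteins.
#' @param metric `"auroc"` or `"aubprc"`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param rule An [eligibility_rule()].
#' @return A `bootstrap_summary`.
#' @export
bootstrap_class_ranking <- function(entries, labels_by_protein,
                                    metric = c("auroc", "aubprc"),
                                    B = 1000L, seed = 1L,
                                    rule = eligibility_rule()) {
  metric <- match.arg(metric)
  stopifnot(B >= 1L)
  if (inherits(labels_by_protein, "clinical_labels"))
    labels_by_protein <- list(labels_by_protein)
  labels_by_protein <- Filter(function(l) protein_eligible(l, rule),
                              labels_by_protein)
  if (!length(labels_by_protein)) stopf("no eligible protein")
  panels <- lapply(labels_by_protein, function(l)
    build_class_panel(entries, l))
  nms <- vapply(entries, set_name, "")
  overall <- matrix(NA_real_, B, length(nms), dimnames = list(NULL, nms))
  for (b in seq_len(B)) {
    rows <- with_seed(derive_seed(seed, "class-boot", b), {
      lapply(panels, function(pl) {
        pos_idx <- sample.int(pl$n_pos, replace = TRUE)
        neg_idx <- sample.int(pl$n_neg, replace = TRUE)
        class_tournament_panel(pl, metric, rule,
                               pos_idx = pos_idx, neg_idx = neg_idx)
      })
    })
    ov <- overall_rank_scores(do.call(rbind, rows))
    overall[b, ov$predictor] <- ov$rank_score
  }
  new_bootstrap_summary(overall, nms, B, as.integer(seed))
}
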