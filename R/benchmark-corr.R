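# The DMS-correlation benchmark: each pair of predictors is compared by its
# Spearman correlation with the DMS scores over the variants all three score,
# a win earns one point, and points / comparisons gives the per-protein rank
# score; per-protein rank scores are averaged (unweighted) across proteins.

#' Scanning-window filter parameters
#'
#' @param window_length Window length in residues (default 20).
#' @param core_length Central residues removed from a flagged window
#'   (default 10).
#' @param sd_multiplier Windows whose average predictor correlation falls
#'   more than this many standard deviations below the mean over all windows
#'   are flagged (default 1).
#' @return A `window_filter_spec` list.
#' @export
window_filter_spec <- function(window_length = 20L, core_length = 10L,
                               sd_multiplier = 1) {
  stopifnot(window_length >= 1L, core_length >= 1L,
            core_length <= window_length, sd_multiplier >= 0)
  structure(list(window_length = as.integer(window_length),
                 core_length = as.integer(core_length),
                 sd_multiplier = sd_multiplier),
            class = "window_filter_spec")
}

# Join a single protein's DMS scores with every predictor on the DMS keys.
# Rows are the DMS-scored variants; predictor columns are NA where unscored.
# All values are oriented (higher = more damaging).
build_corr_panel <- function(dms, predictors, protein) {
  d <- protein_rows(dms, protein)
  if (!nrow(d)) return(NULL)
  ids <- key_df_ids(d)
  scores <- matrix(NA_real_, nrow(d), length(predictors),
                   dimnames = list(NULL, vapply(predictors, set_name, "")))
  for (k in seq_along(predictors)) {
    p <- protein_rows(predictors[[k]], protein)
    if (!nrow(p)) next
    m <- match(ids, key_df_ids(p))
    scores[, k] <- orient(p$score, set_orientation(predictors[[k]]))[m]
  }
  list(protein = protein, ids = ids,
       dms = orient(d$score, set_orientation(dms)),
       positions = d$position, scores = scores)
}

# Run the round-robin on a panel, optionally on bootstrap row indices `idx`
# (a multiset of rows). Returns one row per predictor.
corr_tournament_panel <- function(panel, min_shared = 10L, idx = NULL) {
  d <- panel$dms
  S <- panel$scores
  if (!is.null(idx)) {
    d <- d[idx]
    S <- S[idx, , drop = FALSE]
  }
  k <- ncol(S)
  pts <- numeric(k)
  cmp <- integer(k)
  if (k >= 2L) {
    fin <- is.finite(S)
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      ok <- fin[, i] & fin[, j]
      if (sum(ok) < min_shared) next
      ri <- spearman(S[ok, i], d[ok])
      rj <- spearman(S[ok, j], d[ok])
      if (is.na(ri) || is.na(rj)) next
      cmp[i] <- cmp[i] + 1L; cmp[j] <- cmp[j] + 1L
      if (ri > rj) pts[i] <- pts[i] + 1
      else if (rj > ri) pts[j] <- pts[j] + 1
      else { pts[i] <- pts[i] + 0.5; pts[j] <- pts[j] + 0.5 }
    }
  }
  data.frame(predictor = colnames(S), protein = panel$protein,
             points = pts, comparisons = cmp,
             rank_score = ifelse(cmp > 0L, pts / cmp, NA_real_),
             stringsAsFactors = FALSE)
}

#' Pairwise Spearman tournament of predictors against DMS data
#'
#' For every unordered pair of predictors and every protein in the DMS set,
#' the comparison is restricted to variants scored by both predictors and
#' the DMS assay. If at least `min_shared` variants remain, each predictor's
#' Spearman correlation with the DMS scores on that common set is computed
#' after orientation normalisation; the higher correlation wins one point
#' (ties: half a point each). A predictor's per-protein rank score is its
#' points divided by the comparisons it participated in. Pairs below
#' `min_shared`, or with an undefined correlation, are skipped and counted
#' for neither side.
#'
#' @param dms A DMS [score_set()] (may span several proteins; typically the
#'   representative assay per protein).
#' @param predictors List of predictor [score_set()]s.
#' @param min_shared Minimum shared-variant count per comparison.
#' @return Data frame with columns `predictor`, `protein`, `points`,
#'   `comparisons`, `rank_score`.
#' @export
pairwise_corr_tournament <- function(dms, predictors, min_shared = 10L) {
  if (length(predictors) < 2L) stopf("need at least two predictors")
  rows <- lapply(sort(unique(dms$protein)), function(pr) {
    panel <- build_corr_panel(dms, predictors, pr)
    if (is.null(panel)) return(NULL)
    corr_tournament_panel(panel, min_shared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall rank scores across proteins
#'
#' The overall rank score of a predictor (or any tournament entry) is the
#' unweighted mean of its per-protein rank scores over the proteins where it
#' participated in at least one comparison. Entries never compared anywhere
#' are absent from the result.
#'
#' @param per_protein Per-protein tournament rows from
#'   [pairwise_corr_tournament()] or [pairwise_class_tournament()]; the
#'   entry column may be named `predictor` or `entry`.
#' @return Data frame `predictor`, `n_proteins`, `rank_score`, sorted by
#'   decreasing rank score.
#' @export
overall_rank_scores <- function(per_protein) {
  nmcol <- if ("predictor" %in% names(per_protein)) "predictor" else "entry"
  used <- per_protein[per_protein$comparisons > 0L & !is.na(per_protein$rank_score), ]
  if (!nrow(used))
    return(data.frame(predictor = character(0), n_proteins = integer(0),
                      rank_score = numeric(0)))
  f <- factor(used[[nmcol]])
  tot <- rowsum(used$rank_score, f)
  n <- tabulate(f, nbins = nlevels(f))
  out <- data.frame(predictor = levels(f), n_proteins = n,
                    rank_score = as.numeric(tot) / n, stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Absolute Spearman correlations between DMS assays of one protein
#'
#' Used to gauge reproducibility of independent assays of the same protein.
#' Each pair is correlated over its shared variants; pairs sharing fewer
#' than three variants get `NA`. The diagonal is 1 and the absolute value is
#' taken, so assays measuring the same landscape on inverted scales still
#' agree.
#'
#' @param assays List of DMS [score_set()]s for one protein.
#' @return Symmetric matrix of `|rho|` with assay names on both dimensions.
#' @export
cross_assay_correlations <- function(assays) {
  if (length(assays) < 2L) stopf("need at least two assays")
  nms <- vapply(assays, set_name, "")
  m <- diag(1, length(assays))
  dimnames(m) <- list(nms, nms)
  ids <- lapply(assays, key_df_ids)
  for (i in seq_len(length(assays) - 1L)) for (j in seq.int(i + 1L, length(assays))) {
    mi <- match(ids[[i]], ids[[j]])
    ok <- !is.na(mi)
    rho <- if (sum(ok) >= 3L)
      spearman(assays[[i]]$score[ok], assays[[j]]$score[mi[ok]])
    else NA_real_
    m[i, j] <- m[j, i] <- if (is.na(rho)) NA_real_ else abs(rho)
  }
  m
}

#' Select the representative DMS assay for a protein
#'
#' Among several assays of one protein, picks the one with the highest
#' median absolute Spearman correlation against all predictors (the median
#' keeps a few extreme predictors from driving the choice). Ties break
#' lexicographically by assay name, with a message.
#'
#' @param assays List of DMS [score_set()]s for one protein.
#' @param predictors List of predictor [score_set()]s.
#' @return The name of the selected assay.
#' @export
select_representative_assay <- function(assays, predictors) {
  stopifnot(length(assays) >= 1L, length(predictors) >= 1L)
  med <- vapply(assays, function(a) {
    ids <- key_df_ids(a)
    rhos <- vapply(predictors, function(p) {
      m <- match(ids, key_df_ids(p))
      ok <- !is.na(m)
      if (sum(ok) < 3L) return(NA_real_)
      r <- spearman(a$score[ok], p$score[m[ok]])
      abs(r)
    }, 0)
    if (all(is.na(rhos))) NA_real_ else stats::median(rhos, na.rm = TRUE)
  }, 0)
  if (all(is.na(med)))
    stopf("no assay has a valid correlation with any predictor")
  nms <- vapply(assays, set_name, "")
  best <- nms[which(med == max(med, na.rm = TRUE))]
  if (length(best) > 1L) {
    best <- sort(best)
    message(sprintf("representative-assay tie between %s; keeping '%s'",
                    paste(best, collapse = ", "), best[1]))
  }
  best[1]
}

#' Impute missing predictor scores with the most benign observed value
#'
#' Nucleotide-level or low-coverage predictors leave part of the
#' SNV-reachable universe unscored, often in poorly conserved regions.
#' Under the assumption that unscored positions are mostly tolerant, every
#' missing member of `universe` receives the predictor's most benign
#' observed score on that protein (the minimum under `higher_damaging`
#' orientation, the maximum under `higher_benign`). Existing scores are
#' never altered.
#'
#' @param predictor A predictor [score_set()].
#' @param universe Data frame of variant keys (`protein`, `position`, `ref`,
#'   `alt`), typically [snv_universe()] output.
#' @return A `score_set` covering all of `universe` (plus any scored
#'   variants outside it, untouched).
#' @export
impute_most_benign <- function(predictor, universe) {
  df <- as.data.frame(predictor)
  uni <- unique(as.data.frame(universe)[c("protein", "position", "ref", "alt")])
  add <- NULL
  for (pr in unique(uni$protein)) {
    have <- df[df$protein == pr, , drop = FALSE]
    if (!nrow(have))
      stopf("predictor '%s' has no scores on protein '%s'; cannot impute",
            set_name(predictor), pr)
    fill <- if (set_orientation(predictor) == "higher_damaging")
      min(have$score) else max(have$score)
    u <- uni[uni$protein == pr, , drop = FALSE]
    missing <- u[!(key_df_ids(u) %in% key_df_ids(have)), , drop = FALSE]
    if (nrow(missing)) add <- rbind(add, cbind(missing, score = fill))
  }
  out <- rbind(df, add)
  out <- out[order(out$protein, out$position, out$ref, out$alt), , drop = FALSE]
  rewrap(predictor, out)
}

#' Scanning-window exclusion of poorly predicted regions
#'
#' Slides a window of `spec$window_length` residues along the protein one
#' residue at a time. For each window, the oriented Spearman correlation
#' between the DMS scores and each predictor is computed on the variants
#' inside the window (a predictor needs at least three shared variants to
#' contribute); the window value is the mean over contributing predictors.
#' Windows with no contributing predictor are excluded from the summary.
#' Any window whose value falls strictly more than
#' `spec$sd_multiplier` standard deviations below the mean over all windows
#' has its central `spec$core_length` residues marked; the returned retained
#' set is all positions minus the union of marked cores.
#'
#' @param dms A single-protein DMS [score_set()].
#' @param predictors List of predictor [score_set()]s.
#' @param record A [protein_record()] for the protein (supplies the length).
#' @param spec A [window_filter_spec()].
#' @return Integer vector of retained positions, with attributes `removed`
#'   (marked positions) and `windows` (per-window start and mean
#'   correlation).
#' @export
window_filter <- function(dms, predictors, record,
                          spec = window_filter_spec()) {
  L <- nchar(record$sequence)
  w <- spec$window_length
  if (L < w) stopf("protein '%s' (length %d) shorter than the window (%d)",
                   record$protein, L, w)
  panel <- build_corr_panel(dms, predictors, record$protein)
  if (is.null(panel)) stopf("DMS set has no scores on protein '%s'",
                            record$protein)
  starts <- seq_len(L - w + 1L)
  vals <- vapply(starts, function(s) {
    inw <- panel$positions >= s & panel$positions <= s + w - 1L
    rhos <- vapply(seq_len(ncol(panel$scores)), function(k) {
      ok <- inw & is.finite(panel$scores[, k])
      if (sum(ok) < 3L) return(NA_real_)
      spearman(panel$scores[ok, k], panel$dms[ok])
    }, 0)
    if (all(is.na(rhos))) NA_real_ else mean(rhos, na.rm = TRUE)
  }, 0)
  mu <- mean(vals, na.rm = TRUE)
  sigma <- stats::sd(vals, na.rm = TRUE)
  flagged <- !is.na(vals) & !is.na(sigma) & vals < mu - spec$sd_multiplier * sigma
  core_off <- (w - spec$core_length) %/% 2L
  removed <- sort(unique(unlist(lapply(starts[flagged], function(s)
    seq.int(s + core_off, length.out = spec$core_length)))))
  retained <- setdiff(seq_len(L), removed)
  structure(retained, removed = as.integer(removed),
            windows = data.frame(start = starts, mean_correlation = vals))
}

#' Restrict a score set to a set of residue positions
#'
#' @param x A [score_set()].
#' @param positions Integer positions to keep (e.g. from [window_filter()]).
#' @param protein Protein whose rows are filtered; other proteins pass
#'   through untouched.
#' @return A `score_set`.
#' @export
filter_positions <- function(x, positions, protein) {
  df <- as.data.frame(x)
  keep <- df$protein != protein | df$position %in% positions
  rewrap(x, df[keep, , drop = FALSE])
}
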