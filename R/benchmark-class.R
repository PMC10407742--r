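# The clinical benchmark: predictors and DMS score sets compete by AUROC or
# AUBPRC computed on pathogenic vs putatively benign variants, pairwise on
# shared variants, with the same points / comparisons rank score as the
# correlation benchmark.

#' Eligibility thresholds for the clinical benchmark
#'
#' A protein enters the benchmark only with at least `min_pathogenic`
#' pathogenic and `min_benign` putatively benign missense variants, and a
#' pairwise comparison is executed only when the two entries share at least
#' `min_shared_pathogenic` and `min_shared_benign` labelled variants.
#' All thresholds are inclusive.
#'
#' @param min_pathogenic,min_benign Per-protein label counts (default 10).
#' @param min_shared_pathogenic,min_shared_benign Shared label counts per
#'   pairwise comparison (default 10).
#' @return An `eligibility_rule` list.
#' @export
eligibility_rule <- function(min_pathogenic = 10L, min_benign = 10L,
                             min_shared_pathogenic = 10L,
                             min_shared_benign = 10L) {
  stopifnot(min_pathogenic >= 1L, min_benign >= 1L,
            min_shared_pathogenic >= 1L, min_shared_benign >= 1L)
  structure(list(min_pathogenic = as.integer(min_pathogenic),
                 min_benign = as.integer(min_benign),
                 min_shared_pathogenic = as.integer(min_shared_pathogenic),
                 min_shared_benign = as.integer(min_shared_benign)),
            class = "eligibility_rule")
}

#' Assemble clinical labels with the benign-exclusion rule
#'
#' The putatively benign class is a population-database extract that may
#' contain variants independently reported pathogenic; those are removed
#' from the benign side (never from the pathogenic side) before
#' construction. Inputs may also pool several sources (e.g. labels from
#' identical-sequence paralogues mapped onto one protein): rows are
#' de-duplicated by union before the exclusion.
#'
#' @param pathogenic_rows,benign_rows Data frames with columns `protein`,
#'   `position`, `ref`, `alt` (possibly overlapping).
#' @param protein Protein identifier; defaults to the one found in the rows.
#' @return A [clinical_labels()] with disjoint classes.
#' @export
build_label_set <- function(pathogenic_rows, benign_rows, protein = NULL) {
  cols <- c("protein", "position", "ref", "alt")
  pth <- unique(as.data.frame(pathogenic_rows)[cols])
  ben <- unique(as.data.frame(benign_rows)[cols])
  protein <- protein %||% unique(c(pth$protein, ben$protein))
  if (length(protein) != 1L)
    stopf("label rows span %d proteins; build one label set per protein",
          length(protein))
  overlap <- key_df_ids(ben) %in% key_df_ids(pth)
  if (any(overlap))
    message(sprintf("protein '%s': %d variant(s) in both classes removed from the benign set",
                    protein, sum(overlap)))
  clinical_labels(protein, pth, ben[!overlap, , drop = FALSE])
}

#' Is a protein eligible for the clinical benchmark?
#'
#' @param labels A [clinical_labels()].
#' @param rule An [eligibility_rule()].
#' @return `TRUE` iff both label classes meet their minimum counts.
#' @export
protein_eligible <- function(labels, rule = eligibility_rule()) {
  nrow(labels$pathogenic) >= rule$min_pathogenic &&
    nrow(labels$benign) >= rule$min_benign
}

# Join every entry's oriented scores onto the labelled variants of one
# protein. Rows: pathogenic variants first, then benign.
build_class_panel <- function(entries, labels) {
  keys <- rbind(labels$pathogenic, labels$benign)
  ids <- key_df_ids(keys)
  n_pos <- nrow(labels$pathogenic)
  nms <- vapply(entries, set_name, "")
  if (anyDuplicated(nms)) stopf("duplicate entry names in the tournament")
  scores <- matrix(NA_real_, nrow(keys), length(entries),
                   dimnames = list(NULL, nms))
  for (k in seq_along(entries)) {
    e <- protein_rows(entries[[k]], labels$protein)
    if (!nrow(e)) next
    m <- match(ids, key_df_ids(e))
    scores[, k] <- orient(e$score, set_orientation(entries[[k]]))[m]
  }
  list(protein = labels$protein, n_pos = n_pos,
       n_neg = nrow(keys) - n_pos, scores = scores,
       kinds = vapply(entries, set_kind, ""))
}

# Round-robin on a class panel. pos_idx / neg_idx are bootstrap index
# multisets into the pathogenic rows (1..n_pos) and benign rows (1..n_neg).
class_tournament_panel <- function(panel, metric = "auroc",
                                   rule = eligibility_rule(),
                                   pos_idx = NULL, neg_idx = NULL) {
  pos_idx <- pos_idx %||% seq_len(panel$n_pos)
  neg_idx <- neg_idx %||% seq_len(panel$n_neg)
  P <- panel$scores[pos_idx, , drop = FALSE]
  N <- panel$scores[panel$n_pos + neg_idx, , drop = FALSE]
  k <- ncol(P)
  pts <- numeric(k)
  cmp <- integer(k)
  finP <- is.finite(P); finN <- is.finite(N)
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    okp <- finP[, i] & finP[, j]
    okn <- finN[, i] & finN[, j]
    if (sum(okp) < rule$min_shared_pathogenic ||
        sum(okn) < rule$min_shared_benign) next
    mi <- class_metric(P[okp, i], N[okn, i], metric)
    mj <- class_metric(P[okp, j], N[okn, j], metric)
    cmp[i] <- cmp[i] + 1L; cmp[j] <- cmp[j] + 1L
    if (mi > mj) pts[i] <- pts[i] + 1
    else if (mj > mi) pts[j] <- pts[j] + 1
    else { pts[i] <- pts[i] + 0.5; pts[j] <- pts[j] + 0.5 }
  }
  own <- vapply(seq_len(k), function(i) {
    p <- P[finP[, i], i]; n <- N[finN[, i], i]
    if (!length(p) || !length(n)) return(NA_real_)
    class_metric(p, n, metric)
  }, 0)
  data.frame(entry = colnames(P), kind = panel$kinds, protein = panel$protein,
             metric = metric, metric_value = own,
             points = pts, comparisons = cmp,
             rank_score = ifelse(cmp > 0L, pts / cmp, NA_real_),
             stringsAsFactors = FALSE)
}

#' Pairwise classification tournament on clinical labels
#'
#' Every unordered pair of entries (predictors and DMS score sets alike) is
#' compared on the labelled variants both entries score: if the shared
#' pathogenic and benign counts meet the eligibility rule, the chosen metric
#' (AUROC, or AUBPRC at the shared-set prior) is computed for each entry on
#' that common set and the higher value wins one point (ties: half each).
#' The per-entry `metric_value` column reports, separately, each entry's
#' headline metric on its own full labelled coverage — tournaments always
#' use pairwise-shared subsets, the headline value never does; the two are
#' reported side by side and never mixed.
#'
#' @param entries List of [score_set()]s (any mix of predictors and DMS).
#' @param labels A [clinical_labels()] for one eligible protein.
#' @param metric `"auroc"` or `"aubprc"`.
#' @param rule An [eligibility_rule()].
#' @return Data frame with columns `entry`, `kind`, `protein`, `metric`,
#'   `metric_value`, `points`, `comparisons`, `rank_score`.
#' @export
pairwise_class_tournament <- function(entries, labels,
                                      metric = c("auroc", "aubprc"),
                                      rule = eligibility_rule()) {
  metric <- match.arg(metric)
  if (length(entries) < 2L) stopf("need at least two entries")
  if (!protein_eligible(labels, rule))
    stopf("protein '%s' is not eligible (%d pathogenic, %d benign)",
          labels$protein, nrow(labels$pathogenic), nrow(labels$benign))
  class_tournament_panel(build_class_panel(entries, labels), metric, rule)
}

#' Best DMS score set per protein
#'
#' When several DMS assays of one protein enter the clinical tournament,
#' only the best-ranking one per protein represents "DMS" in the
#' cross-protein summary. Ties break lexicographically by entry name.
#'
#' @param per_protein Rows from [pairwise_class_tournament()] (one or more
#'   proteins), with `kind == "dms"` marking DMS entries.
#' @return Data frame `protein`, `entry`: the selected DMS set per protein.
#' @export
best_dms_per_protein <- function(per_protein) {
  d <- per_protein[per_protein$kind == "dms" & !is.na(per_protein$rank_score), ]
  if (!nrow(d)) return(data.frame(protein = character(0), entry = character(0)))
  picks <- lapply(split(d, d$protein), function(g) {
    g <- g[order(-g$rank_score, g$entry), , drop = FALSE]
    if (nrow(g) > 1L && g$rank_score[2] == g$rank_score[1])
      message(sprintf("protein '%s': DMS rank-score tie; keeping '%s'",
                      g$protein[1], g$entry[1]))
    g[1, c("protein", "entry")]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

# Collapse all DMS rows of a per-protein class-tournament table to a single
# synthetic "DMS" entry, keeping only the best DMS set per protein.
collapse_best_dms <- function(per_protein, label = "DMS") {
  best <- best_dms_per_protein(per_protein)
  is_best <- paste(per_protein$protein, per_protein$entry) %in%
    paste(best$protein, best$entry)
  out <- per_protein[per_protein$kind != "dms" | is_best, , drop = FALSE]
  out$entry[out$kind == "dms"] <- label
  out
}

#' Check and optionally repair a score set's orientation against labels
#'
#' An entry whose AUROC under its declared orientation falls below 0.5 is an
#' inverse predictor of clinical outcome. With `flip = TRUE` its orientation
#' is inverted (a loud warning reports both AUROC values); by default
#' nothing is changed — orientations should be declared, and silently
#' rescuing a broken input would mask upstream errors. An AUROC of exactly
#' 0.5 is never flipped.
#'
#' @param entry A [score_set()].
#' @param labels A [clinical_labels()].
#' @param flip Whether to invert the orientation when AUROC < 0.5.
#' @return The entry, possibly with inverted orientation; attribute
#'   `auroc` records the AUROC under the declared orientation.
#' @export
auto_orient <- function(entry, labels, flip = FALSE) {
  panel <- build_class_panel(list(entry), labels)
  s <- panel$scores[, 1]
  p <- s[seq_len(panel$n_pos)]; n <- s[-seq_len(panel$n_pos)]
  p <- p[is.finite(p)]; n <- n[is.finite(n)]
  if (!length(p) || !length(n))
    stopf("entry '%s' scores no labelled variants of '%s'",
          set_name(entry), labels$protein)
  a <- auroc(p, n)
  out <- entry
  if (a < 0.5 && flip) {
    newo <- setdiff(c("higher_damaging", "higher_benign"),
                    set_orientation(entry))
    out <- score_set(set_name(entry), as.data.frame(entry),
                     kind = set_kind(entry), orientation = newo)
    warning(sprintf(
      "entry '%s' is an inverse predictor on '%s' (AUROC %.3f); orientation inverted (AUROC now %.3f)",
      set_name(entry), labels$protein, a, 1 - a), call. = FALSE)
  }
  structure(out, auroc = a)
}

#' Concordance between the DMS and clinical benchmarks
#'
#' Spearman correlation between the overall rank scores of the two
#' tournaments on the predictors present in both. High concordance means
#' agreement with functional data and discrimination of clinical labels
#' rank predictors the same way.
#'
#' @param corr_overall,class_overall Overall tables from
#'   [overall_rank_scores()] (columns `predictor`, `rank_score`).
#' @return Spearman's rho over the shared predictors (at least 3 required).
#' @export
benchmark_concordance <- function(corr_overall, class_overall) {
  shared <- intersect(corr_overall$predictor, class_overall$predictor)
  if (length(shared) < 3L)
    stopf("only %d predictor(s) shared between the two tables; need >= 3",
          length(shared))
  x <- corr_overall$rank_score[match(shared, corr_overall$predictor)]
  y <- class_overall$rank_score[match(shared, class_overall$predictor)]
  spearman(x, y)
}
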