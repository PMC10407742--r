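# End-to-end drivers tying the stages together. Both accept either a bundle
# list (from simulate_benchmark()) or a directory written by
# write_benchmark(); all tabular results can be mirrored to TSV + JSON.

as_bundle <- function(x) {
  if (is.character(x) && length(x) == 1L) load_benchmark(x) else x
}

write_result_table <- function(df, out_dir, stem) {
  utils::write.table(df, file.path(out_dir, paste0(stem, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, file.path(out_dir, paste0(stem, ".json")),
                       dataframe = "rows", digits = NA, pretty = TRUE)
}

#' Run the DMS-correlation benchmark
#'
#' Pipeline: per protein, DMS assays below the minimum coverage fraction
#' are excluded; among the survivors the representative assay (highest
#' median absolute Spearman against the predictors) is selected; optionally
#' the analysis is restricted to SNV-reachable substitutions with missing
#' predictor scores imputed at the per-protein most benign value
#' (`snv_impute`), and/or poorly predicted regions are removed by the
#' scanning-window filter (`window`). The pairwise Spearman tournament and
#' the overall rank scores are then computed, with optional bootstrap
#' outranking significance. The three recalculation modes are explicit
#' flags, never combined implicitly.
#'
#' @param bundle A bundle list or a directory from [write_benchmark()].
#' @param min_shared Minimum shared variants per pairwise comparison.
#' @param snv_impute Apply the SNV-reachable + most-benign-imputation mode.
#' @param window Apply the scanning-window region filter.
#' @param window_spec A [window_filter_spec()].
#' @param coverage_threshold Minimum DMS coverage fraction (default 0.05).
#' @param B Bootstrap replicates (0 = no bootstrap).
#' @param seed Seed for the bootstrap.
#' @param out_dir Optional directory for TSV/JSON result mirrors.
#' @return List: `per_protein` tournament rows, `overall` rank scores,
#'   `representative` (protein, chosen assay), `excluded_assays`,
#'   `bootstrap` (a `bootstrap_summary` or `NULL`).
#' @export
run_corr_benchmark <- function(bundle, min_shared = 10L,
                               snv_impute = FALSE, window = FALSE,
                               window_spec = window_filter_spec(),
                               coverage_threshold = 0.05,
                               B = 0L, seed = 1L, out_dir = NULL) {
  bundle <- as_bundle(bundle)
  predictors <- bundle$predictors
  if (length(predictors) < 2L) stopf("need at least two predictors")
  dms_parts <- list(); pred_parts <- list(); rep_rows <- NULL; excl <- NULL
  for (pr in names(bundle$dms)) {
    record <- bundle$records[[pr]]
    assays <- bundle$dms[[pr]]
    cov <- vapply(assays, coverage_fraction, 0, record = record)
    if (any(cov < coverage_threshold)) {
      drop <- names(assays)[cov < coverage_threshold]
      message(sprintf("protein '%s': assay(s) %s below %.0f%% coverage, excluded",
                      pr, paste(drop, collapse = ", "),
                      100 * coverage_threshold))
      excl <- rbind(excl, data.frame(protein = pr, assay = drop,
                                     coverage = cov[cov < coverage_threshold]))
      assays <- assays[cov >= coverage_threshold]
    }
    if (!length(assays)) next
    rep_name <- if (length(assays) == 1L) set_name(assays[[1]])
    else select_representative_assay(assays, predictors)
    dms_pr <- assays[[rep_name]]
    preds_pr <- lapply(predictors, function(p)
      rewrap(p, protein_rows(p, pr)))
    if (snv_impute) {
      dms_pr <- snv_filter(dms_pr, record)
      uni <- snv_universe(record)
      preds_pr <- lapply(preds_pr, function(p) {
        if (!nrow(p)) return(p)
        impute_most_benign(p, uni)
      })
    }
    if (window) {
      retained <- window_filter(dms_pr, preds_pr, record, window_spec)
      dms_pr <- filter_positions(dms_pr, retained, pr)
    }
    rep_rows <- rbind(rep_rows, data.frame(protein = pr, assay = rep_name))
    dms_parts[[pr]] <- as.data.frame(dms_pr)
    pred_parts[[pr]] <- lapply(preds_pr, as.data.frame)
  }
  if (!length(dms_parts)) stopf("no protein passed the DMS coverage filter")
  dms_all <- score_set("representative_dms", do.call(rbind, dms_parts),
                       kind = "dms",
                       orientation = bundle$manifest$dms_orientation %||%
                         set_orientation(bundle$dms[[1]][[1]]))
  preds_all <- lapply(names(predictors), function(nm) {
    rows <- do.call(rbind, lapply(pred_parts, `[[`, nm))
    rewrap(predictors[[nm]], rows)
  })
  names(preds_all) <- names(predictors)
  per_protein <- pairwise_corr_tournament(dms_all, preds_all, min_shared)
  overall <- overall_rank_scores(per_protein)
  boot <- if (B > 0L)
    bootstrap_corr_ranking(dms_all, preds_all, B = B, seed = seed,
                           min_shared = min_shared)
  res <- list(per_protein = per_protein, overall = overall,
              representative = rep_rows, excluded_assays = excl,
              bootstrap = boot)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(per_protein, out_dir, "corr_per_protein")
    write_result_table(overall, out_dir, "corr_overall")
    write_result_table(rep_rows, out_dir, "corr_representative_assay")
    if (!is.null(boot))
      write_result_table(bootstrap_table(boot), out_dir, "corr_bootstrap")
  }
  res
}

#' Run the clinical classification benchmark
#'
#' Pipeline: labels are checked against the eligibility rule (proteins with
#' too few pathogenic or benign variants are excluded with a message; zero
#' eligible proteins is an error naming the per-protein counts); predictors
#' and all DMS score sets enter the pairwise AUROC/AUBPRC tournament per
#' eligible protein; the best-ranking DMS set per protein then represents
#' "DMS" in the cross-protein overall table. Optional bootstrap outranking
#' significance and concordance against a correlation-benchmark table.
#' With `flip_inverse = TRUE`, DMS entries whose AUROC under the declared
#' orientation is below 0.5 have their scale inverted (with a warning);
#' this is off by default.
#'
#' @param bundle A bundle list or directory.
#' @param metric `"auroc"` or `"aubprc"`.
#' @param rule An [eligibility_rule()].
#' @param flip_inverse Invert inverse-predictor DMS scales (see
#'   [auto_orient()]).
#' @param B Bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap.
#' @param corr_overall Optional overall table from [run_corr_benchmark()]
#'   for the cross-benchmark concordance.
#' @param out_dir Optional directory for TSV/JSON result mirrors.
#' @return List: `per_protein` rows (all entries), `overall` (best DMS per
#'   protein collapsed to a single "DMS" entry), `best_dms`, `bootstrap`,
#'   `concordance` (Spearman rho, or `NULL`).
#' @export
run_class_benchmark <- function(bundle, metric = c("auroc", "aubprc"),
                                rule = eligibility_rule(),
                                flip_inverse = FALSE,
                                B = 0L, seed = 1L, corr_overall = NULL,
                                out_dir = NULL) {
  metric <- match.arg(metric)
  bundle <- as_bundle(bundle)
  labels <- bundle$labels
  eligible <- vapply(labels, protein_eligible, TRUE, rule = rule)
  if (!any(eligible)) {
    counts <- vapply(labels, function(l)
      sprintf("%s: %d pathogenic, %d benign", l$protein,
              nrow(l$pathogenic), nrow(l$benign)), "")
    stopf("no eligible protein; per-protein counts: %s",
          paste(counts, collapse = "; "))
  }
  if (any(!eligible))
    message(sprintf("excluding ineligible protein(s): %s",
                    paste(names(labels)[!eligible], collapse = ", ")))
  labels <- labels[eligible]
  entries <- c(bundle$predictors, unlist(bundle$dms, recursive = FALSE,
                                         use.names = FALSE))
  names(entries) <- vapply(entries, set_name, "")
  if (flip_inverse) {
    for (pr in names(labels)) {
      for (nm in names(entries)) {
        e <- entries[[nm]]
        if (set_kind(e) != "dms" || e$protein[1] != pr) next
        entries[[nm]] <- auto_orient(e, labels[[pr]], flip = TRUE)
      }
    }
  }
  per_protein <- do.call(rbind, lapply(labels, function(l)
    pairwise_class_tournament(entries, l, metric = metric, rule = rule)))
  rownames(per_protein) <- NULL
  best <- best_dms_per_protein(per_protein)
  collapsed <- collapse_best_dms(per_protein)
  overall <- overall_rank_scores(collapsed)
  boot <- if (B > 0L)
    bootstrap_class_ranking(entries, labels, metric = metric, B = B,
                            seed = seed, rule = rule)
  conc <- NULL
  if (!is.null(corr_overall)) {
    pred_only <- overall[overall$predictor %in% names(bundle$predictors), ]
    conc <- benchmark_concordance(corr_overall, pred_only)
  }
  res <- list(per_protein = per_protein, overall = overall,
              best_dms = best, bootstrap = boot, concordance = conc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(per_protein, out_dir, "class_per_protein")
    write_result_table(overall, out_dir, "class_overall")
    write_result_table(best, out_dir, "class_best_dms")
    if (!is.null(boot))
      write_result_table(bootstrap_table(boot), out_dir, "class_bootstrap")
  }
  res
}
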