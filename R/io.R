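# Tab-separated score/label tables, FASTA sequences, and the predictor
# declaration config. Absence of a row encodes missingness; "." or empty
# score fields are rejected rather than silently dropped.

#' Read a variant score table
#'
#' Expects a UTF-8 TSV with header `protein position ref alt score`. For
#' predictors flagged `nucleotide_level`, repeated substitution keys are
#' legal and are averaged by [aggregate_nucleotide_scores()]; otherwise a
#' duplicate key is an error (DMS tables are residue-level).
#'
#' @param path File path.
#' @param name Score-set name; defaults to the file name without extension.
#' @param kind `"predictor"` or `"dms"`.
#' @param orientation Declared scale orientation.
#' @param nucleotide_level Whether repeated keys should be mean-aggregated.
#' @return A [score_set()].
#' @export
read_score_table <- function(path, name = NULL,
                             kind = c("predictor", "dms"),
                             orientation = c("higher_damaging", "higher_benign"),
                             nucleotide_level = FALSE) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(score = "character"))
  req <- c("protein", "position", "ref", "alt", "score")
  if (!all(req %in% names(df)))
    stopf("%s: expected columns %s", path, paste(req, collapse = ", "))
  blank <- df$score %in% c("", ".", "NA") | is.na(df$score)
  if (any(blank))
    stopf("%s: missing score at line %d; omit the row instead",
          path, which(blank)[1] + 1L)
  df$score <- as.numeric(df$score)
  if (nucleotide_level) df <- aggregate_nucleotide_scores(df)
  score_set(name, df, kind = kind, orientation = orientation)
}

#' Write a variant score table
#'
#' @param x A [score_set()].
#' @param path Output TSV path.
#' @export
write_score_table <- function(x, path) {
  df <- as.data.frame(x)
  df$score <- sprintf("%.17g", df$score)  # round-trips doubles exactly
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical label table
#'
#' TSV with header `protein position ref alt label`,
#' label in `{pathogenic, benign}`. Benign rows found in the pathogenic set
#' are removed (the putatively-benign exclusion rule), with a message giving
#' the overlap count.
#'
#' @param path File path.
#' @return Named list of [clinical_labels()], one per protein.
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein", "position", "ref", "alt", "label")
  if (!all(req %in% names(df)))
    stopf("%s: expected columns %s", path, paste(req, collapse = ", "))
  if (!all(df$label %in% c("pathogenic", "benign")))
    stopf("%s: labels must be 'pathogenic' or 'benign'", path)
  out <- lapply(split(df, df$protein), function(d) {
    build_label_set(d[d$label == "pathogenic", ], d[d$label == "benign", ],
                    protein = d$protein[1])
  })
  out[order(names(out))]
}

#' Write clinical labels as a label table
#'
#' @param labels A [clinical_labels()] or list of them.
#' @param path Output TSV path.
#' @export
write_label_table <- function(labels, path) {
  if (inherits(labels, "clinical_labels")) labels <- list(labels)
  rows <- do.call(rbind, lapply(labels, function(l) {
    rbind(cbind(l$pathogenic, label = rep("pathogenic", nrow(l$pathogenic))),
          cbind(l$benign, label = rep("benign", nrow(l$benign))))
  }))
  rows <- rows[order(rows$protein, rows$position, rows$ref, rows$alt,
                     rows$label), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read protein (and optional coding) sequences into records
#'
#' @param fasta Path to an amino acid FASTA; identifiers are protein ids.
#' @param cds_fasta Optional nucleotide FASTA keyed by the same identifiers.
#' @return Named list of [protein_record()].
#' @export
read_protein_records <- function(fasta, cds_fasta = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  cds <- if (!is.null(cds_fasta)) Biostrings::readDNAStringSet(cds_fasta)
  lapply(stats::setNames(names(aa), names(aa)), function(p) {
    protein_record(p, as.character(aa[[p]]),
                   cds = if (!is.null(cds) && p %in% names(cds))
                     as.character(cds[[p]]))
  })
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()].
#' @param fasta Output amino acid FASTA path.
#' @param cds_fasta Optional output CDS FASTA path (records lacking a CDS
#'   are skipped).
#' @export
write_protein_records <- function(records, fasta, cds_fasta = NULL) {
  aa <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(aa) <- vapply(records, `[[`, "", "protein")
  Biostrings::writeXStringSet(aa, fasta, width = 60)
  if (!is.null(cds_fasta)) {
    has <- !vapply(records, function(r) is.null(r$cds), TRUE)
    if (any(has)) {
      nt <- Biostrings::DNAStringSet(vapply(records[has], `[[`, "", "cds"))
      names(nt) <- vapply(records[has], `[[`, "", "protein")
      Biostrings::writeXStringSet(nt, cds_fasta, width = 60)
    }
  }
  invisible(fasta)
}

#' Read the per-predictor declaration config
#'
#' A YAML mapping of predictor name to `orientation`
#' (`higher_damaging`/`higher_benign`), `nucleotide_level` (logical) and
#' optional `display` name. Every predictor used in a run must be declared;
#' orientation is never guessed from data.
#'
#' @param path YAML file path.
#' @return Named list of declarations.
#' @export
read_predictor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stopf("%s: expected a mapping of predictor name -> declaration", path)
  lapply(stats::setNames(names(cfg), names(cfg)), function(nm) {
    d <- cfg[[nm]]
    ori <- d$orientation %||% stopf("%s: predictor '%s' lacks an orientation",
                                    path, nm)
    if (!ori %in% c("higher_damaging", "higher_benign"))
      stopf("%s: predictor '%s': unknown orientation '%s'", path, nm, ori)
    list(orientation = ori,
         nucleotide_level = isTRUE(d$nucleotide_level),
         display = d$display %||% nm)
  })
}
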