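#' Construct a variant score set
#'
#' A score set is a named mapping from amino acid substitutions (protein,
#' 1-based position, reference and alternate residue) to finite numeric
#' scores, together with a declared scale orientation. It represents either a
#' deep mutational scanning (DMS) assay or a variant effect predictor (VEP)
#' output for one or more proteins. Orientation is always declared, never
#' inferred: `"higher_damaging"` means larger scores indicate more damaging
#' variants, `"higher_benign"` the opposite (the usual convention for DMS
#' fitness scores, where high fitness means a tolerated variant).
#'
#' @param name Identifier for the score set.
#' @param scores A data frame with columns `protein`, `position`, `ref`,
#'   `alt`, `score`.
#' @param kind `"dms"` or `"predictor"`.
#' @param orientation `"higher_damaging"` or `"higher_benign"`.
#' @return An object of class `score_set`: the validated score data frame
#'   with `name`, `kind` and `orientation` attributes.
#' @examples
#' s <- score_set("toy", data.frame(protein = "P", position = 1:2,
#'                                  ref = "M", alt = c("L", "V"),
#'                                  score = c(0.2, 0.8)))
#' n_variants(s)
#' @export
score_set <- function(name, scores,
                      kind = c("predictor", "dms"),
                      orientation = c("higher_damaging", "higher_benign")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  req <- c("protein", "position", "ref", "alt", "score")
  if (!all(req %in% names(scores)))
    stopf("score set '%s': missing columns %s", name,
          paste(setdiff(req, names(scores)), collapse = ", "))
  scores <- as.data.frame(scores)[req]
  scores$protein <- as.character(scores$protein)
  scores$position <- as.integer(scores$position)
  scores$ref <- as.character(scores$ref)
  scores$alt <- as.character(scores$alt)
  scores$score <- as.numeric(scores$score)
  if (nrow(scores)) {
    if (any(!is.finite(scores$score)))
      stopf("score set '%s': non-finite scores", name)
    if (any(scores$position < 1L))
      stopf("score set '%s': positions must be >= 1", name)
    bad <- !(scores$ref %in% AA_ALPHABET) | !(scores$alt %in% AA_ALPHABET)
    if (any(bad))
      stopf("score set '%s': residues outside the 20-letter alphabet (e.g. %s)",
            name, variant_id(scores$protein[bad][1], scores$position[bad][1],
                             scores$ref[bad][1], scores$alt[bad][1]))
    if (any(scores$ref == scores$alt))
      stopf("score set '%s': synonymous entries (ref == alt) are not substitutions",
            name)
    ids <- key_df_ids(scores)
    if (anyDuplicated(ids))
      stopf("score set '%s': duplicate variant %s", name, ids[duplicated(ids)][1])
    rownames(scores) <- NULL
  }
  structure(scores, class = c("score_set", "data.frame"),
            name = name, kind = kind, orientation = orientation)
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set '%s'> kind=%s orientation=%s: %d variants in %d protein(s)\n",
              set_name(x), set_kind(x), set_orientation(x),
              nrow(x), length(unique(x$protein))))
  invisible(x)
}

#' @rdname score_set
#' @param x A `score_set`.
#' @export
set_name <- function(x) attr(x, "name")

#' @rdname score_set
#' @export
set_kind <- function(x) attr(x, "kind")

#' @rdname score_set
#' @export
set_orientation <- function(x) attr(x, "orientation")

#' @rdname score_set
#' @export
n_variants <- function(x) nrow(x)

# Rebuild a score_set from a plain data frame, keeping metadata of `template`.
rewrap <- function(template, scores) {
  score_set(set_name(template), scores, kind = set_kind(template),
            orientation = set_orientation(template))
}

# Subset a score_set to one protein (plain data frame out).
protein_rows <- function(x, protein) {
  as.data.frame(x)[x$protein == protein, , drop = FALSE]
}

#' Clinical variant labels for one protein
#'
#' Holds disjoint pathogenic and putatively benign substitution sets.
#' Construction fails on any key present in both classes; use
#' [build_label_set()] to apply the benign-excludes-pathogenic rule to raw,
#' possibly overlapping inputs.
#'
#' @param protein Protein identifier.
#' @param pathogenic,benign Data frames with columns `protein`, `position`,
#'   `ref`, `alt`.
#' @return An object of class `clinical_labels`.
#' @export
clinical_labels <- function(protein, pathogenic, benign) {
  norm <- function(df) {
    df <- as.data.frame(df)[c("protein", "position", "ref", "alt")]
    df$protein <- as.character(df$protein)
    df$position <- as.integer(df$position)
    df$ref <- as.character(df$ref)
    df$alt <- as.character(df$alt)
    df <- unique(df)
    if (nrow(df) && any(df$protein != protein))
      stopf("label rows for a different protein than '%s'", protein)
    rownames(df) <- NULL
    df
  }
  pathogenic <- norm(pathogenic)
  benign <- norm(benign)
  shared <- intersect(key_df_ids(pathogenic), key_df_ids(benign))
  if (length(shared))
    stopf("clinical labels for '%s': %d variant(s) in both classes (e.g. %s)",
          protein, length(shared), shared[1])
  structure(list(protein = protein, pathogenic = pathogenic, benign = benign),
            class = "clinical_labels")
}

#' @export
print.clinical_labels <- function(x, ...) {
  cat(sprintf("<clinical_labels '%s'> %d pathogenic, %d putatively benign\n",
              x$protein, nrow(x$pathogenic), nrow(x$benign)))
  invisible(x)
}

#' Protein sequence record with optional coding sequence
#'
#' @param protein Protein identifier.
#' @param sequence Amino acid sequence (one-letter, 20-letter alphabet).
#' @param cds Optional coding nucleotide sequence of length
#'   `3 * nchar(sequence)` (stop codon excluded); each codon must translate
#'   to the corresponding residue under the standard genetic code.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein, sequence, cds = NULL) {
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  if (!length(res)) stopf("protein '%s': empty sequence", protein)
  if (!all(res %in% AA_ALPHABET))
    stopf("protein '%s': sequence contains letters outside the 20-letter alphabet",
          protein)
  if (!is.null(cds)) {
    cds <- toupper(cds)
    if (nchar(cds) != 3L * length(res))
      stopf("protein '%s': CDS length %d != 3 x protein length %d",
            protein, nchar(cds), length(res))
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    code <- genetic_code()
    tr <- unname(code[codons])
    if (anyNA(tr)) stopf("protein '%s': CDS contains non-ACGT codons", protein)
    if (any(tr != res))
      stopf("protein '%s': codon %d ('%s') translates to %s, sequence has %s",
            protein, which(tr != res)[1], codons[which(tr != res)[1]],
            tr[which(tr != res)[1]], res[which(tr != res)[1]])
  }
  structure(list(protein = protein, sequence = sequence, cds = cds),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record '%s'> %d aa%s\n", x$protein, nchar(x$sequence),
              if (is.null(x$cds)) "" else ", CDS present"))
  invisible(x)
}

#' The standard genetic code
#'
#' Returns the standard codon table as a named character vector of all 64
#' codons mapping to one-letter amino acids or `"*"` for stop, taken from
#' [Biostrings::GENETIC_CODE]. A custom table may be supplied and is
#' validated (64 entries, 61 sense codons, 3 stops).
#'
#' @param table Optional named character vector replacing the standard code.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    code <- Biostrings::GENETIC_CODE
    return(stats::setNames(as.character(code), names(code)))
  }
  if (length(table) != 64L || is.null(names(table)))
    stopf("a genetic code must map exactly 64 named codons")
  if (sum(table == "*") != 3L || sum(table != "*") != 61L)
    stopf("a genetic code must have 61 sense codons and 3 stops")
  table
}

#' Parse a protein variant token
#'
#' Accepts the compact one-letter form (`"R175H"`) and the HGVS protein form
#' with three-letter residue names (`"p.Arg175His"`).
#'
#' @param token Variant string.
#' @param protein Protein identifier to attach.
#' @return A one-row data frame with columns `protein`, `position`, `ref`,
#'   `alt`.
#' @examples
#' parse_variant("R175H", "TP53")
#' parse_variant("p.Arg175His", "TP53")
#' @export
parse_variant <- function(token, protein) {
  stopifnot(is.character(token), length(token) == 1L)
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) == 4L) {
    ref <- toupper(m[2]); alt <- toupper(m[4]); pos <- as.integer(m[3])
  } else {
    m <- regmatches(token,
                    regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", token))[[1]]
    if (length(m) != 4L)
      stopf("malformed variant token '%s'", token)
    three <- function(s) {
      s <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, 3)))
      if (!s %in% names(AA_THREE_TO_ONE))
        stopf("unknown residue name '%s' in token '%s'", s, token)
      AA_THREE_TO_ONE[[s]]
    }
    ref <- three(m[2]); alt <- three(m[4]); pos <- as.integer(m[3])
  }
  if (!ref %in% AA_ALPHABET || !alt %in% AA_ALPHABET)
    stopf("unknown residue in token '%s'", token)
  if (pos < 1L) stopf("position must be >= 1 in token '%s'", token)
  if (ref == alt)
    stopf("token '%s' is synonymous (ref == alt), not a substitution", token)
  data.frame(protein = protein, position = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Amino acids reachable from a codon by one nucleotide change
#'
#' Enumerates the nine single-nucleotide neighbours of a sense codon,
#' translates them, and returns the resulting amino acids excluding the
#' reference amino acid and stop codons. This implements the restriction to
#' missense changes attainable by a single nucleotide substitution, the
#' variant class that nucleotide-level predictors can score.
#'
#' @param ref_codon A three-letter sense codon.
#' @param code Genetic code table from [genetic_code()].
#' @return Sorted character vector of reachable amino acids (length 1--7).
#' @examples
#' snv_reachable("ATG")  # Met -> I K L R T V
#' @export
snv_reachable <- function(ref_codon, code = genetic_code()) {
  ref_codon <- toupper(ref_codon)
  if (is.na(code[ref_codon]) || !nchar(ref_codon) == 3L)
    stopf("'%s' is not a codon", ref_codon)
  ref_aa <- unname(code[ref_codon])
  if (ref_aa == "*") stopf("'%s' is a stop codon", ref_codon)
  nts <- c("A", "C", "G", "T")
  bases <- strsplit(ref_codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) for (nt in setdiff(nts, bases[i])) {
    nb <- bases; nb[i] <- nt
    out <- c(out, unname(code[paste(nb, collapse = "")]))
  }
  sort(unique(setdiff(out, c(ref_aa, "*"))))
}

# Per-residue reachable sets when no CDS is known: the union over all
# standard-code codons encoding the reference residue. A superset of the
# transcript-specific set.
snv_reachable_fallback <- function(ref_aa, code = genetic_code()) {
  codons <- names(code)[code == ref_aa]
  if (!length(codons)) stopf("no codon encodes '%s'", ref_aa)
  sort(unique(unlist(lapply(codons, snv_reachable, code = code))))
}

# Codon at a 1-based residue position of a record's CDS.
codon_at <- function(record, position) {
  substr(record$cds, 3L * (position - 1L) + 1L, 3L * position)
}

#' All SNV-reachable substitutions of a protein
#'
#' @param record A [protein_record()]; when its CDS is present reachability
#'   is codon-specific, otherwise the union over all codons encoding each
#'   reference residue is used (a documented superset).
#' @param code Genetic code table.
#' @return Data frame of variant keys (`protein`, `position`, `ref`, `alt`).
#' @export
snv_universe <- function(record, code = genetic_code()) {
  res <- strsplit(record$sequence, "")[[1]]
  reach <- if (!is.null(record$cds)) {
    lapply(seq_along(res), function(i) snv_reachable(codon_at(record, i), code))
  } else {
    tabs <- lapply(stats::setNames(AA_ALPHABET, AA_ALPHABET),
                   snv_reachable_fallback, code = code)
    lapply(res, function(a) tabs[[a]])
  }
  n <- lengths(reach)
  data.frame(protein = record$protein,
             position = rep(seq_along(res), n),
             ref = rep(res, n),
             alt = unlist(reach),
             stringsAsFactors = FALSE)
}

#' Restrict a score set to SNV-reachable substitutions
#'
#' @param x A [score_set()] (single protein, matching `record`).
#' @param record A [protein_record()].
#' @param code Genetic code table.
#' @return A `score_set` with the same name, kind and orientation, retaining
#'   only substitutions reachable by one nucleotide change.
#' @export
snv_filter <- function(x, record, code = genetic_code()) {
  df <- as.data.frame(x)
  rows <- df$protein == record$protein
  sub <- df[rows, , drop = FALSE]
  if (nrow(sub)) {
    if (any(sub$position > nchar(record$sequence)))
      stopf("score set '%s': position beyond protein '%s' length %d",
            set_name(x), record$protein, nchar(record$sequence))
    seq_res <- strsplit(record$sequence, "")[[1]]
    mism <- sub$ref != seq_res[sub$position]
    if (any(mism))
      stopf("score set '%s': reference residue mismatch at position %d",
            set_name(x), sub$position[mism][1])
    uni <- snv_universe(record, code)
    keep <- key_df_ids(sub) %in% key_df_ids(uni)
    sub <- sub[keep, , drop = FALSE]
  }
  out <- rbind(df[!rows, , drop = FALSE], sub)
  out <- out[order(out$protein, out$position, out$ref, out$alt), , drop = FALSE]
  rewrap(x, out)
}

#' Aggregate nucleotide-level rows to residue-level scores
#'
#' Nucleotide-resolution predictors can assign several scores to the same
#' amino acid substitution (several nucleotide changes yielding one residue
#' change); the residue-level score is the arithmetic mean of those rows.
#'
#' @param rows Data frame with columns `protein`, `position`, `ref`, `alt`,
#'   `score`; repeated keys allowed.
#' @return Data frame with one row per substitution, score = mean of its rows.
#' @export
aggregate_nucleotide_scores <- function(rows) {
  rows <- as.data.frame(rows)[c("protein", "position", "ref", "alt", "score")]
  if (any(!is.finite(rows$score))) stopf("non-finite score in nucleotide rows")
  if (!nrow(rows)) return(rows)
  agg <- stats::aggregate(score ~ protein + position + ref + alt, data = rows,
                          FUN = mean)
  agg <- agg[order(agg$protein, agg$position, agg$ref, agg$alt), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Fraction of the mutational universe covered by a score set
#'
#' The denominator is the saturation count `19 * protein length` (every
#' non-synonymous single-residue substitution); DMS assays below a minimum
#' coverage (5% in the benchmark pipeline) are excluded as too sparse.
#'
#' @param x A [score_set()].
#' @param record A [protein_record()].
#' @return A number in `[0, 1]`.
#' @export
coverage_fraction <- function(x, record) {
  L <- nchar(record$sequence)
  if (L == 0L) stopf("zero-length sequence")
  sum(x$protein == record$protein) / (19 * L)
}
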