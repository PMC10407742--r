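# Independent oracles: deliberately naive implementations used only to
# check the package's optimised code paths.

# AUROC as an exhaustive concordant-pair count.
auroc_pairs <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# Average precision as an exhaustive descending threshold sweep.
ap_sweep <- function(pos, neg) {
  thresholds <- sort(unique(c(pos, neg)), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    tp <- sum(pos >= t)
    fp <- sum(neg >= t)
    precision <- tp / (tp + fp)
    recall <- tp / length(pos)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# SNV-reachable amino acids by direct neighbour enumeration against the
# Biostrings code table (no shared code with the package implementation).
snv_oracle <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aas <- character(0)
  for (i in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (substr(codon, i, i) == nt) next
    nb <- codon
    substr(nb, i, i) <- nt
    aas <- c(aas, code[[nb]])
  }
  sort(unique(setdiff(aas, c(code[[codon]], "*"))))
}

# Scanning-window filter recomputed naively with cor(method = "spearman").
window_oracle <- function(dms_df, pred_dfs, L, w = 20, core = 10, m = 1) {
  ids <- function(d) paste(d$position, d$ref, d$alt)
  starts <- 1:(L - w + 1)
  vals <- sapply(starts, function(s) {
    d <- dms_df[dms_df$position >= s & dms_df$position <= s + w - 1, ]
    rhos <- sapply(pred_dfs, function(p) {
      mm <- match(ids(d), ids(p))
      ok <- !is.na(mm)
      if (sum(ok) < 3) return(NA_real_)
      r <- suppressWarnings(cor(d$score[ok], p$score[mm[ok]],
                                method = "spearman"))
      if (is.na(r)) NA_real_ else r
    })
    if (all(is.na(rhos))) NA_real_ else mean(rhos, na.rm = TRUE)
  })
  mu <- mean(vals, na.rm = TRUE)
  sigma <- sd(vals, na.rm = TRUE)
  flagged <- which(!is.na(vals) & vals < mu - m * sigma)
  off <- (w - core) %/% 2
  removed <- sort(unique(unlist(lapply(starts[flagged],
                                       function(s) (s + off):(s + off + core - 1)))))
  setdiff(1:L, removed)
}

# Fresh scratch directory, cleaned up with the test frame.
local_dir <- function(env = parent.frame()) {
  d <- tempfile("dmsbench-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Small single-protein score-set builder for hand-constructed cases.
toy_set <- function(name, positions, alts, scores, protein = "P",
                    ref = "A", kind = "predictor",
                    orientation = "higher_damaging") {
  score_set(name, data.frame(protein = protein, position = positions,
                             ref = ref, alt = alts, score = scores),
            kind = kind, orientation = orientation)
}

# Entries scoring labelled variants as a pathogenicity indicator corrupted
# at a given flip rate (plus jitter to break ties).
flip_entry <- function(name, labels, flip_rate, seed) {
  keys <- rbind(labels$pathogenic, labels$benign)
  truth <- rep(c(1, 0), c(nrow(labels$pathogenic), nrow(labels$benign)))
  set.seed(seed)
  flip <- runif(length(truth)) < flip_rate
  s <- ifelse(flip, 1 - truth, truth) + rnorm(length(truth), sd = 0.01)
  score_set(name, cbind(keys, score = s), kind = "predictor",
            orientation = "higher_damaging")
}
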