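# Synthetic benchmark generator. Emulates the statistical structure of a
# DMS-vs-VEP benchmark with known ground truth: a latent per-protein fitness
# landscape (positional severity x residue-exchange component), noisy
# partial-coverage DMS assays, predictors with injected rank correlation to
# fitness (Gaussian copula), and pathogenic/benign label sets drawn from the
# fitness tails with flip noise.

#' Configuration of a synthetic benchmark
#'
#' Defaults describe the regime the package is validated in: five proteins,
#' two DMS assays each with noise calibrated so independent assays of one
#' protein correlate at about \eqn{\rho \approx 0.54} (`dms_noise_sd` =
#' 0.92, since two assays with unit-variance fitness and noise sd
#' \eqn{\sigma} correlate at \eqn{1/(1+\sigma^2)}), five predictors with
#' injected Spearman correlations 0.9/0.75/0.6/0.45/0.3 to fitness, and
#' 50+50 clinical labels per protein with 10% label-flip contamination.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Residues per protein.
#' @param predictors Data frame with columns `name`, `target_spearman`,
#'   `coverage`, `snv_only`, `orientation`.
#' @param dms_assays_per_protein Number of DMS assays per protein.
#' @param dms_noise_sd Gaussian assay noise sd (fitness has unit variance).
#' @param dms_coverage Fraction of the mutational universe each assay
#'   scores.
#' @param dms_orientation Orientation of emitted DMS scales
#'   (`"higher_benign"` mimics fitness scores).
#' @param clinical List with `pathogenic_quantile`, `n_pathogenic`,
#'   `n_benign`, `label_flip_prob`, and optionally `flip_mode`
#'   (`"symmetric"` or `"benign_only"` for one-sided contamination of the
#'   putatively benign class).
#' @param seed Master seed; all artifacts derive named substreams from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 5L,
                              protein_length = 150L,
                              predictors = default_predictor_grid(),
                              dms_assays_per_protein = 2L,
                              dms_noise_sd = 0.92,
                              dms_coverage = 0.8,
                              dms_orientation = "higher_benign",
                              clinical = list(pathogenic_quantile = 0.25,
                                              n_pathogenic = 50L,
                                              n_benign = 50L,
                                              label_flip_prob = 0.1),
                              seed = 1L) {
  predictors <- as.data.frame(predictors)
  stopifnot(n_proteins >= 1L, protein_length >= 1L,
            dms_assays_per_protein >= 1L, dms_noise_sd >= 0,
            dms_coverage > 0, dms_coverage <= 1,
            all(c("name", "target_spearman", "coverage", "snv_only",
                  "orientation") %in% names(predictors)),
            !anyDuplicated(predictors$name),
            all(predictors$target_spearman >= 0 & predictors$target_spearman <= 1),
            all(predictors$coverage > 0 & predictors$coverage <= 1),
            all(predictors$orientation %in% c("higher_damaging", "higher_benign")),
            dms_orientation %in% c("higher_damaging", "higher_benign"))
  clinical$flip_mode <- clinical$flip_mode %||% "symmetric"
  stopifnot(clinical$pathogenic_quantile > 0, clinical$pathogenic_quantile < 1,
            clinical$n_pathogenic >= 1L, clinical$n_benign >= 1L,
            clinical$label_flip_prob >= 0, clinical$label_flip_prob < 0.5,
            clinical$flip_mode %in% c("symmetric", "benign_only"))
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 predictors = predictors,
                 dms_assays_per_protein = as.integer(dms_assays_per_protein),
                 dms_noise_sd = dms_noise_sd,
                 dms_coverage = dms_coverage,
                 dms_orientation = dms_orientation,
                 clinical = clinical,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_predictor_grid <- function() {
  data.frame(name = sprintf("vep%02d", 1:5),
             target_spearman = c(0.9, 0.75, 0.6, 0.45, 0.3),
             coverage = 0.9,
             snv_only = c(FALSE, FALSE, TRUE, FALSE, FALSE),
             orientation = "higher_damaging",
             stringsAsFactors = FALSE)
}

#' Simulate a latent fitness landscape for one protein
#'
#' Draws a random sequence (and a coding sequence realising it), then a
#' damage value for every one of the `19 x protein_length` substitutions:
#' a smoothly varying positional severity (moving-average Gaussian process,
#' giving positive lag-1 autocorrelation along the sequence), plus a
#' per-residue exchange component and i.i.d. scatter. The landscape is
#' standardised to zero mean and unit variance; higher values are more
#' damaging.
#'
#' @param protein_length Number of residues.
#' @param seed Integer seed (landscape is a pure function of it).
#' @param protein Protein identifier.
#' @return List with `record` (a [protein_record()] with CDS) and `fitness`
#'   (data frame `protein`, `position`, `ref`, `alt`, `fitness`).
#' @export
simulate_fitness <- function(protein_length, seed, protein = "P01") {
  L <- as.integer(protein_length)
  stopifnot(L >= 1L)
  code <- genetic_code()
  sense <- code[code != "*"]
  with_seed(seed, {
    sequence <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    res <- strsplit(sequence, "")[[1]]
    cds <- paste(vapply(res, function(a) {
      cods <- names(sense)[sense == a]
      cods[sample.int(length(cods), 1L)]
    }, ""), collapse = "")
    k <- 9L
    raw <- stats::rnorm(L + k - 1L)
    sm <- stats::filter(raw, rep(1 / k, k), sides = 2)
    pos_sev <- as.numeric(sm[!is.na(sm)])[seq_len(L)]
    pos_sev <- as.numeric(scale(pos_sev))
    exch <- stats::setNames(stats::rnorm(20), AA_ALPHABET)
    alts <- lapply(res, function(a) setdiff(AA_ALPHABET, a))
    fit <- data.frame(protein = protein,
                      position = rep(seq_len(L), each = 19L),
                      ref = rep(res, each = 19L),
                      alt = unlist(alts),
                      stringsAsFactors = FALSE)
    f <- pos_sev[fit$position] + 0.45 * exch[fit$alt] +
      0.35 * stats::rnorm(nrow(fit))
    fit$fitness <- as.numeric((f - mean(f)) / stats::sd(f))
    list(record = protein_record(protein, sequence, cds = cds), fitness = fit)
  })
}

#' Simulate a DMS assay from a fitness landscape
#'
#' Assay score = latent fitness + Gaussian noise, on a random binomial
#' subset of the landscape (partial coverage). Under the default
#' `higher_benign` orientation the stored scores are sign-flipped so that,
#' like real functional scores, high values mark tolerated variants.
#'
#' @param fitness Fitness data frame from [simulate_fitness()].
#' @param noise_sd Gaussian noise standard deviation.
#' @param coverage Inclusion probability per variant in `(0, 1]`.
#' @param orientation Emitted scale orientation.
#' @param seed Integer seed.
#' @param name Assay name.
#' @return A DMS [score_set()].
#' @export
simulate_dms <- function(fitness, noise_sd, coverage, seed,
                         orientation = "higher_benign",
                         name = "assay") {
  with_seed(seed, {
    damage <- fitness$fitness + stats::rnorm(nrow(fitness), sd = noise_sd)
    keep <- stats::runif(nrow(fitness)) <= coverage
    if (sum(keep) < 3L) keep[seq_len(3L)] <- TRUE
    df <- fitness[keep, c("protein", "position", "ref", "alt")]
    df$score <- orient(damage[keep], orientation)  # involution: store on scale
    score_set(name, df, kind = "dms", orientation = orientation)
  })
}

#' Simulate a predictor with an injected Spearman correlation to fitness
#'
#' Gaussian-copula construction: the fitness landscape is rank-transformed
#' to normal scores and mixed with independent Gaussian noise at Pearson
#' weight \eqn{r = 2 \sin(\pi \rho_s / 6)}, the bivariate-normal value whose
#' Spearman correlation is the target, so the realised rank correlation
#' converges to `target_spearman` as the landscape grows.
#'
#' @param fitness Fitness data frame from [simulate_fitness()].
#' @param target_spearman Target rank correlation in `[0, 1]`.
#' @param coverage Inclusion probability per variant.
#' @param seed Integer seed.
#' @param orientation Emitted scale orientation.
#' @param name Predictor name.
#' @param snv_only Restrict the universe to substitutions reachable by a
#'   single nucleotide change (requires `record`).
#' @param record A [protein_record()] with CDS, needed when
#'   `snv_only = TRUE`.
#' @return A predictor [score_set()].
#' @export
simulate_predictor <- function(fitness, target_spearman, coverage, seed,
                               orientation = "higher_damaging",
                               name = "vep", snv_only = FALSE,
                               record = NULL) {
  stopifnot(target_spearman >= 0, target_spearman <= 1)
  df <- fitness
  if (snv_only) {
    if (is.null(record)) stopf("snv_only predictors need a protein record")
    uni <- snv_universe(record)
    df <- df[key_df_ids(df) %in% key_df_ids(uni), , drop = FALSE]
  }
  n <- nrow(df)
  with_seed(seed, {
    z <- stats::qnorm((rank(df$fitness) - 0.5) / n)
    r <- 2 * sin(pi * target_spearman / 6)
    pred <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    keep <- stats::runif(n) <= coverage
    if (sum(keep) < 3L) keep[seq_len(3L)] <- TRUE
    out <- df[keep, c("protein", "position", "ref", "alt")]
    out$score <- orient(pred[keep], orientation)
    score_set(name, out, kind = "predictor", orientation = orientation)
  })
}

#' Simulate pathogenic / putatively benign labels from a fitness landscape
#'
#' Pathogenic variants are sampled (without replacement) from the
#' most-damaging `pathogenic_quantile` tail of the landscape, benign
#' variants from the remainder; each sampled variant's label is then
#' flipped independently with probability `label_flip_prob`. With
#' `flip_mode = "benign_only"` the pathogenic class stays clean and the
#' affected benign slots are instead refilled with truly damaging variants
#' (one-sided contamination of the putatively benign class, the structure
#' population databases show). Classes stay disjoint by construction.
#'
#' @param fitness Fitness data frame from [simulate_fitness()].
#' @param pathogenic_quantile Upper tail mass defining the pathogenic pool.
#' @param n_pathogenic,n_benign Label counts to draw.
#' @param label_flip_prob Per-label flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param flip_mode `"symmetric"` or `"benign_only"`.
#' @return A [clinical_labels()].
#' @export
simulate_clinical <- function(fitness, pathogenic_quantile, n_pathogenic,
                              n_benign, label_flip_prob, seed,
                              flip_mode = "symmetric") {
  thr <- stats::quantile(fitness$fitness, 1 - pathogenic_quantile,
                         names = FALSE)
  pool_path <- which(fitness$fitness >= thr)
  pool_ben <- which(fitness$fitness < thr)
  if (length(pool_path) < n_pathogenic || length(pool_ben) < n_benign)
    stopf("requested %d+%d labels exceed available pools (%d damaging, %d tolerant)",
          n_pathogenic, n_benign, length(pool_path), length(pool_ben))
  with_seed(seed, {
    ip <- sample(pool_path, n_pathogenic)
    ib <- sample(pool_ben, n_benign)
    lab <- rep(c("pathogenic", "benign"), c(n_pathogenic, n_benign))
    idx <- c(ip, ib)
    flip <- stats::runif(length(idx)) < label_flip_prob
    if (flip_mode == "symmetric") {
      lab[flip] <- ifelse(lab[flip] == "pathogenic", "benign", "pathogenic")
    } else {
      # benign_only: the pathogenic class stays clean; contaminated benign
      # slots are refilled from the damaging pool instead
      contam <- which(flip & lab == "benign")
      if (length(contam)) {
        spare <- setdiff(pool_path, ip)
        if (length(spare) < length(contam))
          stopf("damaging pool too small for the requested contamination")
        idx[contam] <- sample(spare, length(contam))
      }
    }
    keys <- fitness[idx, c("protein", "position", "ref", "alt")]
    clinical_labels(fitness$protein[1],
                    keys[lab == "pathogenic", , drop = FALSE],
                    keys[lab == "benign", , drop = FALSE])
  })
}

#' Simulate a complete benchmark bundle
#'
#' Generates, per protein, a fitness landscape, DMS assays, predictor score
#' sets and clinical labels, plus a ground-truth manifest recording every
#' injected parameter (including the true predictor quality ordering).
#' Randomness flows from `config$seed` through named substreams per
#' artifact, so the same seed gives byte-identical output files and
#' regenerating one component leaves the others unchanged. With `out_dir`
#' the bundle is written in the TSV/FASTA/YAML dialects consumed by
#' [load_benchmark()] and the pipeline drivers.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return (Invisibly, when writing) a bundle list: `records`, `fitness`,
#'   `dms` (per protein), `predictors`, `labels`, `manifest`, `config`.
#' @export
simulate_benchmark <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  prots <- sprintf("P%02d", seq_len(config$n_proteins))
  records <- list(); fitness <- list(); dms <- list(); labels <- list()
  pred_rows <- stats::setNames(vector("list", nrow(config$predictors)),
                               config$predictors$name)
  for (pr in prots) {
    fl <- simulate_fitness(config$protein_length,
                           derive_seed(seed, "fitness", pr), protein = pr)
    records[[pr]] <- fl$record
    fitness[[pr]] <- fl$fitness
    dms[[pr]] <- lapply(seq_len(config$dms_assays_per_protein), function(a)
      simulate_dms(fl$fitness, config$dms_noise_sd, config$dms_coverage,
                   derive_seed(seed, "dms", pr, a),
                   orientation = config$dms_orientation,
                   name = sprintf("%s_assay%d", pr, a)))
    names(dms[[pr]]) <- vapply(dms[[pr]], set_name, "")
    for (k in seq_len(nrow(config$predictors))) {
      p <- config$predictors[k, ]
      ps <- simulate_predictor(fl$fitness, p$target_spearman, p$coverage,
                               derive_seed(seed, "predictor", p$name, pr),
                               orientation = p$orientation, name = p$name,
                               snv_only = p$snv_only, record = fl$record)
      pred_rows[[p$name]] <- rbind(pred_rows[[p$name]], as.data.frame(ps))
    }
    labels[[pr]] <- simulate_clinical(fl$fitness,
                                      config$clinical$pathogenic_quantile,
                                      config$clinical$n_pathogenic,
                                      config$clinical$n_benign,
                                      config$clinical$label_flip_prob,
                                      derive_seed(seed, "labels", pr),
                                      flip_mode = config$clinical$flip_mode)
  }
  predictors <- lapply(config$predictors$name, function(nm)
    score_set(nm, pred_rows[[nm]], kind = "predictor",
              orientation = config$predictors$orientation[
                config$predictors$name == nm]))
  names(predictors) <- config$predictors$name
  ord <- config$predictors$name[order(-config$predictors$target_spearman,
                                      config$predictors$name)]
  manifest <- list(seed = seed,
                   n_proteins = config$n_proteins,
                   protein_length = config$protein_length,
                   predictors = config$predictors,
                   dms_assays_per_protein = config$dms_assays_per_protein,
                   dms_noise_sd = config$dms_noise_sd,
                   dms_coverage = config$dms_coverage,
                   dms_orientation = config$dms_orientation,
                   clinical = config$clinical,
                   true_predictor_order = ord)
  bundle <- list(records = records, fitness = fitness, dms = dms,
                 predictors = predictors, labels = labels,
                 manifest = manifest, config = config)
  if (!is.null(out_dir)) {
    write_benchmark(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a benchmark bundle to disk
#'
#' Layout: `proteins.fasta` + `cds.fasta`, `dms/<assay>.tsv`,
#' `predictors/<name>.tsv`, `labels.tsv`, `config.yaml` (orientations and
#' nucleotide-level flags) and `manifest.json` (injected ground truth).
#'
#' @param bundle A bundle from [simulate_benchmark()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "dms"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "predictors"), showWarnings = FALSE)
  write_protein_records(bundle$records,
                        file.path(out_dir, "proteins.fasta"),
                        file.path(out_dir, "cds.fasta"))
  for (pr in names(bundle$dms)) for (a in bundle$dms[[pr]])
    write_score_table(a, file.path(out_dir, "dms",
                                   paste0(set_name(a), ".tsv")))
  for (p in bundle$predictors)
    write_score_table(p, file.path(out_dir, "predictors",
                                   paste0(set_name(p), ".tsv")))
  write_label_table(bundle$labels, file.path(out_dir, "labels.tsv"))
  cfg <- list(dms_orientation = bundle$manifest$dms_orientation,
              predictors = lapply(seq_len(nrow(bundle$config$predictors)),
                                  function(k) {
                p <- bundle$config$predictors[k, ]
                list(orientation = p$orientation,
                     nucleotide_level = FALSE, display = p$name)
              }))
  names(cfg$predictors) <- bundle$config$predictors$name
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load a benchmark bundle written by [write_benchmark()]
#'
#' @param dir Bundle directory.
#' @return A bundle list as returned by [simulate_benchmark()] (without the
#'   latent fitness landscapes, which are not part of the on-disk format;
#'   the manifest still records the injected parameters).
#' @export
load_benchmark <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  records <- read_protein_records(file.path(dir, "proteins.fasta"),
                                  file.path(dir, "cds.fasta"))
  dms_files <- sort(list.files(file.path(dir, "dms"), "\\.tsv$",
                               full.names = TRUE))
  dms_sets <- lapply(dms_files, read_score_table, kind = "dms",
                     orientation = cfg$dms_orientation %||% "higher_benign")
  dms <- split(dms_sets,
               vapply(dms_sets, function(s) s$protein[1], ""))
  dms <- lapply(dms, function(l)
    stats::setNames(l, vapply(l, set_name, "")))
  predictors <- lapply(names(cfg$predictors), function(nm) {
    d <- cfg$predictors[[nm]]
    read_score_table(file.path(dir, "predictors", paste0(nm, ".tsv")),
                     name = nm, kind = "predictor",
                     orientation = d$orientation,
                     nucleotide_level = isTRUE(d$nucleotide_level))
  })
  names(predictors) <- names(cfg$predictors)
  labels <- read_label_table(file.path(dir, "labels.tsv"))
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  list(records = records, fitness = NULL, dms = dms,
       predictors = predictors, labels = labels, manifest = manifest,
       config = cfg)
}
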