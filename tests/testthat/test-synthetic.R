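test_that("fitness landscapes are deterministic, complete, and positionally autocorrelated", {
  fl1 <- simulate_fitness(40, seed = 11)
  fl2 <- simulate_fitness(40, seed = 11)
  expect_identical(fl1, fl2)
  expect_equal(nrow(fl1$fitness), 19 * 40)
  expect_false(identical(fl1$fitness$fitness,
                         simulate_fitness(40, seed = 12)$fitness$fitness))
  # positional severity is smooth: lag-1 autocorrelation of per-position
  # mean damage is positive across seeds
  ac1 <- vapply(1:10, function(s) {
    f <- simulate_fitness(80, seed = s)$fitness
    m <- tapply(f$fitness, f$position, mean)
    stats::cor(m[-1], m[-length(m)])
  }, 0)
  expect_true(all(ac1 > 0))
  expect_gt(mean(ac1), 0.4)
})

test_that("noiseless full-coverage DMS reproduces the fitness ordering", {
  fl <- simulate_fitness(30, seed = 21)
  d <- simulate_dms(fl$fitness, noise_sd = 0, coverage = 1, seed = 22,
                    orientation = "higher_benign")
  m <- match(key_ids <- paste(d$position, d$ref, d$alt),
             paste(fl$fitness$position, fl$fitness$ref, fl$fitness$alt))
  expect_equal(spearman(orient(d$score, "higher_benign"),
                        fl$fitness$fitness[m]), 1)
})

test_that("DMS coverage follows the requested inclusion probability", {
  fl <- simulate_fitness(100, seed = 31)
  d <- simulate_dms(fl$fitness, noise_sd = 0.5, coverage = 0.5, seed = 32)
  n <- nrow(d)
  # binomial(1900, 0.5): within 4 sd of the mean
  expect_lt(abs(n - 950), 4 * sqrt(1900 * 0.25))
})

test_that("independent assays at the default noise land in the moderate-correlation band", {
  rhos <- vapply(1:8, function(s) {
    fl <- simulate_fitness(60, seed = 400 + s)
    a1 <- simulate_dms(fl$fitness, 0.92, 1, seed = 500 + s, name = "a1")
    a2 <- simulate_dms(fl$fitness, 0.92, 1, seed = 600 + s, name = "a2")
    cross_assay_correlations(list(a1, a2))["a1", "a2"]
  }, 0)
  expect_true(all(rhos > 0.35 & rhos < 0.65))
  expect_lt(abs(mean(rhos) - 0.52), 0.08)
})

test_that("copula calibration hits the target Spearman at large n", {
  fl <- simulate_fitness(530, seed = 41)  # ~10,000 substitutions
  p <- simulate_predictor(fl$fitness, 0.6, coverage = 1, seed = 42)
  m <- match(paste(p$position, p$ref, p$alt),
             paste(fl$fitness$position, fl$fitness$ref, fl$fitness$alt))
  rho <- spearman(p$score, fl$fitness$fitness[m])
  expect_lt(abs(rho - 0.6), 0.02)
  # extremes
  p1 <- simulate_predictor(fl$fitness, 1, coverage = 1, seed = 43)
  m1 <- match(paste(p1$position, p1$ref, p1$alt),
              paste(fl$fitness$position, fl$fitness$ref, fl$fitness$alt))
  expect_equal(spearman(p1$score, fl$fitness$fitness[m1]), 1)
  p0 <- simulate_predictor(fl$fitness, 0, coverage = 1, seed = 44)
  rho0 <- spearman(p0$score, fl$fitness$fitness[m1])
  expect_lt(abs(rho0), 0.05)
})

test_that("snv_only predictors score only single-nucleotide-reachable substitutions", {
  fl <- simulate_fitness(25, seed = 51)
  p <- simulate_predictor(fl$fitness, 0.8, coverage = 1, seed = 52,
                          snv_only = TRUE, record = fl$record)
  uni <- snv_universe(fl$record)
  expect_true(all(paste(p$position, p$alt) %in% paste(uni$position, uni$alt)))
  expect_lt(nrow(p), nrow(fl$fitness))
})

test_that("clinical label simulation respects pools, flips, and disjointness", {
  fl <- simulate_fitness(60, seed = 61)
  lab0 <- simulate_clinical(fl$fitness, 0.25, 40, 40, 0, seed = 62)
  # flip 0: a noiseless damage predictor attains AUROC 1 on these labels
  ids <- paste(fl$fitness$position, fl$fitness$ref, fl$fitness$alt)
  sc <- function(df) fl$fitness$fitness[match(paste(df$position, df$ref,
                                                    df$alt), ids)]
  expect_equal(auroc(sc(lab0$pathogenic), sc(lab0$benign)), 1)
  # flip noise has a closed-form effect on the noiseless predictor: the two
  # pools occupy disjoint fitness ranges, so a positive beats a negative
  # unless exactly one of the pair is flipped on the "wrong" side:
  # E[AUROC] = (1-p)^2 + 2 p (1-p) / 2 = 1 - p
  mc_auroc <- function(p, seeds) mean(vapply(seeds, function(s) {
    l <- simulate_clinical(fl$fitness, 0.25, 50, 50, p, seed = s)
    auroc(sc(l$pathogenic), sc(l$benign))
  }, 0))
  expect_lt(abs(mc_auroc(0.1, 200 + 1:30) - 0.9), 0.02)
  # near-maximal flip noise: labels nearly uninformative
  expect_lt(abs(mc_auroc(0.49, 100 + 1:10) - 0.51), 0.05)
  expect_error(simulate_clinical(fl$fitness, 0.25, 10000, 10, 0, seed = 1),
               "exceed")
  # benign-only contamination never flips pathogenic labels
  labb <- simulate_clinical(fl$fitness, 0.25, 40, 40, 0.3, seed = 63,
                            flip_mode = "benign_only")
  thr <- stats::quantile(fl$fitness$fitness, 0.75, names = FALSE)
  expect_true(all(sc(labb$pathogenic) >= thr))
})

test_that("benchmark bundles are byte-identical under one seed and substream-stable", {
  cfg <- simulation_config(n_proteins = 2, protein_length = 30, seed = 77)
  d1 <- local_dir(); d2 <- local_dir()
  simulate_benchmark(cfg, out_dir = d1)
  simulate_benchmark(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # changing only the clinical component leaves DMS and predictors unchanged
  cfg2 <- simulation_config(n_proteins = 2, protein_length = 30, seed = 77,
                            clinical = list(pathogenic_quantile = 0.25,
                                            n_pathogenic = 20L,
                                            n_benign = 20L,
                                            label_flip_prob = 0.2))
  b1 <- simulate_benchmark(cfg)
  b2 <- simulate_benchmark(cfg2)
  expect_identical(b1$dms, b2$dms)
  expect_identical(b1$predictors, b2$predictors)
  expect_false(identical(b1$labels, b2$labels))
})

test_that("written bundles load back into equivalent inputs", {
  cfg <- simulation_config(n_proteins = 2, protein_length = 25, seed = 88)
  d <- local_dir()
  b <- simulate_benchmark(cfg, out_dir = d)
  lb <- load_benchmark(d)
  expect_setequal(names(lb$predictors), names(b$predictors))
  for (nm in names(b$predictors))
    expect_equal(as.data.frame(lb$predictors[[nm]]),
                 as.data.frame(b$predictors[[nm]]))
  for (pr in names(b$dms))
    for (a in names(b$dms[[pr]]))
      expect_equal(as.data.frame(lb$dms[[pr]][[a]]),
                   as.data.frame(b$dms[[pr]][[a]]),
                   tolerance = 1e-12)
  expect_equal(lb$manifest$true_predictor_order, b$manifest$true_predictor_order)
  expect_setequal(names(lb$labels), names(b$labels))
})
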