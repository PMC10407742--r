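# Toy landscape shared by several cases: one protein, continuous DMS scores.
make_toy_corr <- function(n = 60, seed = 5, rhos = c(a = 0.95, b = 0.6, c = 0.2)) {
  set.seed(seed)
  dms_scores <- rnorm(n)
  alts <- rep(c("V", "L", "I"), length.out = n)
  dms <- toy_set("dms", seq_len(n), alts, dms_scores, kind = "dms")
  preds <- lapply(names(rhos), function(nm) {
    r <- rhos[[nm]]
    toy_set(nm, seq_len(n), alts, r * dms_scores + sqrt(1 - r^2) * rnorm(n))
  })
  list(dms = dms, preds = preds)
}

test_that("a predictor identical to the DMS scores wins every comparison", {
  toy <- make_toy_corr()
  copy <- toy_set("copy", toy$dms$position, toy$dms$alt, toy$dms$score)
  rows <- pairwise_corr_tournament(toy$dms, c(list(copy), toy$preds),
                                   min_shared = 10)
  expect_equal(rows$rank_score[rows$predictor == "copy"], 1)
  # conservation: summed points equal executed comparisons
  expect_equal(sum(rows$points), sum(rows$comparisons) / 2)
})

test_that("identical predictors split every comparison as ties", {
  toy <- make_toy_corr(rhos = c(a = 0.8))
  twin <- toy_set("a_twin", toy$preds[[1]]$position, toy$preds[[1]]$alt,
                  toy$preds[[1]]$score)
  rows <- pairwise_corr_tournament(toy$dms, c(toy$preds, list(twin)), 10)
  expect_equal(rows$rank_score, c(0.5, 0.5))
  expect_equal(rows$points, c(0.5, 0.5))
})

test_that("tournament is invariant to predictor order and monotone transforms", {
  toy <- make_toy_corr()
  rows <- pairwise_corr_tournament(toy$dms, toy$preds, 10)
  perm <- pairwise_corr_tournament(toy$dms, rev(toy$preds), 10)
  expect_equal(rows[order(rows$predictor), ],
               perm[order(perm$predictor), ], ignore_attr = TRUE)
  warped <- lapply(toy$preds, function(p) {
    q <- as.data.frame(p); q$score <- exp(q$score) + q$score^3
    score_set(set_name(p), q)
  })
  expect_equal(pairwise_corr_tournament(toy$dms, warped, 10), rows)
})

test_that("pairs below min_shared are skipped and counted for neither side", {
  toy <- make_toy_corr(n = 30)
  sparse <- toy_set("sparse", 1:5, rep("V", 5), rnorm(5))
  rows <- pairwise_corr_tournament(toy$dms, c(toy$preds, list(sparse)), 10)
  expect_equal(rows$comparisons[rows$predictor == "sparse"], 0L)
  expect_true(is.na(rows$rank_score[rows$predictor == "sparse"]))
  expect_equal(unique(rows$comparisons[rows$predictor != "sparse"]), 2L)
})

test_that("overall rank scores are unweighted means over participating proteins", {
  rows <- data.frame(predictor = c("x", "x", "y", "y"),
                     protein = c("P1", "P2", "P1", "P2"),
                     points = c(1, 2, 0, 1), comparisons = c(5, 5, 5, 0),
                     rank_score = c(0.2, 0.8, 0.0, NA))
  ov <- overall_rank_scores(rows)
  expect_equal(ov$rank_score[ov$predictor == "x"], 0.5)
  expect_equal(ov$n_proteins[ov$predictor == "y"], 1L)
  expect_equal(ov$rank_score[ov$predictor == "y"], 0)
})

test_that("cross-assay correlation matrix is symmetric with unit diagonal and absolute values", {
  toy <- make_toy_corr()
  neg <- toy_set("neg", toy$dms$position, toy$dms$alt, -toy$dms$score,
                 kind = "dms")
  m <- cross_assay_correlations(list(toy$dms, neg))
  expect_equal(m["dms", "neg"], 1)      # |rho| of own negation
  expect_equal(diag(m), c(dms = 1, neg = 1))
  expect_equal(m, t(m))
})

test_that("representative assay is the one with highest median |rho| to predictors", {
  toy <- make_toy_corr(n = 80)
  set.seed(9)
  noise <- toy_set("noise_assay", toy$dms$position, toy$dms$alt, rnorm(80),
                   kind = "dms")
  # the real landscape assay beats an unrelated-noise assay
  expect_equal(select_representative_assay(list(noise, toy$dms), toy$preds),
               "dms")
  # single assay: trivially selected; ties: lexicographic with a message
  expect_equal(select_representative_assay(list(noise), toy$preds),
               "noise_assay")
  dup <- toy_set("aaa", toy$dms$position, toy$dms$alt, toy$dms$score,
                 kind = "dms")
  expect_message(
    pick <- select_representative_assay(list(toy$dms, dup), toy$preds),
    "tie")
  expect_equal(pick, "aaa")
})

test_that("most-benign imputation fills gaps per protein and never edits existing scores", {
  uni <- data.frame(protein = "P", position = rep(1:2, each = 2),
                    ref = "A", alt = rep(c("V", "L"), 2))
  p <- score_set("p", data.frame(protein = "P", position = c(1, 1),
                                 ref = "A", alt = c("V", "L"),
                                 score = c(0.9, 0.2)))
  imp <- impute_most_benign(p, uni)
  expect_equal(nrow(imp), 4L)
  expect_equal(imp$score[imp$position == 2], c(0.2, 0.2))
  expect_equal(imp$score[imp$position == 1], c(0.2, 0.9)[order(c("L", "V"))])
  # higher_benign orientation: the benign extreme is the maximum
  pb <- score_set("pb", as.data.frame(p), orientation = "higher_benign")
  impb <- impute_most_benign(pb, uni)
  expect_equal(impb$score[impb$position == 2], c(0.9, 0.9))
  # complete coverage: imputation is a no-op
  expect_equal(as.data.frame(impute_most_benign(rewrap_full <- imp, uni)),
               as.data.frame(imp))
  expect_error(impute_most_benign(
    score_set("q", p[0, ]), uni), "no scores")
})

test_that("imputation leaves tournament results unchanged at complete coverage", {
  toy <- make_toy_corr()
  uni <- as.data.frame(toy$dms)[c("protein", "position", "ref", "alt")]
  imputed <- lapply(toy$preds, impute_most_benign, universe = uni)
  expect_equal(pairwise_corr_tournament(toy$dms, imputed, 10),
               pairwise_corr_tournament(toy$dms, toy$preds, 10))
})

test_that("window filter removes nothing when per-window correlation is constant", {
  # predictors equal to the DMS scores: every window correlates at exactly 1
  L <- 50
  set.seed(3)
  sc <- rnorm(19 * L)
  df <- data.frame(protein = "P", position = rep(1:L, each = 19),
                   ref = rep("A", 19 * L),
                   alt = setdiff(c("C","D","E","F","G","H","I","K","L","M",
                                   "N","P","Q","R","S","T","V","W","Y","A"), "A"),
                   score = sc)
  dms <- score_set("dms", df, kind = "dms")
  pred <- score_set("pred", df)
  rec <- protein_record("P", strrep("A", L))
  kept <- window_filter(dms, list(pred), rec)
  expect_equal(as.integer(kept), 1:L)
  expect_length(attr(kept, "removed"), 0L)
})

test_that("window filter flags a scrambled segment and matches the brute-force oracle", {
  L <- 100
  fl <- simulate_fitness(L, seed = 21, protein = "P")
  dms_df <- fl$fitness
  names(dms_df)[names(dms_df) == "fitness"] <- "score"
  # scramble the DMS scores inside residues 36..65 so no predictor matches there
  seg <- which(dms_df$position >= 36 & dms_df$position <= 65)
  set.seed(22)
  dms_df$score[seg] <- sample(dms_df$score[seg])
  dms <- score_set("dms", dms_df, kind = "dms")
  preds <- lapply(1:3, function(k)
    simulate_predictor(fl$fitness, 0.85, coverage = 1, seed = 100 + k,
                       name = paste0("v", k)))
  rec <- fl$record
  kept <- window_filter(dms, preds, rec)
  removed <- attr(kept, "removed")
  expect_gt(length(removed), 0)
  # removal concentrates on the scrambled segment's core
  expect_gt(length(intersect(removed, 41:60)) / length(removed), 0.5)
  oracle <- window_oracle(as.data.frame(dms), lapply(preds, as.data.frame), L)
  expect_equal(as.integer(kept), oracle)
})

test_that("window filter refuses proteins shorter than the window", {
  toy <- make_toy_corr(n = 10)
  rec <- protein_record("P", strrep("A", 10))
  expect_error(window_filter(toy$dms, toy$preds, rec), "shorter")
})
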