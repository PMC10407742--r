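make_labels <- function(n_pos = 20, n_neg = 20, protein = "P", seed = 1) {
  set.seed(seed)
  pos <- data.frame(protein = protein, position = 1:n_pos, ref = "A",
                    alt = "V")
  neg <- data.frame(protein = protein, position = 1:n_neg, ref = "A",
                    alt = "L")
  clinical_labels(protein, pos, neg)
}

test_that("benign set excludes variants also reported pathogenic", {
  pth <- data.frame(protein = "P", position = 1:12, ref = "A", alt = "V")
  ben <- data.frame(protein = "P", position = c(1:3, 20:30), ref = "A",
                    alt = c(rep("V", 3), rep("L", 11)))
  expect_message(l <- build_label_set(pth, ben), "3 variant")
  expect_equal(nrow(l$benign), 11L)
  expect_equal(nrow(l$pathogenic), 12L)
  # disjoint inputs pass through unchanged; pooling de-duplicates by union
  expect_silent(l2 <- build_label_set(pth, ben[4:14, ]))
  merged <- build_label_set(rbind(pth, pth), ben[4:14, ])
  expect_equal(nrow(merged$pathogenic), 12L)
})

test_that("protein eligibility thresholds are inclusive", {
  rule <- eligibility_rule()
  expect_true(protein_eligible(make_labels(10, 10), rule))
  expect_false(protein_eligible(make_labels(9, 100), rule))
  expect_false(protein_eligible(make_labels(1, 1), rule))
})

test_that("a noiseless pathogenicity indicator wins the whole class tournament", {
  labels <- make_labels(25, 25)
  perfect <- flip_entry("perfect", labels, 0, seed = 2)
  noisy <- flip_entry("noisy", labels, 0.2, seed = 3)
  worse <- flip_entry("worse", labels, 0.4, seed = 4)
  rows <- pairwise_class_tournament(list(perfect, noisy, worse), labels)
  expect_equal(rows$rank_score[rows$entry == "perfect"], 1)
  expect_equal(rows$metric_value[rows$entry == "perfect"], 1)
  expect_equal(sum(rows$points), sum(rows$comparisons) / 2)
  expect_equal(mean(rows$rank_score), 0.5)  # full round robin
})

test_that("identical entries tie at half a point each", {
  labels <- make_labels(15, 15)
  a <- flip_entry("a", labels, 0.1, seed = 5)
  b <- score_set("b", as.data.frame(a))
  rows <- pairwise_class_tournament(list(a, b), labels)
  expect_equal(rows$points, c(0.5, 0.5))
  expect_equal(rows$rank_score, c(0.5, 0.5))
})

test_that("entries ranked by label-flip noise recover the quality ordering", {
  labels <- make_labels(50, 50)
  entries <- Map(flip_entry, c("e0", "e1", "e3"), list(labels),
                 c(0, 0.1, 0.3), 11:13)
  rows <- pairwise_class_tournament(unname(entries), labels)
  expect_equal(rows$entry[order(-rows$rank_score)], c("e0", "e1", "e3"))
  # cross-checked against the pair-counting oracle on the shared (full) sets
  s <- function(e) {
    d <- as.data.frame(e)
    ids <- paste(d$position, d$ref, d$alt)
    pk <- paste(labels$pathogenic$position, labels$pathogenic$ref,
                labels$pathogenic$alt)
    list(pos = d$score[match(pk, ids)], neg = d$score[-match(pk, ids)])
  }
  for (e in entries) {
    sc <- s(e)
    expect_equal(rows$metric_value[rows$entry == set_name(e)],
                 auroc_pairs(sc$pos, sc$neg))
  }
})

test_that("pairs sharing too few labelled variants are skipped", {
  labels <- make_labels(15, 15)
  full <- flip_entry("full", labels, 0.1, seed = 6)
  # scores only 5 pathogenic variants: below min_shared_pathogenic
  sparse_keys <- rbind(labels$pathogenic[1:5, ], labels$benign)
  set.seed(8)
  sparse <- score_set("sparse", cbind(sparse_keys, score = rnorm(20)))
  rows <- pairwise_class_tournament(list(full, sparse), labels)
  expect_equal(rows$comparisons, c(0L, 0L))
})

test_that("flipping every entry's orientation reverses a tie-free tournament", {
  labels <- make_labels(20, 20)
  entries <- Map(flip_entry, c("x", "y", "z"), list(labels),
                 c(0.05, 0.15, 0.3), 21:23)
  rows <- pairwise_class_tournament(unname(entries), labels)
  flipped <- lapply(entries, function(e)
    score_set(set_name(e), as.data.frame(e), orientation = "higher_benign"))
  rows_f <- pairwise_class_tournament(unname(flipped), labels)
  expect_equal(rows_f$metric_value, 1 - rows$metric_value)
  expect_equal(rows_f$points, rows$comparisons - rows$points)
})

test_that("AUROC and AUBPRC tournaments agree under stochastic dominance", {
  labels <- make_labels(30, 30)
  perfect <- flip_entry("perfect", labels, 0, seed = 31)
  noisy <- flip_entry("noisy", labels, 0.35, seed = 32)
  for (m in c("auroc", "aubprc")) {
    rows <- pairwise_class_tournament(list(perfect, noisy), labels, metric = m)
    expect_equal(rows$points[rows$entry == "perfect"], 1, info = m)
  }
})

test_that("best DMS per protein picks the top-ranked set, lexicographic on ties", {
  labels <- make_labels(20, 20)
  good <- flip_entry("good_assay", labels, 0, seed = 41)
  bad <- flip_entry("bad_assay", labels, 0.4, seed = 42)
  good <- score_set("good_assay", as.data.frame(good), kind = "dms")
  bad <- score_set("bad_assay", as.data.frame(bad), kind = "dms")
  vep <- flip_entry("vep", labels, 0.2, seed = 43)
  rows <- pairwise_class_tournament(list(good, bad, vep), labels)
  expect_equal(best_dms_per_protein(rows)$entry, "good_assay")
  # tie: two copies -> lexicographically first, with a message
  twin <- score_set("aaa_assay", as.data.frame(good), kind = "dms")
  rows2 <- pairwise_class_tournament(list(good, twin, vep), labels)
  expect_message(pick <- best_dms_per_protein(rows2), "tie")
  expect_equal(pick$entry, "aaa_assay")
})

test_that("auto_orient flips inverse predictors only when asked", {
  labels <- make_labels(20, 20)
  e <- flip_entry("e", labels, 0, seed = 51)
  inv <- score_set("inv", {
    d <- as.data.frame(e); d$score <- -d$score; d
  })
  # declared orientation is wrong: AUROC < 0.5
  expect_silent(out <- auto_orient(inv, labels, flip = FALSE))
  expect_lt(attr(out, "auroc"), 0.5)
  expect_equal(set_orientation(out), "higher_damaging")
  expect_warning(out2 <- auto_orient(inv, labels, flip = TRUE), "inverse")
  expect_equal(set_orientation(out2), "higher_benign")
  expect_equal(attr(auto_orient(out2, labels), "auroc"),
               1 - attr(out, "auroc"))
  # a well-oriented entry is never touched
  expect_silent(ok <- auto_orient(e, labels, flip = TRUE))
  expect_equal(set_orientation(ok), "higher_damaging")
})

test_that("benchmark concordance is Spearman over shared entries", {
  a <- data.frame(predictor = c("p1", "p2", "p3", "p4"),
                  rank_score = c(0.9, 0.7, 0.5, 0.2))
  expect_equal(benchmark_concordance(a, a), 1)
  b <- a; b$rank_score <- rev(b$rank_score)
  expect_equal(benchmark_concordance(a, b), -1)
  expect_error(benchmark_concordance(a, a[1:2, ]), ">= 3")
})
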