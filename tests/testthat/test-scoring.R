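test_that("weight files load with log-OR conversion and validation", {
  df <- toy_score_df(3)
  df$effect_weight <- NULL
  df$OR <- c(1.5, 1.0, 0.8)
  score <- read_score_file(df)
  expect_s3_class(score, "score_file")
  expect_equal(score$weight, log(c(1.5, 1.0, 0.8)))
  expect_equal(score$weight[1], 0.405465, tolerance = 1e-6)
  expect_identical(score$weight[2], 0)

  expect_error(read_score_file(within(df, OR[2] <- -0.2)), "positive")
  expect_error(read_score_file(df[, setdiff(names(df), "effect_allele")]),
               "effect_allele")
  dup <- rbind(df, df[1, ])
  expect_error(read_score_file(dup), "duplicate")
  now <- df
  now$OR <- NULL
  expect_error(read_score_file(now), "effect_weight")
})

test_that("a large weight table keeps size and row order", {
  df <- toy_score_df(313)
  score <- read_score_file(df)
  expect_equal(nrow(score), 313)
  expect_identical(score$variant_id, df$rsID)
})

test_that("the installed toy weight file parses (PGS dialect, comments)", {
  f <- system.file("extdata", "toy_weights.tsv", package = "famprs")
  score <- read_score_file(f)
  expect_equal(nrow(score), 6)
  expect_equal(score$weight[1], 0.0512)
})

test_that("harmonize classifies every allele orientation", {
  score <- read_score_file(data.frame(
    rsID = paste0("rs", 1:6), chr_name = "1", chr_position = 1:6,
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "T", "G"),
    effect_weight = rep(0.1, 6)))
  # panel: direct, swapped, strand-flipped, flipped+swapped, ambiguous,
  # and rs6 missing entirely
  panel <- genotype_panel(
    matrix(1, 2, 5, dimnames = list(c("S1", "S2"), paste0("rs", 1:5))),
    data.frame(variant_id = paste0("rs", 1:5),
               counted_allele = c("A", "G", "T", "C", "A"),
               alternate_allele = c("G", "A", "C", "T", "T")))
  rep <- suppressWarnings(harmonize(score, panel))
  expect_identical(rep$status,
                   c("matched", "allele_swapped", "strand_flipped",
                     "strand_flipped", "ambiguous_dropped",
                     "absent_from_panel"))
  expect_identical(rep$swap, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(sum(rep$contributes), 4L)
  # statuses partition the score file
  expect_equal(sum(unlist(attr(rep, "counts"))), nrow(score))
  expect_warning(harmonize(score, panel), "ambiguous")
})

test_that("score variants missing from the panel are counted absent", {
  score <- read_score_file(toy_score_df(313))
  keep <- sample(313, 307)
  d <- matrix(1, 3, 307)
  colnames(d) <- score$variant_id[keep]
  panel <- toy_panel(d, score)
  rep <- harmonize(score, panel)
  expect_equal(attr(rep, "counts")$absent_from_panel, 6)
  expect_equal(sum(rep$contributes), 307)
})

test_that("raw scores match hand computations", {
  score <- read_score_file(toy_score_df(1, weights = log(1.5)))
  panel <- toy_panel(matrix(c(2, 0), 2, 1), score)
  prs <- compute_prs(score, panel)
  expect_equal(prs$raw_score, c(2 * log(1.5), 0), tolerance = 1e-9)
  expect_equal(prs$raw_score[1], 0.810930, tolerance = 1e-6)

  score2 <- read_score_file(toy_score_df(2, weights = c(0.1, -0.2)))
  panel2 <- toy_panel(matrix(c(1, 2), 1, 2), score2)
  expect_equal(compute_prs(score2, panel2)$raw_score, -0.3)
})

test_that("missing-dosage policies behave and agree when nothing is missing", {
  set.seed(42)
  sp <- random_score_panel(6, 8)
  skip <- compute_prs(sp$score, sp$panel, missing_policy = "skip")
  mean_d <- compute_prs(sp$score, sp$panel, missing_policy = "mean_dosage")
  expect_equal(skip$raw_score, mean_d$raw_score)
  expect_true(all(skip$n_variants_used == 8))

  spm <- random_score_panel(6, 8, miss_rate = 0.2)
  skip <- compute_prs(spm$score, spm$panel, missing_policy = "skip")
  expect_true(any(skip$n_variants_used < 8))
  # skip: missing variant simply absent from that sample's sum
  d <- spm$panel$dosage
  expect_equal(skip$raw_score,
               unname(rowSums(sweep(d, 2, spm$score$weight, `*`),
                              na.rm = TRUE)))
  # mean_dosage: imputed value is the per-variant mean over non-missing
  mean_d <- compute_prs(spm$score, spm$panel, missing_policy = "mean_dosage")
  d_imp <- apply(d, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  expect_equal(mean_d$raw_score,
               unname(rowSums(d_imp %*% diag(spm$score$weight))))
})

test_that("scores are linear in the weights and orientation-invariant", {
  set.seed(7)
  for (rep_i in 1:5) {
    sp <- random_score_panel(5, 6)
    base <- compute_prs(sp$score, sp$panel)$raw_score
    scaled <- sp$score
    scaled$weight <- scaled$weight * 3.5
    expect_equal(compute_prs(scaled, sp$panel)$raw_score, 3.5 * base)

    # complement one panel variant; harmonization should classify it as
    # swapped and leave the scores unchanged
    flipped <- sp$panel
    j <- sample(6, 1)
    flipped$variants[j, c("counted_allele", "alternate_allele")] <-
      flipped$variants[j, c("alternate_allele", "counted_allele")]
    flipped$dosage[, j] <- 2 - flipped$dosage[, j]
    rep2 <- harmonize(sp$score, flipped)
    expect_identical(rep2$status[j], "allele_swapped")
    expect_equal(compute_prs(sp$score, flipped, rep2)$raw_score, base)
  }
})

test_that("raw scores equal a brute-force double loop", {
  set.seed(11)
  for (rep_i in 1:5) {
    sp <- random_score_panel(sample(2:8, 1), sample(2:10, 1), miss_rate = 0.1)
    prs <- compute_prs(sp$score, sp$panel)
    brute <- numeric(length(sp$panel$sample_ids))
    for (i in seq_along(brute)) {
      acc <- 0
      for (j in seq_len(nrow(sp$score))) {
        d <- sp$panel$dosage[i, sp$score$variant_id[j]]
        if (!is.na(d)) acc <- acc + d * sp$score$weight[j]
      }
      brute[i] <- acc
    }
    expect_equal(prs$raw_score, brute)
  }
})

test_that("standardization gives reference mean 0 / sd 1 and catches degeneracy", {
  prs <- manual_prs(c("a", "b", "c"), c(1, 2, 3))
  expect_equal(prs$z_score, c(-1, 0, 1))

  set.seed(3)
  sp <- random_score_panel(10, 5)
  prs <- standardize_prs(compute_prs(sp$score, sp$panel))
  expect_equal(mean(prs$z_score), 0, tolerance = 1e-12)
  expect_equal(sd(prs$z_score), 1, tolerance = 1e-12)

  # controls-only reference: those samples have mean 0 / sd 1
  ref <- prs$sample_id[1:4]
  prs2 <- standardize_prs(prs, reference = ref)
  expect_equal(mean(prs2$z_score[1:4]), 0, tolerance = 1e-12)
  expect_equal(sd(prs2$z_score[1:4]), 1, tolerance = 1e-12)

  flat <- structure(
    data.frame(sample_id = c("a", "b"), raw_score = c(1, 1),
               n_variants_used = 1L, z_score = NA_real_),
    class = c("prs_table", "data.frame"))
  expect_error(standardize_prs(flat), "variance")
})

test_that("VCF genotypes load as ALT-dosage panels", {
  f <- system.file("extdata", "toy_genotypes.vcf", package = "famprs")
  panel <- read_vcf_panel(f)
  expect_identical(panel$sample_ids, c("S1", "S2", "S3"))
  expect_equal(unname(panel$dosage["S1", ]), c(1, 0, 2, 1))
  expect_true(is.na(panel$dosage["S3", "rs1002"]))
  expect_identical(panel$variants$counted_allele[1], "A")
})
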