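test_that("a trio parses with resolved links", {
  ped <- parse_pedigree(data.frame(
    family_id = "F1", individual_id = c("dad", "mom", "kid"),
    father_id = c("0", "0", "dad"), mother_id = c("0", "0", "mom"),
    sex = c("1", "2", "2"), phenotype = "0"))
  expect_equal(nrow(ped), 3)
  expect_equal(sum(!is.na(ped$father_id)) + sum(!is.na(ped$mother_id)), 2)
})

test_that("structural errors are rejected", {
  # self as mother
  expect_error(parse_pedigree(data.frame(
    family_id = "F1", individual_id = "x", father_id = "0",
    mother_id = "x", sex = "2", phenotype = "0")), "cycle")
  # mutual parent cycle
  expect_error(parse_pedigree(data.frame(
    family_id = "F1", individual_id = c("a", "b"),
    father_id = c("0", "0"), mother_id = c("b", "a"),
    sex = c("2", "2"), phenotype = "0")), "cycle")
  # father is female
  expect_error(parse_pedigree(data.frame(
    family_id = "F1", individual_id = c("p", "k"),
    father_id = c("0", "p"), mother_id = c("0", "0"),
    sex = c("2", "2"), phenotype = "0")), "father")
  # duplicate id in a family
  expect_error(parse_pedigree(data.frame(
    family_id = "F1", individual_id = c("a", "a"),
    father_id = "0", mother_id = "0", sex = "2", phenotype = "0")),
    "duplicate")
  # dangling parent reference becomes unknown, with a warning
  expect_warning(ped <- parse_pedigree(data.frame(
    family_id = "F1", individual_id = "k", father_id = "ghost",
    mother_id = "0", sex = "2", phenotype = "0")), "unknown")
  expect_true(is.na(ped$father_id))
})

test_that("the 7-member three-generation fixture resolves fully", {
  ped <- three_gen_ped()
  expect_equal(nrow(ped), 7)
  founders <- is.na(ped$father_id) & is.na(ped$mother_id)
  expect_equal(sum(founders), 3)
  expect_setequal(ped$individual_id[founders], c("gf", "gm", "dad"))
})

test_that("kinship matches hand recursion on canonical relationships", {
  ped <- three_gen_ped()
  expect_equal(kinship(ped, "gf", "gm"), 0)       # founders unrelated
  expect_equal(kinship(ped, "mom", "case"), 0.25) # parent-child
  expect_equal(kinship(ped, "gm", "case"), 0.125) # grandmother
  expect_equal(kinship(ped, "case", "sis"), 0.25) # full sisters
  expect_equal(kinship(ped, "aunt", "case"), 0.125)
  expect_equal(kinship(ped, "dad", "aunt"), 0)    # in-laws unrelated
  expect_equal(kinship(cousin_ped(), "c1", "c2"), 0.0625)
  # half sisters
  half <- parse_pedigree(data.frame(
    family_id = "F1", individual_id = c("f", "m1", "m2", "h1", "h2"),
    father_id = c("0", "0", "0", "f", "f"),
    mother_id = c("0", "0", "0", "m1", "m2"),
    sex = c("1", "2", "2", "2", "2"), phenotype = "0"))
  expect_equal(kinship(half, "h1", "h2"), 0.125)
  expect_error(kinship(ped, "case", "nobody"), "unknown individual")
})

test_that("kinship matrices are symmetric with 0.5 diagonal on outbred pedigrees", {
  set.seed(5)
  ped <- simulate_pedigrees(sim_config(n_families = 5, seed = 5))
  for (fam in unique(ped$family_id)) {
    phi <- kinship_matrix(ped, fam)
    expect_equal(phi, t(phi))
    expect_equal(unname(diag(phi)), rep(0.5, nrow(phi)))
  }
})

test_that("degree classification follows path type with transposed labels", {
  ped <- three_gen_ped()
  expect_identical(classify_degree(ped, "case", "sis"),
                   list(degree = "1", label = "full-sister"))
  expect_identical(classify_degree(ped, "case", "mom"),
                   list(degree = "1", label = "mother"))
  expect_identical(classify_degree(ped, "mom", "case"),
                   list(degree = "1", label = "daughter"))
  expect_identical(classify_degree(ped, "case", "gm"),
                   list(degree = "2", label = "grandmother"))
  expect_identical(classify_degree(ped, "gm", "case"),
                   list(degree = "2", label = "granddaughter"))
  expect_identical(classify_degree(ped, "case", "aunt"),
                   list(degree = "2", label = "aunt"))
  expect_identical(classify_degree(ped, "aunt", "case"),
                   list(degree = "2", label = "niece"))
  expect_identical(classify_degree(ped, "case", "dad"),
                   list(degree = "1", label = "father"))
  expect_identical(classify_degree(ped, "mom", "dad")$degree, "unrelated")
  cz <- cousin_ped()
  expect_identical(classify_degree(cz, "c1", "c2"),
                   list(degree = "3+", label = "other"))
  half <- parse_pedigree(data.frame(
    family_id = "F1", individual_id = c("f", "m1", "m2", "h1", "h2"),
    father_id = c("0", "0", "0", "f", "f"),
    mother_id = c("0", "0", "0", "m1", "m2"),
    sex = c("1", "2", "2", "2", "2"), phenotype = "0"))
  expect_identical(classify_degree(half, "h1", "h2"),
                   list(degree = "2", label = "half-sister"))
})

test_that("degree is symmetric up to label transposition on simulated pedigrees", {
  role <- c(mother = "parent", father = "parent",
            daughter = "child", son = "child",
            "full-sister" = "sib", "full-brother" = "sib",
            "half-sister" = "halfsib", "half-brother" = "halfsib",
            grandmother = "grandparent", grandfather = "grandparent",
            granddaughter = "grandchild", grandson = "grandchild",
            aunt = "avuncular", uncle = "avuncular",
            niece = "nibling", nephew = "nibling",
            other = "other", unrelated = "unrelated")
  partner <- c(parent = "child", child = "parent", sib = "sib",
               halfsib = "halfsib", grandparent = "grandchild",
               grandchild = "grandparent", avuncular = "nibling",
               nibling = "avuncular", other = "other",
               unrelated = "unrelated")
  ped <- simulate_pedigrees(sim_config(n_families = 3, seed = 9), seed = 9)
  for (fam in unique(ped$family_id)) {
    ids <- ped$individual_id[ped$family_id == fam]
    for (a in ids) for (b in setdiff(ids, a)) {
      ab <- classify_degree(ped, a, b)
      ba <- classify_degree(ped, b, a)
      expect_identical(ab$degree, ba$degree)
      expect_identical(unname(role[[ba$label]]),
                       unname(partner[[role[[ab$label]]]]))
    }
  }
})

test_that("pair enumeration repeats the case once per eligible relative", {
  ped <- three_gen_ped()
  prs <- manual_prs(ped$individual_id, seq_len(7))
  total <- enumerate_pairs(ped, "total_relatives", prs = prs)
  # case's unaffected female blood relatives: gm, mom, aunt, sis
  expect_equal(nrow(total), 4)
  expect_true(all(total$case_id == "case"))
  expect_setequal(total$relative_id, c("gm", "mom", "aunt", "sis"))

  expect_equal(enumerate_pairs(ped, "sisters", prs = prs)$relative_id, "sis")
  expect_equal(enumerate_pairs(ped, "mothers", prs = prs)$relative_id, "mom")
  expect_equal(nrow(enumerate_pairs(ped, "daughters", prs = prs)), 0)
  fs <- enumerate_pairs(ped, "first_second", prs = prs)
  expect_setequal(fs$relative_id, c("gm", "mom", "aunt", "sis"))
  expect_error(enumerate_pairs(ped, "cousins"), "arg")
})

test_that("affected or unknown-affection relatives and males never pair", {
  fam <- three_gen_fam()
  fam$phenotype[fam$individual_id == "sis"] <- "2"   # sister affected
  fam$phenotype[fam$individual_id == "aunt"] <- "0"  # affection unknown
  ped <- parse_pedigree(fam)
  ped$age <- 40
  pairs <- enumerate_pairs(ped, "total_relatives")
  expect_false("sis" %in% pairs$relative_id)
  expect_false("aunt" %in% pairs$relative_id)
  expect_false(any(c("gf", "dad") %in% pairs$relative_id))
  # sis is now a case herself, paired with her own relatives
  expect_setequal(unique(pairs$case_id), c("case", "sis"))
  # every pair: affected female case, unaffected female relative, same family
  aff <- setNames(ped$affection, ped$individual_id)
  sex <- setNames(ped$sex, ped$individual_id)
  expect_true(all(aff[pairs$case_id] == "affected"))
  expect_true(all(aff[pairs$relative_id] == "unaffected"))
  expect_true(all(sex[pairs$relative_id] == "female"))
})

test_that("pairs lacking a PRS are dropped and counted", {
  ped <- three_gen_ped()
  prs <- manual_prs(c("case", "sis", "mom"), c(1, 2, 3))  # others unscored
  expect_message(
    total <- enumerate_pairs(ped, "total_relatives", prs = prs),
    "dropped")
  expect_setequal(total$relative_id, c("sis", "mom"))
  expect_equal(attr(total, "n_dropped_no_prs"), 2)
})

test_that("first/second pairs are nested in total relatives on simulated cohorts", {
  co <- simulate_cohort(sim_config(n_families = 60, n_prs_variants = 20,
                                   beta_prs = 0.3, target_prevalence = 0.15,
                                   seed = 21))
  prs <- standardize_prs(compute_prs(co$score, co$panel))
  fs <- enumerate_pairs(co$pedigree, "first_second", prs = prs)
  tot <- enumerate_pairs(co$pedigree, "total_relatives", prs = prs)
  expect_lte(nrow(fs), nrow(tot))
  key <- function(p) paste(p$case_id, p$relative_id)
  expect_true(all(key(fs) %in% key(tot)))
  expect_true(all(fs$degree %in% c("1", "2")))
})
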