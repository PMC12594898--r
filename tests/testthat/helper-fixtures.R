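# Fixture builders shared across test files; everything is constructed in
# code so the suite carries no binary data.

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_score_df <- function(n = 3, weights = NULL) {
  pairs <- rbind(c("A", "G"), c("T", "C"), c("G", "A"), c("C", "T"))
  i <- rep_len(seq_len(nrow(pairs)), n)
  data.frame(rsID = sprintf("rs%03d", seq_len(n)),
             chr_name = "1", chr_position = seq_len(n) * 1000L,
             effect_allele = pairs[i, 1], other_allele = pairs[i, 2],
             effect_weight = weights %||% seq(0.05, by = 0.01, length.out = n),
             stringsAsFactors = FALSE)
}

toy_panel <- function(dosage, score = NULL, counted = NULL, alternate = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%02d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage)) && !is.null(score)) {
    colnames(dosage) <- score$variant_id[seq_len(ncol(dosage))]
  }
  variants <- data.frame(
    variant_id = colnames(dosage),
    counted_allele = counted %||% score$effect_allele[
      match(colnames(dosage), score$variant_id)],
    alternate_allele = alternate %||% score$other_allele[
      match(colnames(dosage), score$variant_id)],
    stringsAsFactors = FALSE)
  genotype_panel(dosage, variants)
}

# random small panel matched to a random score file, for brute-force
# property checks
random_score_panel <- function(n_samples, n_variants, miss_rate = 0) {
  score <- read_score_file(toy_score_df(
    n_variants, weights = round(stats::rnorm(n_variants, 0, 0.2), 4)))
  d <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE),
              n_samples, n_variants)
  if (miss_rate > 0) {
    d[stats::runif(length(d)) < miss_rate] <- NA
  }
  colnames(d) <- score$variant_id
  list(score = score, panel = toy_panel(d, score))
}

# three-generation family: grandparents gm/gf, their daughters mom and
# aunt, founder dad, and two granddaughters (one affected)
three_gen_fam <- function() {
  data.frame(
    family_id = "FAM1",
    individual_id = c("gf", "gm", "mom", "aunt", "dad", "case", "sis"),
    father_id = c("0", "0", "gf", "gf", "0", "dad", "dad"),
    mother_id = c("0", "0", "gm", "gm", "0", "mom", "mom"),
    sex = c("1", "2", "2", "2", "1", "2", "2"),
    phenotype = c("1", "1", "1", "1", "1", "2", "1"),
    stringsAsFactors = FALSE)
}

three_gen_ped <- function() {
  ped <- parse_pedigree(three_gen_fam())
  ped$age <- c(78, 75, 52, 49, 55, 28, 31)
  ped$age_at_onset[ped$individual_id == "case"] <- 27
  ped
}

# pedigree with first cousins: two sibs (u, mo) married to founder
# spouses, one child each
cousin_ped <- function() {
  parse_pedigree(data.frame(
    family_id = "FAM2",
    individual_id = c("gf", "gm", "u", "mo", "su", "smo", "c1", "c2"),
    father_id = c("0", "0", "gf", "gf", "0", "0", "u", "smo"),
    mother_id = c("0", "0", "gm", "gm", "0", "0", "su", "mo"),
    sex = c("1", "2", "1", "2", "2", "1", "2", "2"),
    phenotype = "1", stringsAsFactors = FALSE))
}

# z-scored PRS table from explicit raw values
manual_prs <- function(ids, raw) {
  prs <- structure(
    data.frame(sample_id = ids, raw_score = raw,
               n_variants_used = 1L, z_score = NA_real_,
               stringsAsFactors = FALSE),
    class = c("prs_table", "data.frame"))
  standardize_prs(prs)
}

# independent midrank implementation for oracle checks (counting route,
# deliberately different from rank())
count_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    1 + sum(x < x[i]) + 0.5 * (sum(x == x[i]) - 1)
  }, numeric(1))
}
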