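#' Default candidate gene symbols for the monogenic screen
#'
#' Established breast-cancer susceptibility gene symbols used as the
#' default candidate list by the simulator and the monogenic pipeline
#' stage when no list is supplied. Annotations the simulator attaches to
#' these symbols are synthetic.
#'
#' @format Character vector of 24 gene symbols.
#' @export
default_candidate_genes <- c(
  "BRCA1", "BRCA2", "PALB2", "CHEK2", "ATM", "TP53", "PTEN", "STK11",
  "CDH1", "NF1", "BARD1", "RAD51C", "RAD51D", "BRIP1", "NBN", "MSH2",
  "MLH1", "MSH6", "PMS2", "EPCAM", "CDKN2A", "XRCC2", "FANCC", "FANCM")

# allele pairs that are never strand-ambiguous
NONAMBIG_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                        c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the simulator with defaults chosen to emulate a
#' multi-generation family cohort: three-generation families, a
#' 313-variant score with centered-normal weights (sd 0.05, the magnitude
#' of typical GWAS per-allele log odds ratios), disease prevalence 1.22%
#' under a liability-threshold model, and 21 rare loss-of-function
#' variants with allele frequencies in \[0.00037, 0.026\].
#'
#' @param n_families Number of independent families.
#' @param template `"three_generation"` (founder couple, their children
#'   with spouses, grandchildren) or `"nuclear"` (founder couple and
#'   children).
#' @param sibship Integer vector of possible second-generation sibship
#'   sizes (sampled uniformly).
#' @param grandchildren Possible children-per-married-couple counts in the
#'   third generation.
#' @param spouse_prob Probability a second-generation child has a spouse
#'   (and hence offspring).
#' @param n_prs_variants Number of score variants.
#' @param freq_range Founder allele-frequency range for score variants
#'   (uniform draw).
#' @param weight_sd SD of the centered-normal per-allele weights.
#' @param beta_prs,beta_age Liability slopes per SD of PRS and age
#'   (`beta_prs^2 + beta_age^2 < 1`).
#' @param target_prevalence Disease prevalence K among women.
#' @param n_lof_variants Number of rare LOF variants to inject.
#' @param lof_freq_range Allele-frequency range for LOF variants
#'   (log-uniform draw).
#' @param lof_clinvar_frac Fraction of injected LOF variants also given a
#'   Pathogenic ClinVar-style label.
#' @param seed Integer seed; fixing it makes the whole cohort reproducible
#'   bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 200,
                       template = c("three_generation", "nuclear"),
                       sibship = 2:4,
                       grandchildren = 1:3,
                       spouse_prob = 0.8,
                       n_prs_variants = 313,
                       freq_range = c(0.01, 0.5),
                       weight_sd = 0.05,
                       beta_prs = 0.15,
                       beta_age = 0.25,
                       target_prevalence = 0.0122,
                       n_lof_variants = 21,
                       lof_freq_range = c(0.00037, 0.026),
                       lof_clinvar_frac = 1,
                       seed = 1L) {
  template <- match.arg(template)
  stopifnot(n_families >= 1, n_prs_variants >= 1,
            all(freq_range > 0), all(freq_range < 1),
            target_prevalence > 0, target_prevalence < 1,
            all(lof_freq_range > 0), all(lof_freq_range <= 0.05),
            beta_prs^2 + beta_age^2 < 1)
  structure(list(n_families = n_families, template = template,
                 sibship = sibship, grandchildren = grandchildren,
                 spouse_prob = spouse_prob,
                 n_prs_variants = n_prs_variants, freq_range = freq_range,
                 weight_sd = weight_sd, beta_prs = beta_prs,
                 beta_age = beta_age, target_prevalence = target_prevalence,
                 n_lof_variants = n_lof_variants,
                 lof_freq_range = lof_freq_range,
                 lof_clinvar_frac = lof_clinvar_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# age bands per generation: grandparents 70 +/- 8, parents 47 +/- 6,
# children 25 +/- 5 years
sim_age <- function(generation, n) {
  mu <- c(70, 47, 25)[generation]
  sdv <- c(8, 6, 5)[generation]
  pmax(16, stats::rnorm(n, mu, sdv))
}

#' Simulate pedigree structures
#'
#' Draws `n_families` independent families from the configured template.
#' The default three-generation template is: a founder couple; their
#' children (random sex), each with probability `spouse_prob` married to a
#' founder spouse of the opposite sex; grandchildren for each married
#' couple. Ages are drawn by generation band (70, 47, 25 years with noise)
#' so mother/sister/daughter relative classes are all populated.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A `pedigree` (affection unknown at this stage).
#' @export
simulate_pedigrees <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%04d", f)
    k <- 0L
    nid <- function() {
      k <<- k + 1L
      sprintf("%s_I%02d", fam, k)
    }
    add <- function(id, father, mother, sex, gen) {
      rows[[length(rows) + 1L]] <<- c(fam, id, father %||% "0",
                                      mother %||% "0",
                                      if (sex == "male") "1" else "2",
                                      "0", as.character(gen))
      id
    }
    gf <- add(nid(), NULL, NULL, "male", 1L)
    gm <- add(nid(), NULL, NULL, "female", 1L)
    n_kids <- if (length(config$sibship) == 1) config$sibship else
      sample(config$sibship, 1)
    for (c2 in seq_len(n_kids)) {
      sex2 <- sample(c("male", "female"), 1)
      kid <- add(nid(), gf, gm, sex2, 2L)
      if (config$template == "three_generation" &&
          stats::runif(1) < config$spouse_prob) {
        spouse_sex <- if (sex2 == "male") "female" else "male"
        spouse <- add(nid(), NULL, NULL, spouse_sex, 2L)
        father <- if (sex2 == "male") kid else spouse
        mother <- if (sex2 == "male") spouse else kid
        n_gc <- if (length(config$grandchildren) == 1) config$grandchildren
                else sample(config$grandchildren, 1)
        for (c3 in seq_len(n_gc)) {
          add(nid(), father, mother, sample(c("male", "female"), 1), 3L)
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  tab <- data.frame(family_id = m[, 1], individual_id = m[, 2],
                    father_id = m[, 3], mother_id = m[, 4],
                    sex = m[, 5], phenotype = m[, 6],
                    stringsAsFactors = FALSE)
  generation <- as.integer(m[, 7])
  ped <- parse_pedigree(tab)
  ped$age <- round(sim_age(generation, nrow(ped)), 1)
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders receive two alleles drawn i.i.d. Bernoulli(freq) —
#' Hardy-Weinberg proportions — and every non-founder inherits one allele
#' drawn uniformly from each parent's two. Dosage is the count of the
#' counted (effect) allele. Variants are unlinked.
#'
#' @param ped A `pedigree`; every individual must have either both parents
#'   known or none (an individual with exactly one known parent is an
#'   error).
#' @param freqs Per-variant counted-allele frequencies in (0, 1) —
#'   boundary values 0/1 are accepted for degenerate fixtures.
#' @param variants Optional variant table (`variant_id`, `counted_allele`,
#'   `alternate_allele`); generated (non-ambiguous pairs) when `NULL`.
#' @param seed Optional seed; `NULL` continues the RNG stream.
#' @return A [genotype_panel()].
#' @export
gene_drop <- function(ped, freqs, variants = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(freqs >= 0), all(freqs <= 1))
  v <- length(freqs)
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent)) {
    stop_famprs("gene_drop requires both parents known or none; offending: ",
                paste(ped$individual_id[one_parent][1], collapse = ", "))
  }
  n <- nrow(ped)
  ids <- ped$individual_id
  a1 <- matrix(NA_integer_, n, v, dimnames = list(ids, NULL))
  a2 <- a1
  founder <- is.na(ped$father_id)
  nf <- sum(founder)
  a1[founder, ] <- stats::rbinom(nf * v, 1, rep(freqs, each = nf))
  a2[founder, ] <- stats::rbinom(nf * v, 1, rep(freqs, each = nf))
  # drop alleles down generation levels
  remaining <- which(!founder)
  placed <- founder
  while (length(remaining) > 0) {
    fi <- match(ped$father_id[remaining], ids)
    mi <- match(ped$mother_id[remaining], ids)
    ready <- placed[fi] & placed[mi]
    if (!any(ready)) stop_famprs("pedigree ordering failure in gene_drop")
    idx <- remaining[ready]
    pf <- (a1[match(ped$father_id[idx], ids), , drop = FALSE] +
             a2[match(ped$father_id[idx], ids), , drop = FALSE]) / 2
    pm <- (a1[match(ped$mother_id[idx], ids), , drop = FALSE] +
             a2[match(ped$mother_id[idx], ids), , drop = FALSE]) / 2
    a1[idx, ] <- stats::rbinom(length(pf), 1, as.vector(pf))
    a2[idx, ] <- stats::rbinom(length(pm), 1, as.vector(pm))
    placed[idx] <- TRUE
    remaining <- remaining[!ready]
  }
  if (is.null(variants)) {
    pairs <- NONAMBIG_PAIRS[sample.int(nrow(NONAMBIG_PAIRS), v, replace = TRUE), ,
                            drop = FALSE]
    variants <- data.frame(variant_id = sprintf("v%04d", seq_len(v)),
                           counted_allele = pairs[, 1],
                           alternate_allele = pairs[, 2],
                           stringsAsFactors = FALSE)
  }
  genotype_panel(a1 + a2, variants, sample_ids = ids)
}

#' Liability threshold for a target prevalence
#'
#' Under a standard-normal liability, disease occurs above
#' `qnorm(1 - K)`, so the affected fraction is exactly `K`.
#'
#' @param prevalence Target prevalence K in (0, 1).
#' @return The threshold on the liability scale.
#' @export
liability_threshold <- function(prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  stats::qnorm(1 - prevalence)
}

#' Draw liabilities from the liability-threshold model
#'
#' `L = beta_prs * z_prs + beta_age * z_age + sqrt(1 - beta_prs^2 -
#' beta_age^2) * epsilon` with standard-normal noise, so `Var(L) = 1`
#' when the z inputs are standardized and the prevalence maps to a fixed
#' threshold.
#'
#' @param n Number of liabilities (ignored when `z_prs` is given).
#' @param z_prs,z_age Standardized covariates (default 0 = no effect).
#' @param beta_prs,beta_age Liability slopes (`beta_prs^2 + beta_age^2 < 1`).
#' @return Numeric liability vector.
#' @export
draw_liability <- function(n = NULL, z_prs = 0, z_age = 0,
                           beta_prs = 0, beta_age = 0) {
  stopifnot(beta_prs^2 + beta_age^2 < 1)
  n <- n %||% max(length(z_prs), length(z_age))
  beta_prs * z_prs + beta_age * z_age +
    sqrt(1 - beta_prs^2 - beta_age^2) * stats::rnorm(n)
}

#' Affection status from liabilities
#'
#' @param liability Liability vector from [draw_liability()].
#' @param prevalence Target prevalence K.
#' @return Logical vector, `TRUE` = affected.
#' @export
liability_affected <- function(liability, prevalence) {
  liability > liability_threshold(prevalence)
}

#' Convert a target per-SD odds ratio into a liability slope
#'
#' Numerically searches for the `beta_prs` whose liability-threshold
#' cohort, analyzed by a univariable logistic fit of status on the
#' standardized score, yields the requested per-SD odds ratio. The same
#' simulated noise is reused across candidate slopes, making the profile
#' smooth and the search deterministic given the seed.
#'
#' @param or_target Per-SD odds ratio to match.
#' @param prevalence Disease prevalence K.
#' @param n Simulation size per evaluation.
#' @param seed Seed for the calibration draw.
#' @return The calibrated `beta_prs`.
#' @export
liability_slope_for_or <- function(or_target, prevalence = 0.0122,
                                   n = 200000, seed = 1) {
  stopifnot(or_target > 1)
  set.seed(seed)
  z <- stats::rnorm(n)
  e <- stats::rnorm(n)
  thr <- liability_threshold(prevalence)
  objective <- function(b) {
    y <- as.integer(b * z + sqrt(1 - b^2) * e > thr)
    fit <- stats::glm.fit(cbind(1, z), y, family = stats::binomial())
    fit$coefficients[2] - log(or_target)
  }
  stats::uniroot(objective, c(0.005, 0.8), tol = 1e-4)$root
}

#' Assign liability-threshold phenotypes to a simulated cohort
#'
#' Computes the PRS over the panel, standardizes it together with age, and
#' draws affection for women from the liability-threshold model at the
#' configured prevalence (men are never affected — the phenotype is
#' breast cancer). Returns the phenotype roster consumed by the cohort
#' and pairing stages, with the true liabilities attached.
#'
#' @param ped Simulated `pedigree`.
#' @param panel Gene-dropped [genotype_panel()].
#' @param score The simulated `score_file`.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the RNG stream.
#' @return A roster `data.frame` (`sample_id`, `family_id`, `sex`, `age`,
#'   `affection`, `age_at_onset`, `bc_status`, `personal_history`,
#'   `family_history`, `genotyped`, `phenotype_complete`), with
#'   `attr(, "truth")` holding per-sample `liability` and `z_prs`.
#' @export
assign_phenotypes <- function(ped, panel, score, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prs <- standardize_prs(compute_prs(score, panel))
  z_prs <- prs$z_score[match(ped$individual_id, prs$sample_id)]
  z_age <- as.vector(scale(ped$age))
  liab <- draw_liability(z_prs = z_prs, z_age = z_age,
                         beta_prs = config$beta_prs,
                         beta_age = config$beta_age)
  affected <- liability_affected(liab, config$target_prevalence) &
    ped$sex == "female"
  fam_aff <- tapply(affected, ped$family_id, sum)
  family_history <- unname(fam_aff[ped$family_id] - affected) > 0

  roster <- data.frame(
    sample_id = ped$individual_id,
    family_id = ped$family_id,
    sex = ped$sex,
    age = ped$age,
    affection = ifelse(affected, "affected", "unaffected"),
    age_at_onset = ifelse(affected, ped$age, NA_real_),
    bc_status = ifelse(ped$sex != "female", "ineligible",
                       ifelse(affected, "case", "control_eligible")),
    personal_history = affected,
    family_history = family_history,
    genotyped = TRUE,
    phenotype_complete = TRUE,
    stringsAsFactors = FALSE)
  structure(roster,
            truth = data.frame(sample_id = ped$individual_id,
                               liability = liab, z_prs = z_prs,
                               stringsAsFactors = FALSE))
}

#' Inject rare loss-of-function variants into a panel
#'
#' Gene-drops `n_lof_variants` additional rare variants (allele
#' frequencies drawn log-uniformly inside `lof_freq_range`) down the same
#' pedigree and emits a synthetic annotation table: gene symbols from the
#' candidate list, consequences from the LOF classes, and ClinVar-style
#' pathogenic labels for a configurable fraction.
#'
#' @param panel Existing [genotype_panel()] for the pedigree.
#' @param ped The `pedigree` the panel was dropped on.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with the extended `panel` and the `annotations`
#'   `data.frame` (`variant_id`, `gene`, `consequence`,
#'   `clinvar_significance`, `af`).
#' @export
inject_lof <- function(panel, ped, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_lof_variants
  if (k == 0) {
    return(list(panel = panel, annotations = data.frame()))
  }
  rng <- log(config$lof_freq_range)
  freqs <- exp(stats::runif(k, rng[1], rng[2]))
  variants <- data.frame(
    variant_id = sprintf("lof_v%02d", seq_len(k)),
    counted_allele = NONAMBIG_PAIRS[sample.int(nrow(NONAMBIG_PAIRS), k,
                                               replace = TRUE), 1],
    alternate_allele = NA_character_, stringsAsFactors = FALSE)
  variants$alternate_allele <- vapply(variants$counted_allele, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), c(a, rev_comp(a))), 1)
  }, character(1))
  lof_panel <- gene_drop(ped, freqs, variants = variants)
  annotations <- data.frame(
    variant_id = variants$variant_id,
    gene = sample(default_candidate_genes, k, replace = TRUE),
    consequence = sample(LOF_CLASSES, k, replace = TRUE),
    clinvar_significance = ifelse(
      stats::runif(k) < config$lof_clinvar_frac,
      "Pathogenic", "Uncertain_significance"),
    af = freqs, stringsAsFactors = FALSE)
  merged <- genotype_panel(cbind(panel$dosage, lof_panel$dosage),
                           rbind(panel$variants, lof_panel$variants),
                           sample_ids = panel$sample_ids)
  list(panel = merged, annotations = annotations)
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: pedigrees, a synthetic weight file, gene-dropped
#' genotypes, liability-threshold phenotypes, and injected rare LOF
#' variants with annotations. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `pedigree` (with affection and onset ages
#'   merged in), `panel`, `score`, `roster`, `annotations`, `truth`,
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 20, n_prs_variants = 25))
#' cohort$pedigree
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- simulate_pedigrees(config)
  v <- config$n_prs_variants
  pairs <- NONAMBIG_PAIRS[sample.int(nrow(NONAMBIG_PAIRS), v, replace = TRUE), ,
                          drop = FALSE]
  score <- read_score_file(data.frame(
    rsID = sprintf("rs_sim%04d", seq_len(v)),
    chr_name = as.character(sample(1:22, v, replace = TRUE)),
    chr_position = sample.int(5e7, v),
    effect_allele = pairs[, 1],
    other_allele = pairs[, 2],
    effect_weight = stats::rnorm(v, 0, config$weight_sd),
    stringsAsFactors = FALSE), name = "sim_score")
  freqs <- stats::runif(v, config$freq_range[1], config$freq_range[2])
  panel <- gene_drop(ped, freqs,
                     variants = data.frame(
                       variant_id = score$variant_id,
                       counted_allele = score$effect_allele,
                       alternate_allele = score$other_allele,
                       stringsAsFactors = FALSE))
  roster <- assign_phenotypes(ped, panel, score, config)
  lof <- inject_lof(panel, ped, config)
  ped$affection <- roster$affection
  ped$age_at_onset <- roster$age_at_onset
  structure(list(pedigree = ped, panel = lof$panel, score = score,
                 roster = roster, annotations = lof$annotations,
                 truth = attr(roster, "truth"), config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(paste0("<sim_cohort> %d families, %d individuals, ",
                     "%d score + %d LOF variants, %d affected women\n"),
              length(unique(x$pedigree$family_id)), nrow(x$pedigree),
              nrow(x$score), x$config$n_lof_variants,
              sum(x$roster$bc_status == "case")))
  invisible(x)
}

#' Sample a case-control cohort from a logistic disease model
#'
#' Draws standardized scores `z ~ N(0, 1)` and case status from
#' `logit P(case | z) = qlogis(K) + log(or_per_sd) * z`, then retains the
#' first `n_cases` cases and `n_controls` controls (case-control sampling
#' preserves the logistic slope). Used for estimator-recovery experiments
#' at a known per-SD odds ratio.
#'
#' @param n_cases,n_controls Cohort composition.
#' @param or_per_sd True per-SD odds ratio.
#' @param prevalence Baseline prevalence fixing the intercept.
#' @param seed Optional seed.
#' @return `data.frame` with `z` and `status` (1 = case).
#' @export
simulate_case_control <- function(n_cases, n_controls, or_per_sd,
                                  prevalence = 0.0122, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- stats::qlogis(prevalence)
  b <- log(or_per_sd)
  z_case <- numeric(0)
  z_ctrl <- numeric(0)
  while (length(z_case) < n_cases || length(z_ctrl) < n_controls) {
    chunk <- max(10000, ceiling(n_cases / prevalence / 4))
    z <- stats::rnorm(chunk)
    y <- stats::rbinom(chunk, 1, stats::plogis(a + b * z))
    z_case <- c(z_case, z[y == 1])
    z_ctrl <- c(z_ctrl, z[y == 0])
  }
  data.frame(z = c(z_case[seq_len(n_cases)], z_ctrl[seq_len(n_controls)]),
             status = rep(c(1L, 0L), c(n_cases, n_controls)))
}

#' Write a simulated cohort in the dialects the pipeline reads
#'
#' Emits the weight TSV (PGS-Catalog dialect), dosage TSV with its variant
#' sidecar, `.fam` pedigree, roster TSV and annotation TSV into a
#' directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    weights = file.path(dir, "weights.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    variants = file.path(dir, "dosages.tsv.variants"),
    fam = file.path(dir, "pedigree.fam"),
    roster = file.path(dir, "roster.tsv"),
    annotations = file.path(dir, "annotations.tsv"))
  sc <- as.data.frame(cohort$score)
  write_tsv_file(data.frame(rsID = sc$variant_id, chr_name = sc$chromosome,
                            chr_position = sc$position,
                            effect_allele = sc$effect_allele,
                            other_allele = sc$other_allele,
                            effect_weight = sc$weight), paths$weights)
  dos <- as.data.frame(cohort$panel$dosage, check.names = FALSE)
  dos <- cbind(sample_id = cohort$panel$sample_ids, dos)
  write_tsv_file(dos, paths$dosages)
  write_tsv_file(cohort$panel$variants, paths$variants)
  ped <- cohort$pedigree
  fam <- data.frame(ped$family_id, ped$individual_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    ifelse(ped$sex == "male", 1L, 2L),
                    ifelse(ped$affection == "affected", 2L,
                           ifelse(ped$affection == "unaffected", 1L, 0L)))
  utils::write.table(fam, paths$fam, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_file(cohort$roster, paths$roster)
  write_tsv_file(cohort$annotations, paths$annotations)
  invisible(paths)
}
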