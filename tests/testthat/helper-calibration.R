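# Null-calibration machinery: independent sister pairs gene-dropped down
# flat nuclear families, case label assigned at random (PRS-independent,
# i.e. the simulator's null of zero PRS effect on liability). Pairs that
# repeat a case are dependent and have no nominal signed-rank level, so
# the calibration design uses one pair per family.

null_pair_differences <- function(n_pairs, n_variants = 25) {
  fam <- rep(sprintf("F%06d", seq_len(n_pairs)), each = 4)
  idx <- rep(1:4, n_pairs)
  id <- paste0(fam, "_", idx)
  ped <- parse_pedigree(data.frame(
    family_id = fam, individual_id = id,
    father_id = ifelse(idx >= 3, paste0(fam, "_1"), "0"),
    mother_id = ifelse(idx >= 3, paste0(fam, "_2"), "0"),
    sex = ifelse(idx == 1, "1", "2"), phenotype = "0",
    stringsAsFactors = FALSE))
  score <- read_score_file(toy_score_df(
    n_variants, weights = round(stats::rnorm(n_variants, 0, 0.05), 5)))
  panel <- gene_drop(ped, stats::runif(n_variants, 0.1, 0.5),
                     variants = data.frame(
                       variant_id = score$variant_id,
                       counted_allele = score$effect_allele,
                       alternate_allele = score$other_allele,
                       stringsAsFactors = FALSE))
  prs <- standardize_prs(compute_prs(score, panel))
  z <- matrix(prs$z_score, nrow = 4)  # samples ordered family-major
  sib1 <- z[3, ]
  sib2 <- z[4, ]
  case_first <- stats::runif(n_pairs) < 0.5
  ifelse(case_first, sib1 - sib2, sib2 - sib1)
}

# rejection rate of the signed-rank test at `alpha` over `n_groups`
# independent replicate groups under the null
null_rejection_rate <- function(n_groups, pairs_per_group, alpha = 0.05) {
  d <- null_pair_differences(n_groups * pairs_per_group)
  groups <- matrix(d, nrow = pairs_per_group)
  rejected <- vapply(seq_len(n_groups), function(g) {
    signed_rank_test(groups[, g], alpha = alpha)$p_two_sided <= alpha
  }, logical(1))
  mean(rejected)
}
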