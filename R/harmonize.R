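#' Harmonize a weight file against a genotype panel
#'
#' Classifies every score variant by how its allele labels reconcile with
#' the panel's counted/alternate alleles:
#'
#' * `matched` — panel counts the effect allele; dosage used as-is.
#' * `allele_swapped` — panel counts the other allele; dosage complemented
#'   (`2 - d`) at scoring time.
#' * `strand_flipped` — alleles agree only after reverse-complementing the
#'   panel's labels; orientation (as-is vs complemented) recorded alongside.
#' * `ambiguous_dropped` — A/T or C/G score variants, where strand cannot
#'   be resolved from the labels (dropped by default), plus variants whose
#'   alleles are irreconcilable (`note = "allele_mismatch"`).
#' * `absent_from_panel` — variant id not present in the panel.
#'
#' The statuses partition the score file; only the first three contribute
#' to scores.
#'
#' @param score A [read_score_file()] result.
#' @param panel A [genotype_panel()].
#' @param drop_ambiguous Drop A/T and C/G score variants (default `TRUE`).
#'   When `FALSE`, ambiguous variants are oriented by direct label match
#'   only (no strand flip is attempted for them).
#' @return A `harmonization_report`: a `data.frame` with columns
#'   `variant_id`, `status`, `swap` (complement dosage when scoring),
#'   `contributes`, `note`; counts per status in `attr(, "counts")`.
#' @export
harmonize <- function(score, panel, drop_ambiguous = TRUE) {
  stopifnot(inherits(score, "score_file"), inherits(panel, "genotype_panel"))
  if (nrow(score) == 0 || nrow(panel$variants) == 0) {
    stop_famprs("harmonize needs a non-empty score file and panel")
  }
  idx <- match(score$variant_id, panel$variants$variant_id)
  n <- nrow(score)
  status <- character(n)
  swap <- logical(n)
  note <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (is.na(idx[i])) {
      status[i] <- "absent_from_panel"
      next
    }
    ea <- score$effect_allele[i]
    oa <- score$other_allele[i]
    ca <- panel$variants$counted_allele[idx[i]]
    aa <- panel$variants$alternate_allele[idx[i]]
    ambiguous <- is_strand_ambiguous(ea, oa)
    if (ambiguous && drop_ambiguous) {
      status[i] <- "ambiguous_dropped"
      note[i] <- "palindromic_alleles"
      next
    }
    if (ca == ea && aa == oa) {
      status[i] <- "matched"
    } else if (ca == oa && aa == ea) {
      status[i] <- "allele_swapped"
      swap[i] <- TRUE
    } else if (!ambiguous && identical(rev_comp(ca), ea) && identical(rev_comp(aa), oa)) {
      status[i] <- "strand_flipped"
    } else if (!ambiguous && identical(rev_comp(ca), oa) && identical(rev_comp(aa), ea)) {
      status[i] <- "strand_flipped"
      swap[i] <- TRUE
    } else {
      status[i] <- "ambiguous_dropped"
      note[i] <- "allele_mismatch"
    }
  }

  n_amb <- sum(status == "ambiguous_dropped" & note %in% "palindromic_alleles")
  if (n_amb > 0) {
    warning(n_amb, " strand-ambiguous (A/T or C/G) score variant(s) dropped")
  }
  out <- data.frame(variant_id = score$variant_id, status = status,
                    swap = swap,
                    contributes = status %in% c("matched", "allele_swapped",
                                                "strand_flipped"),
                    note = note, stringsAsFactors = FALSE)
  counts <- table(factor(status, levels = c("matched", "allele_swapped",
                                            "strand_flipped",
                                            "ambiguous_dropped",
                                            "absent_from_panel")))
  structure(out, class = c("harmonization_report", "data.frame"),
            counts = as.list(counts))
}

#' @export
print.harmonization_report <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("<harmonization_report>", nrow(x), "score variants\n")
  for (s in names(counts)) cat(sprintf("  %-18s %d\n", s, counts[[s]]))
  invisible(x)
}

#' Write a harmonization report to disk
#'
#' @param report A [harmonize()] result.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @export
write_harmonization_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) write_tsv_file(as.data.frame(report), tsv)
  if (!is.null(json)) write_json_summary(attr(report, "counts"), json)
  invisible(report)
}
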