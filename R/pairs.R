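#' Enumerate case-relative pairs for a relationship group
#'
#' For every affected female (a case), one pair is formed with each
#' eligible unaffected female relative in the requested group, so a case
#' appears as many times as she has eligible relatives — the deliberate
#' repetition of the within-family paired design. Individuals with unknown
#' affection are excluded from both sides; relatives by marriage (zero
#' kinship) never pair.
#'
#' Groups:
#' * `"sisters"` — full sisters only;
#' * `"mothers"` — the case's mother;
#' * `"daughters"` — the case's daughters;
#' * `"first_second"` — all relatives of degree 1 or 2;
#' * `"total_relatives"` — every female blood relative (nonzero kinship).
#'
#' @param ped A [parse_pedigree()] result carrying affection and ages.
#' @param group One of the group names above.
#' @param prs Optional [standardize_prs()] table; when given, each pair
#'   carries `case_prs`/`relative_prs` z-scores and pairs lacking a score
#'   on either side are dropped (count in `attr(, "n_dropped_no_prs")`).
#' @param dedup_relatives When `TRUE`, a relative paired with several cases
#'   keeps only her first pair (sensitivity analysis for
#'   over-representation); default `FALSE`.
#' @return A `pair_set`: `data.frame` with columns `group`, `family_id`,
#'   `case_id`, `relative_id`, `relationship`, `degree`, `case_age`
#'   (age at onset when known, else age), `relative_age`, and PRS columns
#'   when `prs` is supplied.
#' @export
enumerate_pairs <- function(ped, group = c("sisters", "mothers", "daughters",
                                           "first_second", "total_relatives"),
                            prs = NULL, dedup_relatives = FALSE) {
  group <- match.arg(group)
  rows <- list()
  for (fam_id in unique(ped$family_id)) {
    fam <- ped[ped$family_id == fam_id, , drop = FALSE]
    cases <- fam$individual_id[fam$sex == "female" & fam$affection == "affected"]
    candidates <- fam$individual_id[fam$sex == "female" &
                                      fam$affection == "unaffected"]
    if (length(cases) == 0 || length(candidates) == 0) next
    phi <- kinship_matrix(ped, fam_id)
    for (case in cases) {
      for (rel in candidates) {
        if (phi[case, rel] == 0) next
        cls <- classify_degree(ped, case, rel)
        keep <- switch(group,
          sisters = cls$label == "full-sister",
          mothers = cls$label == "mother",
          daughters = cls$label == "daughter",
          first_second = cls$degree %in% c("1", "2"),
          total_relatives = cls$degree %in% c("1", "2", "3+"))
        if (!keep) next
        crow <- fam[fam$individual_id == case, ]
        rrow <- fam[fam$individual_id == rel, ]
        rows[[length(rows) + 1]] <- data.frame(
          group = group, family_id = fam_id,
          case_id = case, relative_id = rel,
          relationship = cls$label, degree = cls$degree,
          case_age = if (!is.na(crow$age_at_onset)) crow$age_at_onset else crow$age,
          relative_age = rrow$age,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group = character(0), family_id = character(0),
               case_id = character(0), relative_id = character(0),
               relationship = character(0), degree = character(0),
               case_age = numeric(0), relative_age = numeric(0),
               stringsAsFactors = FALSE)
  if (dedup_relatives && nrow(pairs) > 0) {
    pairs <- pairs[!duplicated(pairs$relative_id), , drop = FALSE]
  }
  n_dropped <- 0L
  if (!is.null(prs) && nrow(pairs) > 0) {
    pairs$case_prs <- prs$z_score[match(pairs$case_id, prs$sample_id)]
    pairs$relative_prs <- prs$z_score[match(pairs$relative_id, prs$sample_id)]
    scored <- !is.na(pairs$case_prs) & !is.na(pairs$relative_prs)
    n_dropped <- sum(!scored)
    if (n_dropped > 0) {
      message(n_dropped, " pair(s) dropped for missing PRS in group ", group)
      pairs <- pairs[scored, , drop = FALSE]
    }
  } else if (!is.null(prs)) {
    pairs$case_prs <- numeric(0)
    pairs$relative_prs <- numeric(0)
  }
  rownames(pairs) <- NULL
  structure(pairs, class = c("pair_set", "data.frame"),
            group = group, n_dropped_no_prs = n_dropped)
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> group %s: %d case-relative pairs (%d unique cases)\n",
              attr(x, "group"), nrow(x), length(unique(x$case_id))))
  invisible(x)
}
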