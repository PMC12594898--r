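#' Compute raw polygenic risk scores
#'
#' The raw score of sample *i* is the weighted sum of effect-allele dosages,
#' `sum_j d_ij * w_j`, over the score variants that harmonized against the
#' panel, with dosages orientation-corrected (`2 - d` for swapped variants).
#'
#' @param score A [read_score_file()] result.
#' @param panel A [genotype_panel()].
#' @param report A [harmonize()] report for this score/panel pair; computed
#'   on the fly when `NULL`.
#' @param missing_policy How to handle missing dosages: `"skip"` omits the
#'   variant from that sample's sum (and `n_variants_used` reflects it);
#'   `"mean_dosage"` substitutes the variant's mean oriented dosage over
#'   non-missing samples.
#' @return A `prs_table`: `data.frame` with `sample_id`, `raw_score`,
#'   `n_variants_used` and `z_score` (`NA` until [standardize_prs()]).
#' @examples
#' f <- system.file("extdata", "toy_weights.tsv", package = "famprs")
#' score <- read_score_file(f)
#' g <- system.file("extdata", "toy_dosages.tsv", package = "famprs")
#' panel <- read_dosage_tsv(g)
#' prs <- compute_prs(score, panel)
#' @export
compute_prs <- function(score, panel, report = NULL,
                        missing_policy = c("skip", "mean_dosage")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(report)) report <- harmonize(score, panel)
  use <- report$contributes
  if (!any(use)) stop_famprs("no score variant harmonized against the panel")

  pidx <- match(report$variant_id[use], panel$variants$variant_id)
  d <- panel$dosage[, pidx, drop = FALSE]
  swap <- report$swap[use]
  if (any(swap)) d[, swap] <- 2 - d[, swap, drop = FALSE]
  w <- score$weight[match(report$variant_id[use], score$variant_id)]

  if (missing_policy == "mean_dosage" && anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0  # variant missing in every sample contributes nothing
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- mu[na_idx[, 2]]
  }
  contrib <- !is.na(d)
  raw <- rowSums(sweep(d, 2, w, `*`), na.rm = TRUE)
  n_used <- rowSums(contrib)

  out <- data.frame(sample_id = panel$sample_ids,
                    raw_score = raw,
                    n_variants_used = as.integer(n_used),
                    z_score = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("prs_table", "data.frame"),
            missing_policy = missing_policy,
            score_name = attr(score, "score_name"))
}

#' Standardize PRS to z-scores
#'
#' `z = (raw - mean_ref) / sd_ref`, with the reference mean and standard
#' deviation (denominator `n - 1`) taken over a chosen reference sample set
#' and applied to every sample. The default reference is all scored
#' samples; a controls-only reference can be supplied instead.
#'
#' @param prs A [compute_prs()] table.
#' @param reference Character vector of `sample_id`s defining the reference
#'   set (default: all samples).
#' @return The `prs_table` with `z_score` filled in.
#' @export
standardize_prs <- function(prs, reference = NULL) {
  stopifnot(inherits(prs, "prs_table"))
  reference <- reference %||% prs$sample_id
  ref <- prs$raw_score[prs$sample_id %in% reference]
  if (length(ref) < 2) stop_famprs("standardization reference needs >= 2 samples")
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) {
    stop_famprs("zero raw-score variance in the standardization reference")
  }
  prs$z_score <- (prs$raw_score - mean(ref)) / s
  attr(prs, "reference_n") <- length(ref)
  prs
}

#' @export
print.prs_table <- function(x, ...) {
  cat(sprintf("<prs_table> %s: %d samples (missing_policy = %s)\n",
              attr(x, "score_name") %||% "PRS", nrow(x),
              attr(x, "missing_policy") %||% "?"))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
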