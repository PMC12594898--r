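# Loss-of-function consequence classes used for candidate-gene screening.
LOF_CLASSES <- c("stop_gained", "frameshift", "splice_donor",
                 "splice_acceptor", "start_lost")

clinvar_is_pathogenic <- function(x) {
  tolower(as.character(x)) %in%
    c("pathogenic", "likely_pathogenic", "pathogenic/likely_pathogenic")
}

#' Build the flagged pathogenic variant set
#'
#' Merges two evidence sources over a candidate gene list: (a) predicted
#' loss-of-function consequences in a candidate gene, and (b) a
#' pathogenic/likely-pathogenic ClinVar-style classification. In
#' `"shared"` mode (default) a variant is flagged only when both sources
#' agree; in `"union"` mode either source suffices. Provenance flags are
#' retained per variant.
#'
#' @param candidate_genes Character vector of gene symbols (or a path to a
#'   one-symbol-per-line text file).
#' @param annotations `data.frame` (or TSV path) with columns `variant_id`,
#'   `gene`, `consequence`, `clinvar_significance`, `af`.
#' @param merge_mode `"shared"` or `"union"`.
#' @return `data.frame` of flagged variants with logical columns
#'   `candidate_lof` and `clinvar_pathogenic` (the provenance of each flag).
#' @export
build_pathogenic_set <- function(candidate_genes, annotations,
                                 merge_mode = c("shared", "union")) {
  merge_mode <- match.arg(merge_mode)
  if (is.character(candidate_genes) && length(candidate_genes) == 1 &&
      file.exists(candidate_genes)) {
    candidate_genes <- readLines(candidate_genes)
    candidate_genes <- trimws(candidate_genes[nzchar(trimws(candidate_genes))])
  }
  if (length(candidate_genes) == 0) stop_famprs("candidate gene list is empty")
  if (is.character(annotations)) annotations <- read_tsv_file(annotations)
  if (nrow(annotations) == 0) stop_famprs("annotation table is empty")

  ann <- annotations
  ann$candidate_lof <- ann$gene %in% candidate_genes &
    ann$consequence %in% LOF_CLASSES
  ann$clinvar_pathogenic <- clinvar_is_pathogenic(ann$clinvar_significance)
  flagged <- if (merge_mode == "shared") {
    ann$candidate_lof & ann$clinvar_pathogenic
  } else {
    ann$candidate_lof | ann$clinvar_pathogenic
  }
  out <- ann[flagged, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, merge_mode = merge_mode)
}

#' Flag heterozygous and homozygous carriers of pathogenic variants
#'
#' For every flagged variant present in the panel, carriers are labeled by
#' dosage of the pathogenic (counted) allele — 1 = heterozygous,
#' 2 = homozygous — and the allele frequency is recomputed from the panel
#' as `(het + 2 * hom) / (2 * n_called)`. Variants absent from the panel
#' appear in the table with `status = "absent"` rather than failing.
#'
#' @param panel A [genotype_panel()] whose counted allele is the
#'   pathogenic allele.
#' @param flagged [build_pathogenic_set()] output (needs `variant_id`,
#'   `gene`).
#' @param selection Optional [select_case_control()] result for
#'   case/control carrier counts.
#' @return A `carrier_table`: per variant `gene`, `status`, `n_het`,
#'   `n_hom`, `allele_frequency`, `n_case_carriers`, `n_control_carriers`;
#'   carrier ids in `attr(, "carriers")` (list of `het`/`hom` id vectors).
#' @export
flag_carriers <- function(panel, flagged, selection = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  rows <- list()
  carriers <- list()
  for (i in seq_len(nrow(flagged))) {
    vid <- flagged$variant_id[i]
    j <- match(vid, panel$variants$variant_id)
    if (is.na(j)) {
      message("flagged variant ", vid, " absent from panel")
      rows[[i]] <- data.frame(variant_id = vid, gene = flagged$gene[i],
                              status = "absent", n_het = NA_integer_,
                              n_hom = NA_integer_,
                              allele_frequency = NA_real_,
                              n_case_carriers = NA_integer_,
                              n_control_carriers = NA_integer_,
                              stringsAsFactors = FALSE)
      next
    }
    d <- panel$dosage[, j]
    het <- panel$sample_ids[!is.na(d) & d == 1]
    hom <- panel$sample_ids[!is.na(d) & d == 2]
    n_called <- sum(!is.na(d))
    af <- if (n_called > 0) (length(het) + 2 * length(hom)) / (2 * n_called)
          else NA_real_
    carrier_ids <- c(het, hom)
    rows[[i]] <- data.frame(
      variant_id = vid, gene = flagged$gene[i], status = "present",
      n_het = length(het), n_hom = length(hom), allele_frequency = af,
      n_case_carriers = if (is.null(selection)) NA_integer_ else
        sum(carrier_ids %in% selection$case_ids),
      n_control_carriers = if (is.null(selection)) NA_integer_ else
        sum(carrier_ids %in% selection$control_ids),
      stringsAsFactors = FALSE)
    carriers[[vid]] <- list(het = het, hom = hom)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("carrier_table", "data.frame"),
            carriers = carriers)
}

#' @export
print.carrier_table <- function(x, ...) {
  cat(sprintf("<carrier_table> %d flagged variants (%d present in panel)\n",
              nrow(x), sum(x$status == "present")))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
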