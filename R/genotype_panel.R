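#' Construct a genotype panel
#'
#' A genotype panel holds hard-call dosages of a counted allele (0, 1, 2 or
#' missing) for a set of samples at a set of variants, together with the
#' allele labels needed for harmonization against a weight file.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}. Row names are sample ids, column names
#'   variant ids (or supply `sample_ids`).
#' @param variants `data.frame` with columns `variant_id`, `counted_allele`
#'   (the allele the dosage counts) and `alternate_allele`, one row per
#'   panel column, in column order.
#' @param sample_ids Optional character vector overriding row names.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(dosage, variants, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  sample_ids <- sample_ids %||% rownames(dosage)
  if (is.null(sample_ids)) stop_famprs("sample ids missing (no rownames)")
  if (anyDuplicated(sample_ids)) stop_famprs("duplicate sample ids in panel")
  if (nrow(variants) != ncol(dosage)) {
    stop_famprs("variant table and dosage matrix disagree on variant count")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop_famprs("dosages must be 0, 1, 2 or missing")
  if (anyDuplicated(variants$variant_id)) {
    stop_famprs("duplicate variant ids in panel")
  }
  ca <- toupper(as.character(variants$counted_allele))
  aa <- toupper(as.character(variants$alternate_allele))
  if (any(ca == aa)) stop_famprs("counted allele equals alternate allele")
  variants <- data.frame(variant_id = as.character(variants$variant_id),
                         counted_allele = ca, alternate_allele = aa,
                         stringsAsFactors = FALSE)
  dimnames(dosage) <- list(sample_ids, variants$variant_id)
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants (%.1f%% missing)\n",
              length(x$sample_ids), nrow(x$variants),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read a dosage matrix from TSV
#'
#' Samples as rows (first column `sample_id`), variant ids as remaining
#' column names, `NA` for missing calls. Allele labels for each variant are
#' supplied separately (or default to the score file's during harmonization
#' via an explicit variant table).
#'
#' @param path TSV file of dosages.
#' @param variants Variant table as in [genotype_panel()]; if `NULL`, a
#'   sidecar file `<path>.variants` with columns `variant_id`,
#'   `counted_allele`, `alternate_allele` is read.
#' @return A `genotype_panel`.
#' @export
read_dosage_tsv <- function(path, variants = NULL) {
  tab <- read_tsv_file(path)
  if (names(tab)[1] != "sample_id") {
    stop_famprs("first column of a dosage TSV must be `sample_id`")
  }
  if (is.null(variants)) {
    sidecar <- paste0(path, ".variants")
    if (!file.exists(sidecar)) {
      stop_famprs("no variant allele table given and no sidecar file at ", sidecar)
    }
    variants <- read_tsv_file(sidecar)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample_id
  variants <- variants[match(colnames(m), variants$variant_id), , drop = FALSE]
  if (anyNA(variants$variant_id)) {
    stop_famprs("dosage columns missing from the variant allele table")
  }
  genotype_panel(m, variants)
}

#' Read a genotype panel from VCF
#'
#' Hard GT calls are converted to counts of the ALT allele (the counted
#' allele); `./.` becomes a missing dosage. Multi-allelic records are
#' dropped with a warning. Variant ids come from the ID column, falling
#' back to `chrom:pos:ref:alt`.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return A `genotype_panel` whose counted allele is ALT.
#' @export
read_vcf_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF records dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles from hard calls; any '.' in the call -> missing
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)
  variants <- data.frame(variant_id = ids,
                         counted_allele = fix$ALT,
                         alternate_allele = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_panel(t(dos), variants, sample_ids = colnames(gt))
}
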