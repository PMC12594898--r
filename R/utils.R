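# Internal helpers shared across modules.

# Round half away from zero (the convention behind the reported integer
# critical bounds; base round() would go half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Reverse-complement of per-allele nucleotide strings (handles indel-style
# multi-base alleles too).
rev_comp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    bad <- !b %in% names(comp)
    if (any(bad)) return(NA_character_)
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

# A/T and C/G pairs are palindromic under reverse complement, so strand
# cannot be resolved from the allele labels alone.
is_strand_ambiguous <- function(a, b) {
  !is.na(a) & !is.na(b) & rev_comp(a) == b
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_famprs <- function(...) stop(..., call. = FALSE)

# Deterministic tab-separated writers used by every pipeline stage.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
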