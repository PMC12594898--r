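#' Read a PRS weight file
#'
#' Parses a tab-separated scoring file in the PGS-Catalog dialect: a header
#' line with columns `rsID`, `chr_name`, `chr_position`, `effect_allele`,
#' `other_allele` and either `effect_weight` (per-allele log odds ratio,
#' natural log scale) or `OR` (per-allele odds ratio, converted to
#' `log(OR)`). Lines starting with `#` are treated as comments.
#'
#' @param source Path to a tab-separated weight file, or a `data.frame`
#'   already holding the columns above.
#' @param name Label for the score (defaults to the file name, or "PRS").
#' @return A `score_file`: a `data.frame` with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `weight`,
#'   one row per variant, input order preserved.
#' @examples
#' f <- system.file("extdata", "toy_weights.tsv", package = "famprs")
#' score <- read_score_file(f)
#' head(score)
#' @export
read_score_file <- function(source, name = NULL) {
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      stop_famprs("weight file not found: ", source)
    }
    name <- name %||% sub("\\.[^.]*$", "", basename(source))
    tab <- read_tsv_file(source, colClasses = "character")
  } else if (is.data.frame(source)) {
    tab <- source
  } else {
    stop_famprs("`source` must be a file path or a data.frame")
  }
  name <- name %||% "PRS"

  id_col <- intersect(c("rsID", "variant_id", "rsid"), names(tab))[1]
  if (is.na(id_col)) stop_famprs("weight table lacks an rsID/variant_id column")
  for (col in c("effect_allele", "other_allele")) {
    if (!col %in% names(tab)) {
      stop_famprs("weight table lacks mandatory column `", col, "`")
    }
  }

  if ("effect_weight" %in% names(tab)) {
    weight <- as.numeric(tab$effect_weight)
  } else if ("OR" %in% names(tab)) {
    or <- as.numeric(tab$OR)
    if (any(!is.na(or) & or <= 0)) {
      stop_famprs("odds ratios must be positive to take log(OR)")
    }
    weight <- log(or)
  } else {
    stop_famprs("weight table needs an `effect_weight` or `OR` column")
  }
  if (any(!is.finite(weight))) {
    stop_famprs("non-finite weight in score file")
  }

  variant_id <- as.character(tab[[id_col]])
  if (anyDuplicated(variant_id)) {
    stop_famprs("duplicate variant ids in score file: ",
                paste(unique(variant_id[duplicated(variant_id)]), collapse = ", "))
  }

  ea <- toupper(as.character(tab$effect_allele))
  oa <- toupper(as.character(tab$other_allele))
  if (any(ea == oa)) stop_famprs("effect allele equals other allele for some variants")

  out <- data.frame(
    variant_id = variant_id,
    chromosome = if ("chr_name" %in% names(tab)) as.character(tab$chr_name) else NA_character_,
    position = if ("chr_position" %in% names(tab)) as.integer(tab$chr_position) else NA_integer_,
    effect_allele = ea,
    other_allele = oa,
    weight = weight,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("score_file", "data.frame"), score_name = name)
}

#' @export
print.score_file <- function(x, ...) {
  cat(sprintf("<score_file> %s: %d weighted variants\n",
              attr(x, "score_name"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
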