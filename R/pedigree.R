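#' Parse a pedigree from a PLINK-style family table
#'
#' Accepts the first six columns of the PLINK `.fam`/`.ped` dialect
#' (whitespace-separated: family id, individual id, father id, mother id,
#' sex coded 1 = male / 2 = female, phenotype coded 1 = unaffected /
#' 2 = affected, 0 or -9 = unknown), with `'0'` for an unknown parent.
#' An optional phenotype roster overrides affection and supplies ages.
#'
#' Validation: duplicate individual ids within a family, individuals listed
#' as their own ancestor (cycles), named fathers that are female (or
#' mothers male) are errors; parent ids that do not resolve within the
#' family are demoted to unknown with a warning.
#'
#' @param source Path to a `.fam`/`.ped` file, or a `data.frame` with at
#'   least 6 columns in that order.
#' @param roster Optional roster `data.frame` (or TSV path) with columns
#'   `sample_id`, `sex`, `age`, `affection`, and optionally `age_at_onset`;
#'   matched to individuals by `sample_id` = individual id.
#' @return A `pedigree`: a `data.frame` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (`NA` = unknown), `sex`
#'   (`"female"`/`"male"`), `affection` (`"affected"`, `"unaffected"`,
#'   `"unknown"`), `age`, `age_at_onset`.
#' @export
parse_pedigree <- function(source, roster = NULL) {
  if (is.character(source) && length(source) == 1) {
    tab <- utils::read.table(source, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
  } else {
    tab <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 6) stop_famprs("pedigree table needs 6 columns (fam dialect)")
  tab <- tab[, 1:6]
  names(tab) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  for (j in 1:4) tab[[j]] <- as.character(tab[[j]])

  sex <- as.character(tab$sex)
  sex <- ifelse(sex %in% c("1", "male"), "male",
                ifelse(sex %in% c("2", "female"), "female", NA))
  if (anyNA(sex)) stop_famprs("unrecognized sex code (expected 1/2)")

  phen <- as.character(tab$phenotype)
  affection <- ifelse(phen %in% c("2", "affected"), "affected",
                      ifelse(phen %in% c("1", "unaffected"), "unaffected",
                             "unknown"))

  ped <- data.frame(family_id = tab$family_id,
                    individual_id = tab$individual_id,
                    father_id = ifelse(tab$father_id == "0", NA, tab$father_id),
                    mother_id = ifelse(tab$mother_id == "0", NA, tab$mother_id),
                    sex = sex, affection = affection,
                    age = NA_real_, age_at_onset = NA_real_,
                    stringsAsFactors = FALSE)

  key <- paste(ped$family_id, ped$individual_id)
  if (anyDuplicated(key)) {
    stop_famprs("duplicate individual id within a family: ",
                paste(unique(key[duplicated(key)]), collapse = ", "))
  }

  # resolve parent references within each family
  for (col in c("father_id", "mother_id")) {
    pk <- paste(ped$family_id, ped[[col]])
    unresolved <- !is.na(ped[[col]]) & !pk %in% key
    if (any(unresolved)) {
      warning(sum(unresolved), " ", col,
              " reference(s) not found in family; treated as unknown")
      ped[[col]][unresolved] <- NA
    }
  }

  # sex consistency of named parents
  sex_of <- stats::setNames(ped$sex, key)
  fk <- paste(ped$family_id, ped$father_id)
  mk <- paste(ped$family_id, ped$mother_id)
  if (any(!is.na(ped$father_id) & sex_of[fk] != "male")) {
    stop_famprs("individual named as father is not male")
  }
  if (any(!is.na(ped$mother_id) & sex_of[mk] != "female")) {
    stop_famprs("individual named as mother is not female")
  }

  if (!is.null(roster)) {
    if (is.character(roster)) roster <- read_tsv_file(roster)
    i <- match(ped$individual_id, roster$sample_id)
    hit <- !is.na(i)
    if ("affection" %in% names(roster)) {
      ped$affection[hit] <- as.character(roster$affection[i[hit]])
    }
    if ("age" %in% names(roster)) ped$age[hit] <- as.numeric(roster$age[i[hit]])
    if ("age_at_onset" %in% names(roster)) {
      ped$age_at_onset[hit] <- as.numeric(roster$age_at_onset[i[hit]])
    }
  }
  if (any(!is.na(ped$age) & ped$age < 0)) stop_famprs("negative age in roster")

  ped <- structure(ped, class = c("pedigree", "data.frame"))
  check_acyclic(ped)
  ped
}

# Vectorized global peel: every individual must become placeable once its
# (known) parents are placed; leftovers indicate a cycle.
check_acyclic <- function(ped) {
  key <- paste(ped$family_id, ped$individual_id)
  fi <- match(paste(ped$family_id, ped$father_id), key)
  mi <- match(paste(ped$family_id, ped$mother_id), key)
  fi_safe <- ifelse(is.na(fi), 1L, fi)
  mi_safe <- ifelse(is.na(mi), 1L, mi)
  placed <- rep(FALSE, nrow(ped))
  repeat {
    ready <- !placed &
      (is.na(fi) | placed[fi_safe]) &
      (is.na(mi) | placed[mi_safe])
    if (!any(ready)) break
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    bad <- ped$family_id[!placed][1]
    stop_famprs("pedigree cycle detected in family ", bad,
                " (an individual is its own ancestor)")
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals in %d families (%d affected)\n",
              nrow(x), length(unique(x$family_id)),
              sum(x$affection == "affected")))
  invisible(x)
}

# Topological order (parents before children) of one family; errors on
# cycles, including self-parenting.
ped_order <- function(ped, family_id) {
  fam <- ped[ped$family_id == family_id, , drop = FALSE]
  ids <- fam$individual_id
  father <- stats::setNames(fam$father_id, ids)
  mother <- stats::setNames(fam$mother_id, ids)
  placed <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(father[i]) || father[i] %in% placed) &&
        (is.na(mother[i]) || mother[i] %in% placed)
    }, logical(1))]
    if (length(ready) == 0) {
      stop_famprs("pedigree cycle detected in family ", family_id,
                  " (an individual is its own ancestor)")
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Kinship matrix of one family
#'
#' Standard recursive kinship on the family graph: founders are pairwise
#' unrelated and non-inbred (`phi(a, a) = 1/2`), and for `a` with parents
#' `f, m` and any `b` that is not a descendant of `a`,
#' `phi(a, b) = (phi(f, b) + phi(m, b)) / 2` with `phi(unknown, b) = 0`;
#' `phi(a, a) = 1/2 + phi(f, m) / 2`.
#'
#' @param ped A [parse_pedigree()] result.
#' @param family_id Family to compute.
#' @return Symmetric numeric matrix indexed by individual id.
#' @export
kinship_matrix <- function(ped, family_id) {
  ord <- ped_order(ped, family_id)
  fam <- ped[ped$family_id == family_id, , drop = FALSE]
  father <- stats::setNames(fam$father_id, fam$individual_id)
  mother <- stats::setNames(fam$mother_id, fam$individual_id)
  n <- length(ord)
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  get <- function(p, j) if (is.na(p)) 0 else phi[p, j]
  for (i in seq_len(n)) {
    a <- ord[i]
    f <- father[a]; m <- mother[a]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        b <- ord[j]
        phi[a, b] <- phi[b, a] <- (get(f, b) + get(m, b)) / 2
      }
    }
    phi[a, a] <- 0.5 + (if (is.na(f) || is.na(m)) 0 else phi[f, m] / 2)
  }
  phi
}

#' Kinship coefficient between two individuals
#'
#' @param ped A [parse_pedigree()] result.
#' @param a,b Individual ids (must share a family).
#' @return The kinship coefficient (0 for members of different families).
#' @export
kinship <- function(ped, a, b) {
  fa <- ped$family_id[ped$individual_id == a]
  fb <- ped$family_id[ped$individual_id == b]
  if (length(fa) == 0 || length(fb) == 0) {
    stop_famprs("unknown individual: ", if (length(fa) == 0) a else b)
  }
  if (fa != fb) return(0)
  phi <- kinship_matrix(ped, fa)
  phi[a, b]
}

# parents of id within a family slice; character(0) when unknown
ped_parents <- function(fam, id) {
  r <- fam[fam$individual_id == id, ]
  stats::na.omit(c(r$father_id, r$mother_id))
}

full_siblings <- function(fam, id) {
  r <- fam[fam$individual_id == id, ]
  if (is.na(r$father_id) || is.na(r$mother_id)) return(character(0))
  sib <- fam$individual_id[!is.na(fam$father_id) & !is.na(fam$mother_id) &
                             fam$father_id == r$father_id &
                             fam$mother_id == r$mother_id]
  setdiff(sib, id)
}

#' Classify the relationship between two individuals
#'
#' Degree is assigned from the canonical path type, not the raw kinship
#' value, so inbreeding cannot promote a pair: first degree =
#' parent/offspring or full sibling; second degree = grandparent/grandchild,
#' half sibling, or (full) aunt/uncle vs niece/nephew; any other pair with
#' nonzero kinship is `"3+"`; zero kinship is `"unrelated"`. The label
#' describes `b` relative to `a` (e.g. `"mother"` means `b` is `a`'s
#' mother), using female terms for female `b`.
#'
#' @inheritParams kinship
#' @return List with `degree` (`"1"`, `"2"`, `"3+"`, `"unrelated"`) and
#'   `label`.
#' @export
classify_degree <- function(ped, a, b) {
  fa <- ped$family_id[ped$individual_id == a]
  fb <- ped$family_id[ped$individual_id == b]
  if (length(fa) == 0 || length(fb) == 0) {
    stop_famprs("unknown individual: ", if (length(fa) == 0) a else b)
  }
  if (fa != fb) return(list(degree = "unrelated", label = "unrelated"))
  fam <- ped[ped$family_id == fa, , drop = FALSE]
  sex_b <- fam$sex[fam$individual_id == b]
  fem <- sex_b == "female"
  lab <- function(f, m) if (fem) f else m

  pa <- ped_parents(fam, a)
  pb <- ped_parents(fam, b)
  if (b %in% pa) {
    return(list(degree = "1", label = lab("mother", "father")))
  }
  if (a %in% pb) {
    return(list(degree = "1", label = lab("daughter", "son")))
  }
  shared <- intersect(pa, pb)
  if (length(pa) == 2 && length(pb) == 2 && length(shared) == 2) {
    return(list(degree = "1", label = lab("full-sister", "full-brother")))
  }
  if (length(shared) >= 1) {
    return(list(degree = "2", label = lab("half-sister", "half-brother")))
  }
  grand_a <- unique(unlist(lapply(pa, ped_parents, fam = fam)))
  grand_b <- unique(unlist(lapply(pb, ped_parents, fam = fam)))
  if (b %in% grand_a) {
    return(list(degree = "2", label = lab("grandmother", "grandfather")))
  }
  if (a %in% grand_b) {
    return(list(degree = "2", label = lab("granddaughter", "grandson")))
  }
  parent_sibs_a <- unique(unlist(lapply(pa, full_siblings, fam = fam)))
  if (b %in% parent_sibs_a) {
    return(list(degree = "2", label = lab("aunt", "uncle")))
  }
  parent_sibs_b <- unique(unlist(lapply(pb, full_siblings, fam = fam)))
  if (a %in% parent_sibs_b) {
    return(list(degree = "2", label = lab("niece", "nephew")))
  }
  phi <- kinship_matrix(ped, fa)
  if (phi[a, b] > 0) return(list(degree = "3+", label = "other"))
  list(degree = "unrelated", label = "unrelated")
}
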