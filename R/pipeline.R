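# Pipeline orchestration: each run_* stage reads the file dialects, calls
# the module functions, and writes deterministic TSV/JSON artifacts. The
# JSON summary of every stage echoes the package version, seed, and the
# policy switches in force.

#' Read a pipeline run configuration
#'
#' A YAML (or key: value) file with input paths (`weights`, `dosages`,
#' `pedigree`, `roster`, `annotations`, `candidate_genes`), policy switches
#' (`missing_policy`, `merge_mode`, `standardization_reference`,
#' `control_tie_break`, `alpha`), `seed` and `outdir`. Missing keys take
#' the package defaults.
#'
#' @param path YAML file, or a named list passed through.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(missing_policy = "skip", merge_mode = "shared",
                   standardization_reference = "all",
                   control_tie_break = "oldest", alpha = 0.05,
                   seed = 1L, outdir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

run_summary <- function(config, stage, extra = list()) {
  c(list(stage = stage,
         package = "famprs",
         version = as.character(utils::packageVersion("famprs")),
         seed = config$seed,
         policies = list(missing_policy = config$missing_policy,
                         merge_mode = config$merge_mode,
                         standardization_reference = config$standardization_reference,
                         control_tie_break = config$control_tie_break,
                         alpha = config$alpha)),
    extra)
}

load_inputs <- function(config, need) {
  for (key in need) {
    if (is.null(config[[key]]) || !file.exists(config[[key]])) {
      stop_famprs("run config is missing a usable `", key, "` input")
    }
  }
  out <- list()
  if ("weights" %in% need) out$score <- read_score_file(config$weights)
  if ("dosages" %in% need) out$panel <- read_dosage_tsv(config$dosages)
  if ("roster" %in% need) out$roster <- read_tsv_file(config$roster)
  if ("pedigree" %in% need) {
    out$ped <- parse_pedigree(config$pedigree,
                              roster = if (!is.null(config$roster))
                                read_tsv_file(config$roster))
  }
  out
}

scored_table <- function(config, inputs) {
  report <- harmonize(inputs$score, inputs$panel)
  prs <- compute_prs(inputs$score, inputs$panel, report,
                     missing_policy = config$missing_policy)
  reference <- if (identical(config$standardization_reference, "controls") &&
                   !is.null(inputs$roster)) {
    inputs$roster$sample_id[inputs$roster$bc_status == "control_eligible"]
  } else {
    NULL
  }
  list(report = report, prs = standardize_prs(prs, reference = reference))
}

#' Run the scoring stage
#'
#' Loads weights and genotypes, harmonizes, scores, standardizes, and
#' writes `prs.tsv`, `harmonization.tsv` and `score_summary.json` to the
#' output directory.
#'
#' @param config A [read_run_config()] result (or path / named list).
#' @return The `prs_table`, invisibly.
#' @export
run_score <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config, c("weights", "dosages"))
  if (!is.null(config$roster) && file.exists(config$roster %||% "")) {
    inputs$roster <- read_tsv_file(config$roster)
  }
  st <- scored_table(config, inputs)
  write_tsv_file(as.data.frame(st$prs), file.path(config$outdir, "prs.tsv"))
  write_harmonization_report(st$report,
                             tsv = file.path(config$outdir, "harmonization.tsv"))
  write_json_summary(
    run_summary(config, "score",
                list(n_samples = nrow(st$prs),
                     harmonization = attr(st$report, "counts"))),
    file.path(config$outdir, "score_summary.json"))
  invisible(st$prs)
}

#' Run pair construction
#'
#' Builds the five case-relative pair groups with PRS attached and writes
#' `pairs.tsv` (columns group, case, relative, relationship, degree, ages,
#' PRS).
#'
#' @inheritParams run_score
#' @return Named list of `pair_set`s, invisibly.
#' @export
run_pairs <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config, c("weights", "dosages", "pedigree", "roster"))
  st <- scored_table(config, inputs)
  groups <- c("sisters", "mothers", "daughters", "first_second",
              "total_relatives")
  pairsets <- lapply(groups, function(g) {
    enumerate_pairs(inputs$ped, g, prs = st$prs)
  })
  names(pairsets) <- groups
  write_tsv_file(do.call(rbind, lapply(pairsets, as.data.frame)),
                 file.path(config$outdir, "pairs.tsv"))
  invisible(pairsets)
}

#' Run the within-family analysis
#'
#' Pair construction plus the per-group signed-rank report (W, critical
#' bounds at the configured alpha, Z, p, mean ages); writes
#' `within_family.tsv` and `within_family.json`. A cohort with no affected
#' women yields an empty report and a warning, not an error.
#'
#' @inheritParams run_score
#' @return The per-group report `data.frame`, invisibly.
#' @export
run_wf <- function(config) {
  config <- read_run_config(config)
  pairsets <- run_pairs(config)
  if (all(vapply(pairsets, nrow, integer(1)) == 0)) {
    warning("no case-relative pairs in any group; empty within-family report")
  }
  report <- run_within_family(pairsets, alpha = config$alpha)
  write_tsv_file(report, file.path(config$outdir, "within_family.tsv"))
  write_json_summary(
    run_summary(config, "within_family",
                list(groups = stats::setNames(as.list(report$p), report$group))),
    file.path(config$outdir, "within_family.json"))
  invisible(report)
}

#' Run the population-level cohort analysis
#'
#' Case/control selection with the exclusion tally, per-SD logistic
#' association, and the PRS / age / joint AUCs; writes `selection.tsv`,
#' `association.json` and the density-plot data (`density_data.tsv`,
#' two columns: z-score and group).
#'
#' @inheritParams run_score
#' @return The `prs_assoc` result, invisibly.
#' @export
run_cohort <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config, c("weights", "dosages", "roster"))
  st <- scored_table(config, inputs)
  sel <- select_case_control(inputs$roster, tie_break = config$control_tie_break,
                             seed = config$seed)
  ids <- c(sel$case_ids, sel$control_ids)
  status <- as.integer(ids %in% sel$case_ids)
  z <- st$prs$z_score[match(ids, st$prs$sample_id)]
  age <- inputs$roster$age[match(ids, inputs$roster$sample_id)]
  assoc <- joint_model(z, age, status)
  write_tsv_file(data.frame(criterion = names(sel$tally),
                            n_removed = as.integer(sel$tally)),
                 file.path(config$outdir, "selection.tsv"))
  write_tsv_file(data.frame(z_score = z,
                            group = ifelse(status == 1, "case", "control")),
                 file.path(config$outdir, "density_data.tsv"))
  write_json_summary(
    run_summary(config, "cohort",
                list(n_cases = assoc$n_cases, n_controls = assoc$n_controls,
                     or_per_sd = assoc$or_per_sd, ci_low = assoc$ci_low,
                     ci_high = assoc$ci_high, auc_prs = assoc$auc_prs,
                     auc_age = assoc$auc_age, auc_joint = assoc$auc_joint)),
    file.path(config$outdir, "association.json"))
  invisible(assoc)
}

#' Run the monogenic carrier screen
#'
#' Merges the candidate-gene and ClinVar-style evidence per the configured
#' `merge_mode`, flags het/hom carriers, and writes `carriers.tsv` and a
#' per-gene JSON summary.
#'
#' @inheritParams run_score
#' @return The `carrier_table`, invisibly.
#' @export
run_monogenic <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$annotations) || !file.exists(config$annotations)) {
    stop_famprs("run config is missing a usable `annotations` input")
  }
  inputs <- load_inputs(config, c("dosages", "roster"))
  genes <- if (!is.null(config$candidate_genes)) config$candidate_genes
           else default_candidate_genes
  flagged <- build_pathogenic_set(genes, config$annotations,
                                  merge_mode = config$merge_mode)
  sel <- tryCatch(select_case_control(inputs$roster,
                                      tie_break = config$control_tie_break,
                                      seed = config$seed),
                  error = function(e) NULL)
  carriers <- flag_carriers(inputs$panel, flagged, selection = sel)
  write_tsv_file(as.data.frame(carriers),
                 file.path(config$outdir, "carriers.tsv"))
  present <- carriers[carriers$status == "present", , drop = FALSE]
  per_gene <- lapply(split(present, present$gene), function(g) {
    list(n_variants = nrow(g), n_het = sum(g$n_het), n_hom = sum(g$n_hom))
  })
  write_json_summary(
    run_summary(config, "monogenic",
                list(n_flagged = nrow(carriers),
                     n_present = nrow(present), per_gene = per_gene)),
    file.path(config$outdir, "monogenic_summary.json"))
  invisible(carriers)
}

#' Run the synthetic cohort generator
#'
#' Builds a [simulate_cohort()] from the run config (simulator fields may
#' be given under `sim:` in the YAML) and writes every input dialect the
#' other stages read, plus `simulate_summary.json`.
#'
#' @inheritParams run_score
#' @return The `sim_cohort`, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$sim %||% list()
  sim_args$seed <- config$seed
  cohort <- simulate_cohort(do.call(sim_config, sim_args))
  paths <- write_cohort(cohort, config$outdir)
  write_json_summary(
    run_summary(config, "simulate",
                list(n_families = cohort$config$n_families,
                     n_individuals = nrow(cohort$pedigree),
                     n_cases = sum(cohort$roster$bc_status == "case"),
                     files = lapply(paths, basename))),
    file.path(config$outdir, "simulate_summary.json"))
  invisible(cohort)
}
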