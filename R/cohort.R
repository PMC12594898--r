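#' Select cases and controls from a phenotype roster
#'
#' Applies the study exclusion rules in order: (i) males removed;
#' (ii) individuals with incomplete genetic or phenotypic information
#' removed; (iii) controls with any personal or family history of disease
#' removed; (iv) at most one control per family. Cases are the remaining
#' affected women; controls are drawn from the remaining eligible women.
#'
#' @param roster `data.frame` with columns `sample_id`, `family_id`, `sex`,
#'   `age`, `bc_status` (`"case"`, `"control_eligible"`, `"ineligible"`),
#'   `personal_history`, `family_history`, `genotyped`,
#'   `phenotype_complete` (logical flags).
#' @param tie_break How to pick the one control per family: `"oldest"`
#'   (deterministic, ties broken by sample id) or `"random"` (seeded).
#' @param seed Seed for `tie_break = "random"`; `NULL` uses the current
#'   RNG state.
#' @return A `selection_result` list: `case_ids`, `control_ids`, and
#'   `tally` (named count removed per criterion, application order).
#' @export
select_case_control <- function(roster, tie_break = c("oldest", "random"),
                                seed = NULL) {
  tie_break <- match.arg(tie_break)
  need <- c("sample_id", "family_id", "sex", "age", "bc_status",
            "personal_history", "family_history", "genotyped",
            "phenotype_complete")
  miss <- setdiff(need, names(roster))
  if (length(miss) > 0) stop_famprs("roster lacks columns: ",
                                    paste(miss, collapse = ", "))
  tally <- c(male = 0L, incomplete = 0L, history = 0L, one_per_family = 0L)

  keep <- roster$sex == "female"
  tally["male"] <- sum(!keep)
  r <- roster[keep, , drop = FALSE]

  complete <- as.logical(r$genotyped) & as.logical(r$phenotype_complete)
  tally["incomplete"] <- sum(!complete)
  r <- r[complete, , drop = FALSE]

  case_ids <- r$sample_id[r$bc_status == "case"]
  pool <- r[r$bc_status == "control_eligible", , drop = FALSE]

  hist_flag <- as.logical(pool$personal_history) | as.logical(pool$family_history)
  tally["history"] <- sum(hist_flag)
  pool <- pool[!hist_flag, , drop = FALSE]

  if (nrow(pool) > 0) {
    if (tie_break == "random" && !is.null(seed)) set.seed(seed)
    pick <- vapply(split(seq_len(nrow(pool)), pool$family_id), function(i) {
      if (tie_break == "oldest") {
        i[order(-pool$age[i], pool$sample_id[i])][1]
      } else {
        if (length(i) == 1) i else sample(i, 1)
      }
    }, integer(1))
    tally["one_per_family"] <- nrow(pool) - length(pick)
    pool <- pool[pick, , drop = FALSE]
  }
  control_ids <- sort(pool$sample_id)

  if (length(case_ids) == 0) stop_famprs("no cases left after selection")
  if (length(control_ids) == 0) stop_famprs("no controls left after selection")
  structure(list(case_ids = sort(case_ids), control_ids = control_ids,
                 tally = tally, tie_break = tie_break),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d cases, %d controls\n",
              length(x$case_ids), length(x$control_ids)))
  cat("  removed:", paste(names(x$tally), x$tally, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# shared glm wrapper with separation detection
fit_logit <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) stop_famprs("logistic fit did not converge")
  if (sep && any(abs(stats::coef(fit)[-1]) > 10)) {
    stop_famprs("perfect separation: the logistic odds ratio is not identifiable")
  }
  fit
}

#' Per-SD logistic association between PRS and disease status
#'
#' Maximum-likelihood logistic regression of case status on the
#' standardized score (optionally adjusted for age); the odds ratio per SD
#' is `exp(beta)` with a Wald 95% interval `exp(beta +/- 1.96 * SE)`.
#'
#' @param z Standardized PRS per sample.
#' @param status Binary status (1/TRUE = case).
#' @param covariate Optional adjustment covariate (age).
#' @return A `prs_assoc` list: `or_per_sd`, `ci_low`, `ci_high`, `beta`,
#'   `se`, `p`, `n_cases`, `n_controls`, `fit`.
#' @export
fit_logistic <- function(z, status, covariate = NULL) {
  status <- as.integer(as.logical(status))
  if (length(unique(status)) < 2) stop_famprs("need both cases and controls")
  if (stats::sd(z) == 0) stop_famprs("predictor has zero variance")
  df <- data.frame(y = status, z = z)
  form <- y ~ z
  if (!is.null(covariate)) {
    df$covariate <- covariate
    form <- y ~ z + covariate
  }
  fit <- fit_logit(form, df)
  beta <- stats::coef(fit)[["z"]]
  se <- sqrt(stats::vcov(fit)["z", "z"])
  zq <- stats::qnorm(0.975)
  structure(list(or_per_sd = exp(beta),
                 ci_low = exp(beta - zq * se),
                 ci_high = exp(beta + zq * se),
                 beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n_cases = sum(status == 1), n_controls = sum(status == 0),
                 fit = fit),
            class = "prs_assoc")
}

#' @export
print.prs_assoc <- function(x, ...) {
  cat(sprintf("OR per SD = %.3f (95%% CI %.3f-%.3f), p = %.3g [%d cases / %d controls]\n",
              x$or_per_sd, x$ci_low, x$ci_high, x$p, x$n_cases, x$n_controls))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with ties credited 1/2 — computed from midranks, which
#' is exactly the case-control pair count divided by
#' `n_cases * n_controls`.
#'
#' @param scores Numeric risk scores.
#' @param status Binary status (1/TRUE = case).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, status) {
  status <- as.logical(status)
  n1 <- sum(status)
  n0 <- sum(!status)
  if (n1 == 0 || n0 == 0) stop_famprs("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[status]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Joint PRS + age model with discrimination summary
#'
#' Fits the two-covariate logistic model and reports the per-SD odds ratio
#' for the score adjusted for age, together with the rank-based AUCs of the
#' score alone, age alone, and the joint fitted probabilities.
#'
#' @param z Standardized PRS.
#' @param age Age in years (modeled linearly).
#' @param status Binary status (1/TRUE = case).
#' @return A `prs_assoc` list extended with `auc_prs`, `auc_age`,
#'   `auc_joint`.
#' @export
joint_model <- function(z, age, status) {
  if (stats::sd(age) == 0 || qr(cbind(1, z, age))$rank < 3) {
    stop_famprs("degenerate design: age and PRS columns are collinear or constant")
  }
  assoc <- fit_logistic(z, status, covariate = age)
  assoc$auc_prs <- rank_auc(z, status)
  assoc$auc_age <- rank_auc(age, status)
  assoc$auc_joint <- rank_auc(stats::fitted(assoc$fit), status)
  assoc
}
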