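#' Normal-approximation critical interval for the signed-rank W
#'
#' Under the null, the smaller rank sum W has mean `n(n+1)/4` and standard
#' deviation `sqrt(n(n+1)(2n+1)/24)`; the two-sided acceptance region at
#' level `alpha` is `mean_w +/- z_{1-alpha/2} * sd_w`, rounded
#' half-away-from-zero to the nearest integer.
#'
#' @param n Number of pairs after dropping zero differences.
#' @param alpha Two-sided level (default 0.05).
#' @return Named numeric vector `c(low, high)` of integer bounds.
#' @examples
#' critical_interval(200, 0.05)  # 8444 11656
#' @export
critical_interval <- function(n, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  mean_w <- n * (n + 1) / 4
  sd_w <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  zq <- stats::qnorm(1 - alpha / 2)
  c(low = round_half_away(mean_w - zq * sd_w),
    high = round_half_away(mean_w + zq * sd_w))
}

# Normal-approximation summary from (n, w) alone; the arithmetic behind
# every reported Z, p and critical bound.
wilcoxon_normal <- function(n, w, alpha = 0.05, tie_term = 0) {
  mean_w <- n * (n + 1) / 4
  var_w <- n * (n + 1) * (2 * n + 1) / 24 - tie_term / 48
  sd_w <- sqrt(var_w)
  z <- (w - mean_w) / sd_w
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  ci <- critical_interval(n, alpha)
  list(n_used = n, w = w, mean_w = mean_w, sd_w = sd_w, z = z,
       p_two_sided = p, alpha = alpha,
       critical_low = unname(ci["low"]), critical_high = unname(ci["high"]))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Exact-zero differences are dropped; absolute differences are ranked with
#' midranks for ties; `w_plus` and `w_minus` are the rank sums of positive
#' and negative differences and `W = min(w_plus, w_minus)` (the
#' smaller-rank-sum convention, so the standardized `z` is always <= 0);
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` with no tie correction by
#' default, and `p = 2 * Phi(z)`. A `direction` field records which side
#' dominated. The acceptance region for W at `alpha` comes from
#' [critical_interval()].
#'
#' @param differences Numeric vector of paired differences
#'   (case minus relative).
#' @param alpha Level for the critical interval.
#' @param tie_correction Subtract the tied-group term
#'   `sum(t^3 - t) / 48` from the null variance (default `FALSE`).
#' @return A `wilcoxon_result` list: `n_pairs`, `n_zero`, `n_used`,
#'   `w_plus`, `w_minus`, `w`, `mean_w`, `sd_w`, `z`, `p_two_sided`,
#'   `alpha`, `critical_low`, `critical_high`, `direction`.
#' @examples
#' signed_rank_test(c(1.2, -0.5, 0.3, 2.1, -0.2))
#' @export
signed_rank_test <- function(differences, alpha = 0.05, tie_correction = FALSE) {
  stopifnot(is.numeric(differences), length(differences) >= 1)
  n_pairs <- length(differences)
  d <- differences[differences != 0]
  n_zero <- n_pairs - length(d)
  if (length(d) == 0) stop_famprs("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))  # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  tie_term <- 0
  if (tie_correction) {
    t <- table(abs(d))
    tie_term <- sum(t^3 - t)
  }
  base <- wilcoxon_normal(n, w, alpha, tie_term)
  out <- c(list(n_pairs = n_pairs, n_zero = n_zero,
                w_plus = w_plus, w_minus = w_minus,
                direction = sign(w_plus - w_minus)),
           base)
  structure(out, class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank (normal approximation)\n")
  cat(sprintf("  n = %d pairs (%d zero differences dropped)\n",
              x$n_pairs, x$n_zero))
  cat(sprintf("  W = %g (W+ = %g, W- = %g), critical [%d, %d] at alpha = %g\n",
              x$w, x$w_plus, x$w_minus, x$critical_low, x$critical_high,
              x$alpha))
  cat(sprintf("  Z = %.4f, two-sided p = %.4g\n", x$z, x$p_two_sided))
  invisible(x)
}

#' Exact sign-flip p-value (enumeration oracle)
#'
#' Enumerates all `2^n` sign assignments of the absolute differences and
#' returns the exact two-sided p-value of the observed smaller rank sum:
#' the fraction of assignments whose positive rank sum is at most
#' `min(w_plus, w_minus)` or at least the symmetric upper counterpart.
#' Intended as an independent check of the normal approximation at small n.
#'
#' @param differences Paired differences; at most 20 nonzero values.
#' @return Exact two-sided p in (0, 1].
#' @export
exact_permutation_p <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) stop_famprs("all paired differences are zero")
  if (n > 20) stop_famprs("exact enumeration limited to n <= 20")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  total <- sum(r)
  w_obs <- min(w_plus, total - w_plus)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wp <- as.vector(signs %*% r)
  mean(wp <= w_obs + 1e-9 | wp >= total - w_obs - 1e-9)
}

#' Run the within-family signed-rank analysis over pair groups
#'
#' Applies [signed_rank_test()] to the PRS z-score differences
#' (case minus relative) of each pair group and assembles one row per
#' group: sample size, W, the alpha-level critical bounds for W, Z, p, and
#' the mean case/relative ages. Groups with no pairs are reported as
#' skipped rather than failing the run.
#'
#' @param pairsets A `pair_set` or (possibly named) list of them, each
#'   carrying `case_prs`/`relative_prs` (see [enumerate_pairs()] with
#'   `prs`).
#' @param alpha Level for critical intervals.
#' @param tie_correction Passed to [signed_rank_test()].
#' @return `data.frame` with columns `group`, `n_pairs`, `n_used`, `w`,
#'   `critical_low`, `critical_high`, `z`, `p`, `mean_case_age`,
#'   `mean_relative_age`, `skipped`.
#' @export
run_within_family <- function(pairsets, alpha = 0.05, tie_correction = FALSE) {
  if (inherits(pairsets, "pair_set")) pairsets <- list(pairsets)
  rows <- lapply(pairsets, function(ps) {
    grp <- attr(ps, "group") %||% unique(ps$group) %||% "?"
    if (nrow(ps) == 0) {
      message("group ", grp, " has no pairs; skipped")
      return(data.frame(group = grp, n_pairs = 0L, n_used = NA_integer_,
                        w = NA_real_, critical_low = NA_real_,
                        critical_high = NA_real_, z = NA_real_, p = NA_real_,
                        mean_case_age = NA_real_, mean_relative_age = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    if (!all(c("case_prs", "relative_prs") %in% names(ps))) {
      stop_famprs("pair set for group ", grp, " lacks PRS columns")
    }
    wt <- signed_rank_test(ps$case_prs - ps$relative_prs, alpha = alpha,
                           tie_correction = tie_correction)
    data.frame(group = grp, n_pairs = wt$n_pairs, n_used = wt$n_used,
               w = wt$w, critical_low = wt$critical_low,
               critical_high = wt$critical_high, z = wt$z, p = wt$p_two_sided,
               mean_case_age = mean(ps$case_age, na.rm = TRUE),
               mean_relative_age = mean(ps$relative_age, na.rm = TRUE),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
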