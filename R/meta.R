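#' Inverse-variance fixed-effect pooling
#'
#' Weights each study by the inverse of its squared standard error:
#' `w_i = 1/se_i^2`, `beta_F = sum(w_i b_i) / sum(w_i)`,
#' `se_F = 1/sqrt(sum(w_i))`, and Cochran's
#' `Q = sum(w_i (b_i - beta_F)^2)`.
#'
#' @param estimates Effect-estimate data frame with columns `beta`, `se`
#'   (at least 2 rows, all `se > 0`).
#' @return List with `beta_fixed`, `se_fixed`, `q_stat`, `weights`.
#' @export
fixed_effect <- function(estimates) {
  beta <- estimates$beta; se <- estimates$se
  k <- length(beta)
  if (k < 2L) stop("meta-analysis requires at least 2 studies (k = ", k, ")")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  beta_fixed <- sum(w * beta) / sum(w)
  list(beta_fixed = beta_fixed,
       se_fixed = 1 / sqrt(sum(w)),
       q_stat = sum(w * (beta - beta_fixed)^2),
       weights = w)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' The moment estimator of the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w`. Random-effects weights are
#' `w*_i = 1/(se_i^2 + tau2)`; the pooled log odds ratio is their weighted
#' mean with `se_R = 1/sqrt(sum(w*))`. The 95% CI uses the normal 1.96
#' quantile on the log scale and is exponentiated for reporting.
#' Heterogeneity is `I2 = max(0, (Q - (k-1))/Q) * 100` (0 when `Q = 0`).
#' The summary p-value is two-sided normal on `z = beta_R/se_R`.
#'
#' When `tau2` truncates to 0 the random-effects result equals the
#' fixed-effect result exactly.
#'
#' @param estimates Effect-estimate data frame (`beta`, `se`, optionally
#'   `study_id`), `k >= 2` rows.
#' @return Object of class `meta_result` with fields `k`, `beta_fixed`,
#'   `se_fixed`, `q_stat`, `tau2`, `i2`, `beta_random`, `se_random`,
#'   `or_random`, `ci_random` (length 2, OR scale), `z`, `p_summary`,
#'   `weights_random`, `estimates`.
#' @examples
#' est <- rbind(se_from_ci(1.5, 1.2, study_id = "A"),
#'              se_from_ci(1.3, 1.05, study_id = "B"))
#' dersimonian_laird(est)
#' @export
dersimonian_laird <- function(estimates) {
  fe <- fixed_effect(estimates)
  beta <- estimates$beta; se <- estimates$se
  k <- length(beta)
  w <- fe$weights
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (fe$q_stat - (k - 1)) / denom) else 0
  w_star <- 1 / (se^2 + tau2)
  beta_random <- sum(w_star * beta) / sum(w_star)
  se_random <- 1 / sqrt(sum(w_star))
  i2 <- if (fe$q_stat > 0) max(0, (fe$q_stat - (k - 1)) / fe$q_stat) * 100 else 0
  z <- beta_random / se_random
  structure(list(k = k,
                 beta_fixed = fe$beta_fixed, se_fixed = fe$se_fixed,
                 q_stat = fe$q_stat, tau2 = tau2, i2 = i2,
                 beta_random = beta_random, se_random = se_random,
                 or_random = exp(beta_random),
                 ci_random = exp(beta_random + c(-1.96, 1.96) * se_random),
                 z = z,
                 p_summary = 2 * stats::pnorm(-abs(z)),
                 weights_random = w_star,
                 estimates = estimates),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k))
  cat(sprintf("  OR = %.2f [%.2f, %.2f], z = %.2f, p = %.3g\n",
              x$or_random, x$ci_random[1L], x$ci_random[2L], x$z, x$p_summary))
  cat(sprintf("  Q = %.3f, tau2 = %.4f, I2 = %.1f%% (%s heterogeneity)\n",
              x$q_stat, x$tau2, x$i2, classify_heterogeneity(x)))
  invisible(x)
}

#' Classify heterogeneity from I-squared
#'
#' `"low"` iff `I2 < 50` (strict); 50% and above is `"high"`.
#'
#' @param result A `meta_result` (or a number interpreted as I2).
#' @return `"low"` or `"high"`.
#' @export
classify_heterogeneity <- function(result) {
  i2 <- if (inherits(result, "meta_result")) result$i2 else result
  if (i2 < 50) "low" else "high"
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs the random-effects pooling with each study omitted in turn and
#' records whether the summary significance (p < 0.05, strict) flips
#' relative to the full analysis. In restricted mode only studies flagged
#' by the quality gate (`high_risk_nos` or `hwe_deviation`) are omitted —
#' the omission-if-suspect protocol.
#'
#' @param estimates Effect-estimate data frame, ideally gated via
#'   [quality_gate()]; `k >= 3` for any omission to leave a valid pooled
#'   result (`k = 2` returns an empty list with a warning).
#' @param restrict_to_flagged Omit only flagged studies (default `FALSE`:
#'   omit every study in turn).
#' @param alpha Summary-significance threshold (default 0.05).
#' @return List of `sensitivity_result` objects, each with
#'   `omitted_study_id`, `result_without` (a `meta_result`) and
#'   `significance_flipped`.
#' @export
leave_one_out <- function(estimates, restrict_to_flagged = FALSE,
                          alpha = 0.05) {
  k <- nrow(estimates)
  if (k < 2L) stop("meta-analysis requires at least 2 studies")
  if (k == 2L) {
    warning("k = 2: omitting a study leaves a single estimate; no sensitivity analysis")
    return(list())
  }
  parent <- dersimonian_laird(estimates)
  parent_sig <- parent$p_summary < alpha
  idx <- seq_len(k)
  if (restrict_to_flagged) {
    flagged <- (if ("high_risk_nos" %in% names(estimates))
                  estimates$high_risk_nos else rep(FALSE, k)) |
               (if ("hwe_deviation" %in% names(estimates))
                  estimates$hwe_deviation else rep(FALSE, k))
    idx <- idx[flagged]
  }
  lapply(idx, function(i) {
    res <- dersimonian_laird(estimates[-i, , drop = FALSE])
    structure(list(omitted_study_id = estimates$study_id[i],
                   result_without = res,
                   significance_flipped = xor(parent_sig, res$p_summary < alpha)),
              class = "sensitivity_result")
  })
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("omit %s: OR = %.2f, p = %.3g%s\n", x$omitted_study_id,
              x$result_without$or_random, x$result_without$p_summary,
              if (x$significance_flipped) "  [significance flipped]" else ""))
  invisible(x)
}

#' Funnel-plot data
#'
#' Returns the per-study points (`study_id`, `beta`, `se`) and the
#' pseudo-95% guide lines `beta_random +/- 1.96 se` evaluated over the
#' standard-error range, for visual publication-bias assessment. No
#' asymmetry statistic is computed.
#'
#' @param estimates Effect-estimate data frame.
#' @param result The `meta_result` for these estimates.
#' @param n_guide Number of guide-line points (default 25).
#' @return List with data frames `points` (`study_id`, `beta`, `se`) and
#'   `guides` (`se`, `lower`, `upper`).
#' @export
funnel_data <- function(estimates, result, n_guide = 25L) {
  stopifnot(inherits(result, "meta_result"), nrow(estimates) >= 2L)
  se_grid <- seq(0, max(estimates$se) * 1.05, length.out = n_guide)
  list(points = data.frame(study_id = estimates$study_id,
                           beta = estimates$beta, se = estimates$se,
                           stringsAsFactors = FALSE),
       guides = data.frame(se = se_grid,
                           lower = result$beta_random - 1.96 * se_grid,
                           upper = result$beta_random + 1.96 * se_grid))
}

#' Summary table across SNPs
#'
#' One row per SNP: number of studies, pooled OR (2 decimals for display;
#' full precision retained in the input objects), 95% CI, summary p, I2,
#' heterogeneity class and the significance flag at p < 0.05 (strict). No
#' multiple-testing correction is applied across SNPs; the footer attribute
#' records this.
#'
#' @param results Named list mapping SNP -> `meta_result`.
#' @return Data frame with attribute `footer`.
#' @export
meta_table <- function(results) {
  cols <- c("snp", "k", "or", "ci_lower", "ci_upper", "p_summary", "i2",
            "heterogeneity", "significant")
  if (length(results) == 0L) {
    out <- data.frame(snp = character(0), k = integer(0), or = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p_summary = numeric(0), i2 = numeric(0),
                      heterogeneity = character(0), significant = logical(0))
  } else {
    out <- do.call(rbind, lapply(names(results), function(snp) {
      r <- results[[snp]]
      data.frame(snp = snp, k = r$k, or = round(r$or_random, 2),
                 ci_lower = round(r$ci_random[1L], 2),
                 ci_upper = round(r$ci_random[2L], 2),
                 p_summary = r$p_summary, i2 = r$i2,
                 heterogeneity = classify_heterogeneity(r),
                 significant = r$p_summary < 0.05,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  stopifnot(identical(names(out), cols))
  attr(out, "footer") <-
    "summary significance at p < 0.05, uncorrected across SNPs"
  out
}
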