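#' Genotype counts for one case-control study
#'
#' Counts of effect-allele homozygotes, heterozygotes and other-allele
#' homozygotes in each arm.
#'
#' @param study_id Study identifier.
#' @param case_counts,control_counts Length-3 nonnegative integer vectors
#'   `(n_EE, n_EO, n_OO)`; each arm total must be positive.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(study_id, case_counts, control_counts) {
  check_triple <- function(x, arm) {
    if (length(x) != 3L || any(is.na(x)) || any(x < 0) || any(x != round(x)))
      stop(arm, " counts must be 3 nonnegative integers (n_EE, n_EO, n_OO)")
    if (sum(x) <= 0) stop(arm, " arm total must be > 0")
    as.integer(x)
  }
  structure(list(study_id = as.character(study_id),
                 case_counts = check_triple(case_counts, "case"),
                 control_counts = check_triple(control_counts, "control")),
            class = "genotype_counts")
}

#' Collapse genotype counts to an allelic 2x2 table
#'
#' Under the allelic model each subject contributes two alleles:
#' `a = 2 n_EE + n_EO` effect alleles and `b = 2 n_OO + n_EO` other alleles
#' in cases, and likewise `c`, `d` in controls.
#'
#' @param g A [genotype_counts()] object.
#' @return An object of class `allele_table` with fields `a`, `b`, `c`, `d`
#'   and `study_id`.
#' @examples
#' g <- genotype_counts("S1", c(10, 20, 70), c(5, 30, 65))
#' alleles_from_genotypes(g)
#' @export
alleles_from_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_counts"))
  ca <- g$case_counts; co <- g$control_counts
  structure(list(study_id = g$study_id,
                 a = 2 * ca[1L] + ca[2L], b = 2 * ca[3L] + ca[2L],
                 c = 2 * co[1L] + co[2L], d = 2 * co[3L] + co[2L]),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("allelic 2x2 table (%s): cases %d/%d, controls %d/%d (effect/other)\n",
              x$study_id, x$a, x$b, x$c, x$d))
  invisible(x)
}

new_effect_estimate <- function(study_id, beta, se, source,
                                continuity_corrected = FALSE,
                                hwe_p = NA_real_, nos_stars = NA_integer_) {
  if (!is.finite(se) || se <= 0) stop("standard error must be finite and > 0")
  data.frame(study_id = as.character(study_id), beta = beta, se = se,
             source = source, continuity_corrected = continuity_corrected,
             hwe_p = hwe_p, nos_stars = as.integer(nos_stars),
             stringsAsFactors = FALSE)
}

#' Log odds ratio from an allelic 2x2 table
#'
#' `OR = (a d) / (b c)`, `beta = ln OR`,
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. If any cell is zero and
#' `correction = "haldane"`, 0.5 is added to all four cells first
#' (Haldane-Anscombe) and the estimate is flagged `continuity_corrected`;
#' tables without zero cells are never altered. With `correction = "strict"`
#' a zero cell is an error.
#'
#' @param t An [alleles_from_genotypes()] table.
#' @param correction `"haldane"` (default) or `"strict"`.
#' @return One-row effect-estimate data frame (`study_id`, `beta`, `se`,
#'   `source = "counts"`, `continuity_corrected`).
#' @export
or_from_table <- function(t, correction = c("haldane", "strict")) {
  correction <- match.arg(correction)
  stopifnot(inherits(t, "allele_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "strict")
      stop("zero cell in allelic table for study ", t$study_id,
           " (use correction = \"haldane\")")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  beta <- log(cells[1L]) + log(cells[4L]) - log(cells[2L]) - log(cells[3L])
  se <- sqrt(sum(1 / cells))
  new_effect_estimate(t$study_id, beta, se, "counts",
                      continuity_corrected = corrected)
}

#' Standard error from a reported odds ratio and lower 95% limit
#'
#' Implements `se = (ln OR - ln lower) / 1.96` for studies that report an
#' adjusted odds ratio with a 95% confidence interval instead of counts.
#' When an upper limit is also given, a symmetry consistency check warns if
#' `|ln upper + ln lower - 2 ln OR| > 0.05` (the interval should be
#' symmetric on the log scale).
#'
#' @param or_value Reported odds ratio (> 0).
#' @param ci_lower Lower 95% confidence limit, `0 < ci_lower < or_value`.
#' @param ci_upper Optional upper limit, used only for the symmetry check.
#' @param study_id Study identifier.
#' @param nos_stars Optional Newcastle-Ottawa quality stars (0-9).
#' @return One-row effect-estimate data frame (`source = "reported_ci"`).
#' @examples
#' se_from_ci(1.5, 1.2)  # se ~ 0.1139
#' @export
se_from_ci <- function(or_value, ci_lower, ci_upper = NA_real_,
                       study_id = "reported", nos_stars = NA_integer_) {
  if (!is.finite(or_value) || or_value <= 0) stop("or_value must be > 0")
  if (!is.finite(ci_lower) || ci_lower <= 0) stop("ci_lower must be > 0")
  if (ci_lower > or_value) stop("ci_lower exceeds the odds ratio")
  if (ci_lower == or_value)
    stop("degenerate confidence interval: ci_lower equals the odds ratio")
  beta <- log(or_value)
  se <- (beta - log(ci_lower)) / 1.96
  if (!is.na(ci_upper)) {
    if (abs(log(ci_upper) + log(ci_lower) - 2 * beta) > 0.05)
      warning("reported CI is asymmetric on the log scale for study ",
              study_id, "; se derived from the lower limit only")
  }
  new_effect_estimate(study_id, beta, se, "reported_ci", nos_stars = nos_stars)
}

#' Hardy-Weinberg equilibrium test on control genotypes
#'
#' Tests deviation from the expected `p^2 : 2pq : q^2` genotype proportions
#' in the control arm. The default is the 1-df chi-square goodness-of-fit
#' test; `method = "exact"` uses full enumeration of heterozygote counts
#' conditional on the observed allele counts, preferable for small samples.
#' Monomorphic controls return `p = 1` with attribute `monomorphic = TRUE`.
#'
#' @param control_counts Length-3 vector `(n_EE, n_EO, n_OO)`.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return The deviation p-value, with attributes `chisq` (for the
#'   chi-square method) and `monomorphic`.
#' @examples
#' hwe_test(c(30, 40, 30))   # chisq = 4, p ~ 0.0455
#' @export
hwe_test <- function(control_counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  x <- control_counts
  if (length(x) != 3L || any(is.na(x)) || any(x < 0))
    stop("control_counts must be 3 nonnegative counts (n_EE, n_EO, n_OO)")
  n <- sum(x)
  if (n <= 0) stop("control arm total must be > 0")
  p_hat <- (2 * x[1L] + x[2L]) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    out <- 1
    attr(out, "monomorphic") <- TRUE
    return(out)
  }
  if (method == "chisq") {
    q_hat <- 1 - p_hat
    expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
    chisq <- sum((x - expected)^2 / expected)
    out <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    attr(out, "chisq") <- chisq
  } else {
    out <- hwe_exact_p(x)
  }
  attr(out, "monomorphic") <- FALSE
  out
}

# Exact HWE test: enumerate heterozygote counts with the observed rare-allele
# total; two-sided p sums configurations no more probable than the observed.
hwe_exact_p <- function(x) {
  n <- sum(x)
  n_rare <- min(2 * x[1L] + x[2L], 2 * x[3L] + x[2L])
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  log_prob <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- x[2L]
  sum(prob[prob <= prob[hets == obs] * (1 + 1e-12)])
}

#' Quality rule for sensitivity gating
#'
#' @param nos_fail_max Newcastle-Ottawa star count at or below which a study
#'   is flagged high risk (default 6; the comparison is inclusive `<=`).
#' @param hwe_alpha Significance level for the control-arm Hardy-Weinberg
#'   deviation flag (default 0.05, strict `<`).
#' @return An object of class `quality_rule`.
#' @export
quality_rule <- function(nos_fail_max = 6L, hwe_alpha = 0.05) {
  stopifnot(nos_fail_max >= 0, nos_fail_max <= 9, hwe_alpha > 0, hwe_alpha < 1)
  structure(list(nos_fail_max = as.integer(nos_fail_max),
                 hwe_alpha = hwe_alpha), class = "quality_rule")
}

#' Attach quality flags to effect estimates
#'
#' Flags `high_risk_nos` (NOS stars `<= nos_fail_max`) and `hwe_deviation`
#' (control-arm HWE p `< hwe_alpha`). Flagged studies are never deleted
#' here; removal happens downstream in the leave-one-out sensitivity
#' analysis.
#'
#' @param estimates Effect-estimate data frame (rows from
#'   [or_from_table()] / [se_from_ci()], possibly with `hwe_p` and
#'   `nos_stars` filled in).
#' @param rule A [quality_rule()].
#' @return `estimates` with logical columns `high_risk_nos` and
#'   `hwe_deviation` added (FALSE when the underlying value is missing).
#' @export
quality_gate <- function(estimates, rule = quality_rule()) {
  stopifnot(inherits(rule, "quality_rule"))
  nos <- if ("nos_stars" %in% names(estimates)) estimates$nos_stars
         else rep(NA_integer_, nrow(estimates))
  hwe <- if ("hwe_p" %in% names(estimates)) estimates$hwe_p
         else rep(NA_real_, nrow(estimates))
  estimates$high_risk_nos <- !is.na(nos) & nos <= rule$nos_fail_max
  estimates$hwe_deviation <- !is.na(hwe) & hwe < rule$hwe_alpha
  estimates
}

#' Read per-study genotype counts
#'
#' Expects a CSV with columns `study_id`, `snp`, `arm` (`case`/`control`),
#' `n_EE`, `n_EO`, `n_OO`; each study/SNP needs one row per arm.
#'
#' @param path CSV path.
#' @return Named list (by `snp`) of lists of [genotype_counts()] objects.
#' @export
read_genotype_counts <- function(path) {
  if (!file.exists(path)) stop("genotype counts file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "snp", "arm", "n_EE", "n_EO", "n_OO")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop("genotype counts file lacks column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (snp in unique(raw$snp)) {
    sub <- raw[raw$snp == snp, , drop = FALSE]
    per_study <- lapply(unique(sub$study_id), function(sid) {
      rows <- sub[sub$study_id == sid, , drop = FALSE]
      ca <- rows[rows$arm == "case", c("n_EE", "n_EO", "n_OO")]
      co <- rows[rows$arm == "control", c("n_EE", "n_EO", "n_OO")]
      if (nrow(ca) != 1L || nrow(co) != 1L)
        stop("study ", sid, " / ", snp,
             " must have exactly one case and one control row")
      genotype_counts(sid, as.numeric(ca), as.numeric(co))
    })
    out[[snp]] <- per_study
  }
  out
}

#' Read reported per-study effects
#'
#' Expects a CSV with columns `study_id`, `snp`, `or`, `ci_lower` and
#' optionally `ci_upper`, `nos_stars`, `cohort_group`, `n_total`, `year`.
#'
#' @param path CSV path.
#' @return Data frame of reported effects.
#' @export
read_reported_effects <- function(path) {
  if (!file.exists(path)) stop("reported effects file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "snp", "or", "ci_lower")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop("reported effects file lacks column(s): ", paste(missing, collapse = ", "))
  for (opt in c("ci_upper", "nos_stars", "cohort_group", "n_total", "year"))
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  raw
}

#' Assemble one effect estimate per study per SNP
#'
#' Combines counts-based and reported-CI inputs into a per-SNP table of
#' effect estimates, enforcing one record per study per SNP:
#' * when both a counts record and a reported (adjusted) record exist for
#'   the same study and SNP, the reported one is preferred;
#' * studies sharing a declared `cohort_group` are duplicates of one
#'   cohort; only the largest (`n_total`), breaking ties by most recent
#'   `year`, is kept.
#'
#' Counts-based estimates carry the control-arm HWE p-value; quality flags
#' are attached via [quality_gate()].
#'
#' @param counts Named list from [read_genotype_counts()] (may be `NULL`).
#' @param reported Data frame from [read_reported_effects()] (may be `NULL`).
#' @param rule A [quality_rule()].
#' @param correction Continuity policy passed to [or_from_table()].
#' @return Named list (by SNP) of effect-estimate data frames.
#' @export
effect_estimates <- function(counts = NULL, reported = NULL,
                             rule = quality_rule(),
                             correction = "haldane") {
  snps <- union(names(counts),
                if (is.null(reported)) character(0) else unique(reported$snp))
  out <- list()
  for (snp in snps) {
    rows <- list()
    rep_sub <- if (is.null(reported)) NULL
               else reported[reported$snp == snp, , drop = FALSE]
    reported_ids <- if (is.null(rep_sub)) character(0) else rep_sub$study_id
    for (g in counts[[snp]]) {
      if (g$study_id %in% reported_ids) next  # adjusted estimate preferred
      e <- or_from_table(alleles_from_genotypes(g), correction = correction)
      e$hwe_p <- as.numeric(hwe_test(g$control_counts))
      rows[[length(rows) + 1L]] <- e
    }
    if (!is.null(rep_sub) && nrow(rep_sub) > 0L) {
      for (i in seq_len(nrow(rep_sub))) {
        r <- rep_sub[i, ]
        rows[[length(rows) + 1L]] <-
          se_from_ci(r$or, r$ci_lower, ci_upper = r$ci_upper,
                     study_id = r$study_id, nos_stars = r$nos_stars)
      }
    }
    est <- do.call(rbind, rows)
    if (!is.null(rep_sub) && any(!is.na(rep_sub$cohort_group))) {
      est <- resolve_duplicate_cohorts(est, rep_sub)
    }
    if (anyDuplicated(est$study_id))
      stop("multiple records for one study at ", snp, ": ",
           paste(est$study_id[duplicated(est$study_id)], collapse = ", "))
    out[[snp]] <- quality_gate(est, rule)
  }
  out
}

# keep, within each declared cohort group, the largest then most recent record
resolve_duplicate_cohorts <- function(est, rep_sub) {
  meta <- rep_sub[!is.na(rep_sub$cohort_group),
                  c("study_id", "cohort_group", "n_total", "year")]
  drop <- character(0)
  for (grp in unique(meta$cohort_group)) {
    ids <- meta$study_id[meta$cohort_group == grp]
    if (length(ids) < 2L) next
    sub <- meta[meta$cohort_group == grp, , drop = FALSE]
    ord <- order(-replace(sub$n_total, is.na(sub$n_total), -Inf),
                 -replace(sub$year, is.na(sub$year), -Inf))
    drop <- c(drop, sub$study_id[ord][-1L])
  }
  est[!(est$study_id %in% drop), , drop = FALSE]
}
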