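test_that("genotype counts collapse to allele counts under the allelic model", {
  t1 <- alleles_from_genotypes(genotype_counts("S", c(10, 20, 70), c(25, 50, 25)))
  expect_equal(c(t1$a, t1$b), c(40, 160))
  expect_equal(c(t1$c, t1$d), c(100, 100))   # frequency 0.5 in controls
  t2 <- alleles_from_genotypes(genotype_counts("S", c(0, 0, 50), c(1, 1, 1)))
  expect_equal(c(t2$a, t2$b), c(0, 100))     # monomorphic cases
  expect_error(genotype_counts("S", c(0, 0, 0), c(1, 1, 1)), "total")
  expect_error(genotype_counts("S", c(-1, 0, 5), c(1, 1, 1)), "nonnegative")
})

test_that("allele collapsing conserves chromosome counts", {
  set.seed(21)
  for (rep in 1:50) {
    ca <- rmultinom(1, sample(50:500, 1), c(0.2, 0.5, 0.3))[, 1]
    co <- rmultinom(1, sample(50:500, 1), c(0.1, 0.4, 0.5))[, 1]
    t <- alleles_from_genotypes(genotype_counts("S", ca, co))
    expect_equal(t$a + t$b, 2 * sum(ca))
    expect_equal(t$c + t$d, 2 * sum(co))
  }
})

mk_table <- function(a, b, c, d) {
  structure(list(study_id = "S", a = a, b = b, c = c, d = d),
            class = "allele_table")
}

test_that("odds ratios from 2x2 tables match hand arithmetic", {
  null <- or_from_table(mk_table(10, 10, 10, 10))
  expect_equal(null$beta, 0)
  expect_equal(null$se, sqrt(0.4))

  e <- or_from_table(mk_table(40, 160, 20, 180))
  expect_equal(e$beta, log(2.25))
  expect_equal(e$se, sqrt(1/40 + 1/160 + 1/20 + 1/180))
  expect_false(e$continuity_corrected)
})

test_that("Haldane correction applies only to zero-cell tables", {
  e <- or_from_table(mk_table(0, 100, 10, 90), correction = "haldane")
  expect_true(e$continuity_corrected)
  expect_equal(exp(e$beta), (0.5 * 90.5) / (100.5 * 10.5))
  expect_equal(e$se, sqrt(1/0.5 + 1/100.5 + 1/10.5 + 1/90.5))
  expect_error(or_from_table(mk_table(0, 100, 10, 90), correction = "strict"),
               "zero cell")
})

test_that("swapping effect and other alleles negates beta, preserving se", {
  set.seed(31)
  for (rep in 1:25) {
    x <- sample(1:200, 4)
    e1 <- or_from_table(mk_table(x[1], x[2], x[3], x[4]))
    e2 <- or_from_table(mk_table(x[2], x[1], x[4], x[3]))
    expect_equal(e2$beta, -e1$beta)
    expect_equal(e2$se, e1$se)
  }
})

test_that("standard errors from reported CIs follow the lower-limit formula", {
  e <- se_from_ci(1.5, 1.2)
  expect_equal(e$se, (log(1.5) - log(1.2)) / 1.96)
  expect_equal(e$se, 0.11385, tolerance = 1e-4)
  expect_equal(e$source, "reported_ci")

  inv <- se_from_ci(1.0, exp(-1.96 * 0.1))
  expect_equal(inv$se, 0.1)

  expect_error(se_from_ci(2, 2), "degenerate")
  expect_error(se_from_ci(2, 2.5), "exceeds")
  expect_error(se_from_ci(2, -1), "ci_lower")
})

test_that("reconstructing the lower limit inverts se_from_ci to 1e-12", {
  set.seed(41)
  or_v <- exp(runif(1000, -1.5, 1.5))
  lo <- or_v * exp(-runif(1000, 0.01, 1))
  for (i in seq_len(1000)) {
    e <- se_from_ci(or_v[i], lo[i])
    rec <- exp(e$beta - 1.96 * e$se)
    expect_lt(abs(rec - lo[i]) / lo[i], 1e-12)
  }
})

test_that("an asymmetric reported CI triggers the consistency warning", {
  expect_warning(se_from_ci(1.5, 1.2, ci_upper = 2.5), "asymmetric")
  expect_silent(se_from_ci(1.5, 1.2, ci_upper = 1.5^2 / 1.2))
})

test_that("the HWE chi-square matches hand computation and conventions", {
  perfect <- hwe_test(c(81, 18, 1))
  expect_equal(as.numeric(perfect), 1)
  expect_equal(attr(perfect, "chisq"), 0)
  expect_equal(as.numeric(hwe_test(c(25, 50, 25))), 1)

  dev <- hwe_test(c(30, 40, 30))
  expect_equal(attr(dev, "chisq"), 4)
  expect_equal(as.numeric(dev), pchisq(4, 1, lower.tail = FALSE))

  mono <- hwe_test(c(50, 0, 0))
  expect_equal(as.numeric(mono), 1)
  expect_true(attr(mono, "monomorphic"))
})

test_that("the exact HWE test matches an independent enumeration oracle", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(100:800, 1)
    p <- runif(1, 0.05, 0.5)
    counts <- rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))[, 1]
    if (min(2 * counts[1] + counts[2], 2 * counts[3] + counts[2]) == 0) next
    expect_equal(as.numeric(hwe_test(counts, method = "exact")),
                 hwe_enum_reference(counts), tolerance = 1e-10)
  }
})

test_that("chi-square and exact HWE tests agree where the gate operates", {
  # The two tests order outcomes differently mid-range (the conservative
  # exact p can exceed the chi-square p by > 0.1 near the HWE mode even at
  # large n), but they coincide in the deviation tail that drives the
  # sensitivity gate: close p-values below 0.1 and matching alpha = 0.05
  # decisions.
  set.seed(52)
  checked <- 0L
  for (rep in 1:150) {
    n <- sample(500:2000, 1)
    p <- runif(1, 0.1, 0.5)
    f <- runif(1, 0, 0.12)                  # mild inbreeding-style distortion
    pr <- c(p^2 + f * p * (1 - p), 2 * p * (1 - p) * (1 - f),
            (1 - p)^2 + f * p * (1 - p))
    counts <- rmultinom(1, n, pr)[, 1]
    if (min(2 * counts[1] + counts[2], 2 * counts[3] + counts[2]) == 0) next
    chisq_p <- as.numeric(hwe_test(counts))
    exact_p <- as.numeric(hwe_test(counts, method = "exact"))
    if ((chisq_p < 0.05) != (exact_p < 0.05)) {
      # disagreements only happen right at the alpha boundary
      expect_true(all(abs(c(chisq_p, exact_p) - 0.05) < 0.01))
    }
    if (min(chisq_p, exact_p) < 0.1) {
      expect_lt(abs(chisq_p - exact_p), 0.02)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)                   # the tail regime was exercised
})

test_that("quality gating flags but never deletes", {
  est <- rbind(se_from_ci(1.5, 1.2, study_id = "A", nos_stars = 6),
               se_from_ci(1.4, 1.1, study_id = "B", nos_stars = 7),
               se_from_ci(1.3, 1.0, study_id = "C", nos_stars = 9))
  est$hwe_p <- c(0.5, 0.049, NA)
  gated <- quality_gate(est, quality_rule())
  expect_equal(nrow(gated), 3L)
  expect_equal(gated$high_risk_nos, c(TRUE, FALSE, FALSE))  # <= 6 inclusive
  expect_equal(gated$hwe_deviation, c(FALSE, TRUE, FALSE))  # < 0.05 strict
})

test_that("the loader prefers adjusted reported estimates over raw counts", {
  counts_csv <- tempfile(fileext = ".csv")
  writeLines(c("study_id,snp,arm,n_EE,n_EO,n_OO",
               "A,rs1,case,30,80,90",
               "A,rs1,control,20,70,110",
               "B,rs1,case,25,90,85",
               "B,rs1,control,18,72,110"), counts_csv)
  reported_csv <- tempfile(fileext = ".csv")
  writeLines(c("study_id,snp,or,ci_lower,ci_upper,nos_stars",
               "A,rs1,1.45,1.10,1.91,7",
               "C,rs1,1.20,0.95,1.52,8"), reported_csv)
  est <- effect_estimates(read_genotype_counts(counts_csv),
                          read_reported_effects(reported_csv))$rs1
  expect_setequal(est$study_id, c("A", "B", "C"))
  expect_equal(est$source[est$study_id == "A"], "reported_ci")
  expect_equal(est$source[est$study_id == "B"], "counts")
  expect_false(is.na(est$hwe_p[est$study_id == "B"]))
})

test_that("duplicate cohorts keep the larger, more recent record", {
  reported_csv <- tempfile(fileext = ".csv")
  writeLines(c("study_id,snp,or,ci_lower,ci_upper,nos_stars,cohort_group,n_total,year",
               "Old,rs1,1.5,1.2,1.88,7,grpA,500,2010",
               "New,rs1,1.4,1.15,1.70,8,grpA,900,2018",
               "Other,rs1,1.3,1.05,1.61,8,,600,2015"), reported_csv)
  est <- effect_estimates(reported = read_reported_effects(reported_csv))$rs1
  expect_setequal(est$study_id, c("New", "Other"))
})
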