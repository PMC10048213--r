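est_df <- function(beta, se, id = sprintf("S%d", seq_along(beta))) {
  data.frame(study_id = id, beta = beta, se = se, stringsAsFactors = FALSE)
}

test_that("fixed-effect pooling matches hand arithmetic", {
  fe1 <- fixed_effect(est_df(c(0.3, 0.3), c(0.1, 0.1)))
  expect_equal(fe1$beta_fixed, 0.3)
  expect_equal(fe1$se_fixed, 0.1 / sqrt(2))
  expect_equal(fe1$q_stat, 0)

  fe2 <- fixed_effect(est_df(c(0, 0.4), c(0.1, 0.1)))
  expect_equal(fe2$beta_fixed, 0.2)
  expect_equal(fe2$q_stat, 8)

  expect_error(fixed_effect(est_df(0.2, 0.1)), "at least 2")
})

test_that("the moment estimator reproduces the hand-worked example", {
  r <- dersimonian_laird(est_df(c(0, 0.4), c(0.1, 0.1)))
  expect_equal(r$q_stat, 8)
  expect_equal(r$tau2, 7 / 100)            # (8-1)/(200 - 100)
  expect_equal(r$beta_random, 0.2)
  expect_equal(r$i2, 87.5)
  expect_equal(r$ci_random,
               exp(0.2 + c(-1.96, 1.96) / sqrt(2 / (0.01 + 0.07))))
})

test_that("identical studies give zero heterogeneity and random = fixed", {
  r <- dersimonian_laird(est_df(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1)))
  expect_identical(r$tau2, 0)
  expect_identical(r$i2, 0)
  expect_identical(r$beta_random, r$beta_fixed)
  expect_identical(r$se_random, r$se_fixed)
})

test_that("Q below its degrees of freedom truncates tau2 to zero", {
  r <- dersimonian_laird(est_df(c(0.1, 0.11), c(0.2, 0.2)))
  expect_lt(r$q_stat, 1)
  expect_identical(r$tau2, 0)
  expect_identical(r$beta_random, r$beta_fixed)
  expect_identical(r$se_random, r$se_fixed)
})

test_that("pooled results match the loop-coded reference to 1e-8", {
  set.seed(61)
  for (rep in 1:100) {
    k <- sample(2:10, 1)
    est <- random_estimates(k)
    got <- dersimonian_laird(est)
    want <- dl_reference(est$beta, est$se)
    expect_equal(got$beta_random, want$beta_random, tolerance = 1e-8)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-8)
    expect_equal(got$i2, want$i2, tolerance = 1e-8)
    expect_equal(got$ci_random, want$ci, tolerance = 1e-8)
  }
})

test_that("pooled results agree with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(71)
  for (rep in 1:20) {
    est <- random_estimates(sample(3:8, 1))
    got <- dersimonian_laird(est)
    ref <- metafor::rma(yi = est$beta, sei = est$se, method = "DL")
    expect_equal(got$beta_random, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(got$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(got$i2, ref$I2, tolerance = 1e-6)
    expect_equal(got$q_stat, ref$QE, tolerance = 1e-8)
  }
})

test_that("the pooled estimate is a convex combination of study effects", {
  set.seed(81)
  for (rep in 1:50) {
    est <- random_estimates(sample(2:10, 1))
    r <- dersimonian_laird(est)
    expect_gte(r$beta_random, min(est$beta))
    expect_lte(r$beta_random, max(est$beta))
  }
})

test_that("I2 is invariant to rescaling effects and errors together", {
  set.seed(91)
  est <- random_estimates(6)
  r1 <- dersimonian_laird(est)
  est2 <- est; est2$beta <- est2$beta * 3.7; est2$se <- est2$se * 3.7
  r2 <- dersimonian_laird(est2)
  expect_equal(r2$i2, r1$i2, tolerance = 1e-10)
  expect_equal(r2$q_stat, r1$q_stat, tolerance = 1e-10)
})

test_that("heterogeneity classification is strict at 50%", {
  expect_equal(classify_heterogeneity(0), "low")
  expect_equal(classify_heterogeneity(49.999), "low")
  expect_equal(classify_heterogeneity(50), "high")
  expect_equal(classify_heterogeneity(87.5), "high")
})

test_that("leave-one-out flags exactly the study that drives significance", {
  # two equivocal studies plus one precise strong study carrying the signal
  est <- est_df(c(0.15, 0.12, 0.30), c(0.20, 0.22, 0.07),
                id = c("S_small1", "S_small2", "S_driver"))
  parent <- dersimonian_laird(est)
  expect_lt(parent$p_summary, 0.05)
  sens <- leave_one_out(est)
  expect_length(sens, 3L)
  flips <- vapply(sens, `[[`, logical(1), "significance_flipped")
  omitted <- vapply(sens, `[[`, character(1), "omitted_study_id")
  expect_equal(omitted[flips], "S_driver")
  expect_equal(sum(flips), 1L)
})

test_that("leave-one-out of identical studies never flips", {
  sens <- leave_one_out(est_df(c(0.3, 0.3, 0.3), c(0.05, 0.05, 0.05)))
  expect_length(sens, 3L)
  expect_false(any(vapply(sens, `[[`, logical(1), "significance_flipped")))
  for (s in sens) expect_equal(s$result_without$k, 2L)
})

test_that("k = 2 yields no sensitivity results, with a warning", {
  expect_warning(out <- leave_one_out(est_df(c(0.1, 0.2), c(0.1, 0.1))),
                 "single")
  expect_length(out, 0L)
})

test_that("restricted sensitivity omits only flagged studies", {
  est <- est_df(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1))
  est$nos_stars <- c(5L, 8L, 9L)
  est$hwe_p <- c(0.8, 0.01, 0.9)
  gated <- quality_gate(est, quality_rule())
  sens <- leave_one_out(gated, restrict_to_flagged = TRUE)
  expect_setequal(vapply(sens, `[[`, character(1), "omitted_study_id"),
                  c("S1", "S2"))
  clean <- quality_gate(est_df(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1)),
                        quality_rule())
  expect_length(leave_one_out(clean, restrict_to_flagged = TRUE), 0L)
})

test_that("funnel data centre on the pooled effect for symmetric inputs", {
  beta <- 0.3 + c(-0.2, -0.1, 0, 0.1, 0.2)
  est <- est_df(beta, rep(0.1, 5))
  r <- dersimonian_laird(est)
  fd <- funnel_data(est, r)
  expect_equal(nrow(fd$points), 5L)
  expect_true(all(fd$points$se > 0))
  expect_equal(mean(fd$points$beta - r$beta_random), 0, tolerance = 1e-12)
  expect_equal(fd$guides$upper - fd$guides$lower, 2 * 1.96 * fd$guides$se)
})

test_that("the summary table applies the 0.05 significance rule strictly", {
  r_sig <- dersimonian_laird(est_df(c(0.4, 0.45, 0.42), c(0.05, 0.06, 0.05)))
  expect_lt(r_sig$p_summary, 0.05)
  r_null <- dersimonian_laird(est_df(c(0.01, -0.01), c(0.2, 0.2)))
  tab <- meta_table(list(rsA = r_sig, rsB = r_null))
  expect_equal(tab$significant, c(TRUE, FALSE))
  expect_equal(tab$heterogeneity, c("low", "low"))
  expect_equal(tab$or, round(c(r_sig$or_random, r_null$or_random), 2))
  # boundary: p exactly 0.05 is not significant
  fake <- r_null; fake$p_summary <- 0.05
  expect_false(meta_table(list(x = fake))$significant)
  empty <- meta_table(list())
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 9L)
})
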