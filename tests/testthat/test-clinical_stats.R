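# Exact binomial intervals, association test, and the packaged trial tables.

test_that("Clopper-Pearson bounds match tail inversion and boundary rules", {
  expect_equal(round(clopper_pearson_ci(13, 50), 1), c(14.6, 40.3),
               ignore_attr = TRUE)
  expect_equal(clopper_pearson_ci(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson_ci(10, 10)[["upper"]], 100)
  set.seed(2)
  for (r in 1:25) {
    n <- sample(1:60, 1); x <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson_ci(x, n)), cp_oracle(x, n),
                 tolerance = 1e-7)
  }
  expect_error(clopper_pearson_ci(5, 4), "x")
})

test_that("interval bounds are monotone in x and conservatively cover", {
  n <- 50
  ci <- t(vapply(0:n, clopper_pearson_ci, numeric(2), n = n))
  expect_true(all(diff(ci[, 1]) > 0))
  expect_true(all(diff(ci[, 2]) > 0))
  set.seed(3)
  draws <- rbinom(2000, 50, 0.25)
  cover <- vapply(draws, function(x) {
    ci <- clopper_pearson_ci(x, 50) / 100
    ci[1] <= 0.25 && 0.25 <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.95)
})

test_that("the 2x2 chi-square matches hand expansion and handles edge cases", {
  tab <- matrix(c(3, 5, 10, 27), 2)
  res <- chi2_2x2(tab)
  # hand expansion: E_11 = 13 * 8 / 45 etc.
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(res$p.value, 2), 0.55)
  eq <- matrix(c(4, 8, 6, 12), 2)
  res_eq <- chi2_2x2(eq)
  expect_equal(res_eq$statistic, 0)
  expect_equal(res_eq$p.value, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  # Fisher mode defers to the exact test
  expect_equal(chi2_2x2(tab, fisher = TRUE)$p.value,
               fisher.test(tab)$p.value)
})

test_that("packaged response table reproduces every printed rate and CI", {
  rr <- response_rates()
  get <- function(stat, tp) rr[rr$statistic == stat & rr$timepoint == tp, ]
  orr12 <- get("ORR", "wk12")
  expect_equal(orr12$x, 2)
  expect_equal(round(orr12$ci_lower_pct, 2), 0.47)
  expect_equal(round(orr12$ci_upper_pct, 2), 13.21)
  orr28 <- get("ORR", "wk28")
  expect_equal(orr28$x, 3)
  expect_equal(round(orr28$ci_lower_pct, 2), 1.21)
  expect_equal(round(orr28$ci_upper_pct, 2), 15.95)
  cbr12 <- get("CBR", "wk12")
  expect_equal(cbr12$x / cbr12$n, 21 / 52)
  expect_equal(round(cbr12$rate_pct, 1), 40.4)
  expect_equal(round(cbr12$ci_lower_pct, 1), 27.0)
  expect_equal(round(cbr12$ci_upper_pct, 1), 54.9)
  cbr28 <- get("CBR", "wk28")
  expect_equal(c(cbr28$x, cbr28$n), c(13, 50))
  expect_equal(round(cbr28$rate_pct, 0), 26)
  expect_equal(round(cbr28$ci_lower_pct, 1), 14.6)
  expect_equal(round(cbr28$ci_upper_pct, 1), 40.3)
  itt <- get("CBR_ITT", "wk28")
  expect_equal(c(itt$x, itt$n), c(13, 52))
  expect_equal(round(itt$ci_lower_pct, 1), 14.0)
  expect_equal(round(itt$ci_upper_pct, 1), 38.9)
})

test_that("RPED summaries use the earliest-onset eye per subject", {
  s <- rped_summary()
  expect_equal(s$time_to_diagnosis$median, 1.0)
  expect_equal(s$time_to_diagnosis$range, c(0.8, 6.7))
  expect_equal(s$duration$median, 0.7)
  expect_equal(s$duration$range, c(0.4, 2.1))
  one <- data.frame(subject = "A", time_to_diagnosis_months = 2.0,
                    duration_months = 0.5)
  s1 <- rped_summary(one)
  expect_equal(s1$time_to_diagnosis$median, 2.0)
  expect_equal(s1$time_to_diagnosis$range, c(2.0, 2.0))
  expect_equal(s1$duration$median, 0.5)
})

test_that("RPED-benefit cross-tabulation and association reproduce print", {
  tab <- rped_benefit_table()
  expect_equal(unname(tab), matrix(c(3, 5, 10, 27), 2))
  expect_equal(round(chi2_2x2(tab)$p.value, 2), 0.55)
  expect_error(rped_benefit_table(data.frame(subject = "x", benefit = "huh",
                                             rped = TRUE)), "unknown")
  expect_error(rped_benefit_table(data.frame(subject = character(0),
                                             benefit = character(0),
                                             rped = logical(0))), "empty")
  # all-benefit input drives the downstream test into its zero-margin guard
  allb <- data.frame(subject = c("a", "b"), benefit = "benefit",
                     rped = c(TRUE, FALSE))
  expect_error(chi2_2x2(rped_benefit_table(allb)), "margin")
})

test_that("the full clinical report assembles all statistics", {
  rep <- clinical_report()
  expect_s3_class(rep$rates, "data.frame")
  expect_equal(round(rep$rped_association$p.value, 2), 0.55)
  expect_equal(rep$rped_events$duration$median, 0.7)
})
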