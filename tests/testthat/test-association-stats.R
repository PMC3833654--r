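test_that("quintile bounds and assignment follow rank interpolation", {
  q <- assign_quintiles(1:10)
  expect_equal(q$bounds, c(2.8, 4.6, 6.4, 8.2))
  expect_equal(q$quintile[3], 2L)
  expect_equal(q$quintile, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_equal(sort(unique(q$quintile)), 1:5)
})

test_that("degenerate and overridden quintile grids are handled explicitly", {
  expect_error(assign_quintiles(rep(3, 50)), "ties")
  expect_error(assign_quintiles(1:4), "at least 5")
  # externally published bounds accepted verbatim
  q <- assign_quintiles(c(0.5, 1.2, 2.0, 3.0, 5.0),
                        bounds = c(0.94, 1.59, 2.31, 3.44))
  expect_equal(q$bounds, c(0.94, 1.59, 2.31, 3.44))
  expect_equal(q$quintile, c(1L, 2L, 3L, 4L, 5L))
})

test_that("quintile assignment partitions with near-equal group sizes", {
  set.seed(10)
  x <- rlnorm(1000, 0.5, 0.6)
  q <- assign_quintiles(x)
  expect_equal(sum(table(q$quintile)), 1000)
  expect_true(all(abs(table(q$quintile) - 200) <= 1))
})

test_that("crude odds ratio and Woolf interval match the closed form", {
  res <- crude_or(10, 90, 2, 98)
  expect_equal(res$or, (10 * 98) / (90 * 2))
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 2 + 1 / 98)
  expect_equal(res$ci_low, exp(log(res$or) - 1.96 * se))
  expect_equal(res$ci_high, exp(log(res$or) + 1.96 * se))
  expect_false(res$corrected)

  expect_equal(crude_or(5, 5, 5, 5)$or, 1)

  zero <- crude_or(4, 0, 3, 7)
  expect_true(zero$corrected)
  expect_equal(zero$or, (4.5 * 7.5) / (0.5 * 3.5))
})

test_that("unadjusted logistic quintile ORs reproduce the 2x2 closed form", {
  set.seed(73)
  for (rep in 1:5) {
    n <- 200
    quintile <- sample(1:5, n, replace = TRUE)
    outcome <- runif(n) < plogis(-2 + 0.5 * quintile)
    if (sum(outcome[quintile == 1]) %in% c(0, sum(quintile == 1))) next
    fit <- fit_logistic_or(outcome, quintile)
    for (k in 2:5) {
      a <- sum(outcome & quintile == k); b <- sum(!outcome & quintile == k)
      c_ <- sum(outcome & quintile == 1); d <- sum(!outcome & quintile == 1)
      if (min(a, b, c_, d) == 0) next
      expect_equal(fit$or[fit$quintile == k], (a * d) / (b * c_),
                   tolerance = 1e-6)
    }
  }
})

test_that("null outcomes give quintile CIs that cover 1", {
  set.seed(99)
  hits <- sapply(1:10, function(r) {
    n <- 1500
    quintile <- sample(1:5, n, replace = TRUE)
    outcome <- runif(n) < 0.25
    covars <- data.frame(age = runif(n, 6, 18),
                         sex = sample(c("M", "F"), n, TRUE),
                         tanner = sample(1:5, n, TRUE))
    fit <- fit_logistic_or(outcome, quintile, covars)
    rows <- fit[fit$quintile > 1, ]
    all(rows$ci_low <= 1 & rows$ci_high >= 1)
  })
  expect_gte(mean(hits), 0.7)
})

test_that("separation is flagged with unbounded intervals, not a crash", {
  quintile <- rep(1:5, each = 20)
  outcome <- quintile == 5  # quintile 5 perfectly predicts the outcome
  fit <- fit_logistic_or(outcome, quintile)
  expect_equal(fit$n, rep(20L, 5))
  expect_equal(fit$n_cases[fit$quintile == 1], 0)
  expect_true(any(fit$flagged))
  expect_true(all(is.infinite(fit$ci_high[fit$flagged & fit$quintile > 1])))
})

test_that("chi-squared statistic matches hand-computed expected counts", {
  flat <- chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  t2 <- rbind(c(20, 10), c(10, 20))
  res <- chi_square(t2)
  expect_equal(res$statistic, 4 * 25 / 15)  # E = 15 in every cell
  expect_equal(res$df, 1)
  expect_equal(chi_square(t(t2))$statistic, res$statistic)

  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi_square(matrix(1:3, 1)), "2x2")
})

test_that("prevalence-of-IR table counts strict exceedances by group", {
  co <- make_cohort(
    make_subject("A", insulin = 10, glucose = 4.5),  # HOMA 2.0
    make_subject("B", insulin = 10, glucose = 4.5),
    make_subject("C", insulin = 20, glucose = 4.5)   # HOMA 4.0
  )
  profiles <- tibble::tibble(
    id = co$id, central_obesity = c(TRUE, TRUE, TRUE),
    high_bp = FALSE, high_tg = FALSE, low_hdl = FALSE, ifg = FALSE,
    count = 1L, ms = FALSE
  )
  weight <- tibble::tibble(id = co$id,
                           category = factor(c("normal", "overweight",
                                               "obese"),
                                             levels = c("underweight",
                                                        "normal",
                                                        "overweight",
                                                        "obese")))
  out <- prevalence_of_ir(co, profiles, weight,
                          c(low = 1.0, mid = 3.0))
  prev <- out$prevalence
  g <- function(grp, lab) prev$prevalence_pct[prev$group == grp &
                                                prev$cutoff_label == lab]
  expect_equal(g("central obesity", "low"), 100)   # cutoff below all
  expect_equal(g("central obesity", "mid"), 100 / 3)
  expect_equal(g("obese", "mid"), 100)
  expect_equal(g("normal weight", "mid"), 0)
  # empty group flagged NA, not zero
  expect_true(is.na(g("MS", "mid")))
  expect_equal(prev$n[prev$group == "MS"][1], 0L)
})

test_that("IR prevalence is higher in obese than normal-weight synthetic children", {
  co <- generate_cohort(cohort_config(seed = 55, n_subjects = 3000))
  pr <- classify_components(co, derive_component_thresholds(co))
  wt <- classify_weight_status(co, build_growth_reference(co))
  out <- prevalence_of_ir(co, pr, wt, c("p95-like" = 3.0))
  prev <- out$prevalence
  expect_gt(prev$prevalence_pct[prev$group == "obese"],
            prev$prevalence_pct[prev$group == "normal weight"])
  expect_lt(out$weight_status_chi_sq$p[1], 0.001)
})
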