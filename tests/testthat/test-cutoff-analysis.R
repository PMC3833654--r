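test_that("perfectly separated scores give AUC 1 and a perfect cut-off", {
  roc <- build_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc$auc, 1.0)
  best <- optimal_cutoff(roc, "youden")
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 1)
  expect_equal(best$youden, 1)
  expect_equal(best$distance_sq, 0)
})

test_that("identical scores carry no discrimination: AUC 0.5", {
  roc <- build_roc(rep(2.2, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(roc$auc, 0.5)
})

test_that("degenerate labels are rejected", {
  expect_error(build_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC curves satisfy the monotone operating-point invariants", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    scores <- round(rlnorm(n, 0.5, 0.6), 1)  # rounding forces ties
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    roc <- build_roc(scores, labels)
    expect_true(all(diff(roc$points$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$points$specificity) >= -1e-12))
    expect_equal(roc$points$sensitivity[1], 1)
    expect_equal(roc$points$specificity[1], 0)
    expect_equal(roc$points$sensitivity[nrow(roc$points)], 0)
    expect_equal(roc$points$specificity[nrow(roc$points)], 1)
    expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
  }
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    scores <- sample(seq(0.5, 5, by = 0.5), n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    roc <- build_roc(scores, labels)
    expect_equal(roc$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rlnorm(80, 0.6, 0.5)
  labels <- runif(80) < plogis(2 * (log(scores) - 0.6))
  roc <- build_roc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("optimal cut-offs match an exhaustive scan, ties included", {
  set.seed(27)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    scores <- sample(seq(1, 4, by = 0.25), n, replace = TRUE)
    labels <- runif(n) < 0.45
    if (length(unique(labels)) < 2) next
    roc <- build_roc(scores, labels)
    for (method in c("youden", "distance")) {
      got <- optimal_cutoff(roc, method)
      want <- oracle_best_cutoff(scores, labels, method)
      expect_equal(got$cutoff, want$cutoff)
      expect_equal(got$youden, want$youden, tolerance = 1e-12)
      expect_equal(got$distance_sq, want$dist, tolerance = 1e-12)
    }
  }
})

test_that("the Youden identity holds at every operating point", {
  set.seed(5)
  scores <- rlnorm(60, 0.5, 0.5)
  labels <- runif(60) < 0.4
  roc <- build_roc(scores, labels)
  for (method in c("youden", "distance")) {
    best <- optimal_cutoff(roc, method)
    expect_equal(best$youden, best$sensitivity + best$specificity - 1)
    expect_equal(best$distance_sq,
                 (1 - best$sensitivity)^2 + (1 - best$specificity)^2)
  }
  oc <- operating_characteristics(roc, c(0.5, 1.5, 2.5))
  expect_equal(oc$youden, oc$sensitivity + oc$specificity - 1)
  expect_equal(oc$distance_sq,
               (1 - oc$sensitivity)^2 + (1 - oc$specificity)^2)
})

test_that("operating characteristics recount correctly at any cut-off", {
  scores <- c(0.8, 1.1, 1.9, 2.4, 3.0, 3.6)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  roc <- build_roc(scores, labels)
  expect_equal(unlist(operating_characteristics(roc, 0.1)[, 2:3]),
               c(sensitivity = 1, specificity = 0))
  expect_equal(unlist(operating_characteristics(roc, 10)[, 2:3]),
               c(sensitivity = 0, specificity = 1))
  # at 2.4 (an observed candidate): positives above are 3.0, 3.6 -> 2/3;
  # negatives at or below are 0.8, 1.1, 2.4 -> 3/3
  at <- operating_characteristics(roc, 2.4)
  expect_equal(at$sensitivity, 2 / 3)
  expect_equal(at$specificity, 1)
  pt <- roc$points[roc$points$cutoff == 2.4, ]
  expect_equal(at$sensitivity, pt$sensitivity)
  expect_equal(at$specificity, pt$specificity)
  # off-grid cut-off between candidates behaves like the one below it
  expect_equal(operating_characteristics(roc, 2.7)$sensitivity, 2 / 3)
})

test_that("the inclusive-call variant flips boundary subjects", {
  scores <- c(1, 2, 2, 3)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  strict <- build_roc(scores, labels)
  incl <- build_roc(scores, labels, rule = ">=")
  s2 <- operating_characteristics(strict, 2)
  i2 <- operating_characteristics(incl, 2)
  expect_equal(s2$sensitivity, 0.5)  # only the 3 is called
  expect_equal(i2$sensitivity, 1.0)  # both 2 and 3 are called
})

test_that("reference p95 table covers the standard overlapping strata", {
  one <- make_subject("A", tanner = 1, age = 8, insulin = 10,
                      glucose = 4.5)
  tab <- derive_reference_p95_table(one)
  covered <- tab[tab$n > 0, ]
  expect_equal(covered$p95, rep(2.0, nrow(covered)))
  expect_setequal(covered$stratum,
                  c("total", "male", "age 6-9", "tanner I"))
  empty <- tab[tab$n == 0, ]
  expect_true(all(is.na(empty$p95)))
  expect_error(derive_reference_p95_table(one[0, ]), "empty")
})

test_that("age strata overlap by design so ns need not sum to the total", {
  co <- generate_cohort(cohort_config(seed = 41, n_subjects = 1200))
  tab <- derive_reference_p95_table(co)
  n <- function(s) tab$n[tab$stratum == s]
  expect_equal(n("age >=10"), n("age 10-15") + n("age >=16"))
  expect_equal(n("total"), n("age 6-9") + n("age >=10"))
  expect_gt(n("age 6-9") + n("age >=10") + n("age 10-15") + n("age >=16"),
            n("total"))
  expect_equal(n("total"), nrow(co))
})

test_that("pubertal HOMA-IR p95 exceeds the prepubertal one on synthetic references", {
  co <- generate_cohort(cohort_config(seed = 47, n_subjects = 3200))
  pr <- classify_components(co, derive_component_thresholds(co))
  wt <- classify_weight_status(co, build_growth_reference(co))
  ref <- select_reference_population(co, pr, wt)
  tab <- derive_reference_p95_table(ref)
  p95 <- function(s) tab$p95[tab$stratum == s]
  expect_gt(p95("tanner >=II"), p95("tanner I"))
  # right-skewed HOMA-IR: p95 well above the mean in every populated row
  pop <- tab[tab$n > 30, ]
  expect_true(all(pop$p95 > pop$mean))
})
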