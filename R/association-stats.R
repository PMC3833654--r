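#' Assign exposure quintiles
#'
#' Cuts a continuous exposure (HOMA-IR throughout this package) into
#' quintiles at its 20th/40th/60th/80th percentiles ([pct()] convention),
#' or at externally supplied bounds. Intervals are half-open on the left:
#' subject i is in quintile `1 + #(bounds < value_i)`, i.e. quintile k
#' covers `(b[k-1], b[k]]`. Heavily tied data that collapse two bounds
#' cannot be binned into five groups and raise an error rather than being
#' silently mis-binned.
#'
#' @param values Numeric exposure per subject, `n >= 5`.
#' @param bounds Optional numeric length-4 vector of fixed cut values
#'   (strictly increasing), e.g. bounds published for another cohort.
#'
#' @return A list with `quintile` (integer 1-5 per subject) and `bounds`
#'   (the four cut values used).
#' @export
assign_quintiles <- function(values, bounds = NULL) {
  if (length(values) < 5L) {
    stop("need at least 5 values to form quintiles", call. = FALSE)
  }
  if (is.null(bounds)) {
    bounds <- pct(values, c(0.2, 0.4, 0.6, 0.8))
  }
  if (length(bounds) != 4L || any(diff(bounds) <= 0)) {
    stop("quintile bounds are not strictly increasing (ties collapse the ",
         "grid); supply explicit `bounds` or use a coarser grouping",
         call. = FALSE)
  }
  quintile <- 1L + rowSums(outer(values, bounds, `>`))
  list(quintile = as.integer(quintile), bounds = as.numeric(bounds))
}

#' Crude odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Closed-form odds ratio `ad / (bc)` for the table
#' `rbind(c(a, b), c(c, d))` (rows: exposed / unexposed; columns: cases /
#' non-cases), with the Woolf (log-scale normal) 95% interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero, 0.5 is added to all four cells (Haldane-Anscombe) and the result
#' is flagged `corrected`.
#'
#' @param a,b,c,d Non-negative counts.
#' @return A one-row tibble: `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
crude_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    corrected = corrected
  )
}

#' Quintile odds ratios from a maximum-likelihood logistic fit
#'
#' Fits `outcome ~ quintile indicators (+ covariates)` by ML logistic
#' regression (IRLS via [stats::glm()]), with quintile 1 as referent, and
#' returns per-quintile odds ratios with Wald 95% confidence intervals
#' and Wald p-values. In the screening analyses the covariates are age
#' (years, continuous), sex, and Tanner stage treated as a numeric
#' ordinal (`tanner_numeric = FALSE` switches to indicator coding).
#' Non-convergence or separation does not crash: affected quintile rows
#' are flagged and their intervals reported unbounded.
#'
#' @param outcome Logical (or 0/1) outcome per subject; both classes
#'   required.
#' @param quintile Integer 1-5 per subject (see [assign_quintiles()]).
#' @param covariates Optional data frame with any of `age`, `sex`,
#'   `tanner`; `NULL` fits the quintile-only model, whose odds ratios
#'   equal the crude 2x2 ones.
#' @param tanner_numeric Treat Tanner as numeric ordinal (default) or as
#'   factor indicators.
#'
#' @return A tibble with one row per quintile (1 = referent with
#'   `or = 1`): `quintile`, `n`, `n_cases`, `or`, `ci_low`, `ci_high`,
#'   `p`, `flagged`.
#' @export
fit_logistic_or <- function(outcome, quintile, covariates = NULL,
                            tanner_numeric = TRUE) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2L) {
    stop("`outcome` must contain both classes", call. = FALSE)
  }
  if (!all(quintile %in% 1:5)) {
    stop("`quintile` must be integers 1-5", call. = FALSE)
  }
  dat <- data.frame(y = outcome, q = factor(quintile, levels = 1:5))
  form <- y ~ q
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("age" %in% names(covariates)) dat$age <- covariates$age
    if ("sex" %in% names(covariates)) {
      dat$sex <- factor(normalize_sex(covariates$sex))
    }
    if ("tanner" %in% names(covariates)) {
      dat$tanner <- if (tanner_numeric) as.numeric(covariates$tanner)
                    else factor(covariates$tanner)
    }
    extra <- intersect(c("age", "sex", "tanner"), names(dat))
    form <- stats::reformulate(c("q", extra), response = "y")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  rows <- purrr::map(2:5, function(k) {
    term <- paste0("q", k)
    n_k <- sum(quintile == k)
    cases_k <- sum(outcome[quintile == k])
    if (!term %in% rownames(cf)) {
      return(tibble::tibble(quintile = k, n = n_k, n_cases = cases_k,
                            or = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p = NA_real_,
                            flagged = TRUE))
    }
    est <- cf[term, "Estimate"]; se <- cf[term, "Std. Error"]
    bad <- separation && (abs(est) > 15 || se > 100)
    tibble::tibble(
      quintile = k, n = n_k, n_cases = cases_k,
      or = exp(est),
      ci_low = if (bad) 0 else exp(est - 1.96 * se),
      ci_high = if (bad) Inf else exp(est + 1.96 * se),
      p = cf[term, "Pr(>|z|)"],
      flagged = bad || !fit$converged
    )
  })
  n1 <- sum(quintile == 1L)
  cases1 <- sum(outcome[quintile == 1L])
  dplyr::bind_rows(
    tibble::tibble(quintile = 1L, n = n1, n_cases = cases1,
                   or = 1, ci_low = NA_real_, ci_high = NA_real_,
                   p = NA_real_, flagged = FALSE),
    dplyr::bind_rows(rows)
  )
}

#' Pearson chi-squared test of an r x c contingency table
#'
#' Plain Pearson statistic `sum (O - E)^2 / E` with margin-derived
#' expected counts, no continuity correction; degrees of freedom
#' `(r - 1)(c - 1)`.
#'
#' @param table An `r x c` matrix of non-negative counts (at least 2x2)
#'   with no zero row or column margin.
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: expected counts undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = unname(ht$p.value)
  )
}

#' Prevalence of insulin resistance by risk group and HOMA-IR cut-off
#'
#' For each risk-factor group (MS and each of its five components) and
#' each weight-status category, computes the percentage of subjects whose
#' HOMA-IR strictly exceeds each labelled cut-off, and a chi-squared
#' comparison of insulin-resistance prevalence across the weight-status
#' groups at each cut-off.
#'
#' @param cohort Cohort tibble.
#' @param profiles Component profiles ([classify_components()]).
#' @param weight Weight-status tibble ([classify_weight_status()]).
#' @param cutoffs Named numeric vector of HOMA-IR cut-offs; names label
#'   their provenance (e.g. `c("ROC" = 2.3, "p95" = 3.0)`).
#'
#' @return A list: `prevalence` (tibble `group`, `cutoff_label`, `cutoff`,
#'   `n`, `n_ir`, `prevalence_pct`; empty groups keep `n = 0` with `NA`
#'   prevalence) and `weight_status_chi_sq` (tibble `cutoff_label`,
#'   `statistic`, `df`, `p` across normal/overweight/obese).
#' @export
prevalence_of_ir <- function(cohort, profiles, weight, cutoffs) {
  if (length(cutoffs) == 0L) stop("`cutoffs` must be non-empty", call. = FALSE)
  if (is.null(names(cutoffs)) || any(!nzchar(names(cutoffs)))) {
    names(cutoffs) <- paste0("cutoff_", seq_along(cutoffs))
  }
  dat <- dplyr::inner_join(cohort, profiles, by = "id") |>
    dplyr::inner_join(weight[, c("id", "category")], by = "id")
  dat$homa <- homa_ir(dat$insulin, dat$glucose)
  groups <- list(
    "MS" = dat$ms,
    "central obesity" = dat$central_obesity,
    "low HDL-C" = dat$low_hdl,
    "high TG" = dat$high_tg,
    "IFG" = dat$ifg,
    "high BP" = dat$high_bp,
    "normal weight" = dat$category == "normal",
    "overweight" = dat$category == "overweight",
    "obese" = dat$category == "obese"
  )
  prevalence <- purrr::imap(groups, function(mask, gname) {
    x <- dat$homa[mask]
    purrr::imap(cutoffs, function(ct, lab) {
      n <- length(x)
      n_ir <- sum(x > ct)
      tibble::tibble(
        group = gname, cutoff_label = lab, cutoff = ct, n = n,
        n_ir = n_ir,
        prevalence_pct = if (n > 0) 100 * n_ir / n else NA_real_
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  wt_levels <- c("normal", "overweight", "obese")
  chi_rows <- purrr::imap(cutoffs, function(ct, lab) {
    tab <- vapply(wt_levels, function(w) {
      x <- dat$homa[dat$category == w]
      c(sum(x > ct), sum(x <= ct))
    }, numeric(2))
    res <- tryCatch(
      chi_square(t(tab)),
      error = function(e) tibble::tibble(statistic = NA_real_,
                                         df = NA_real_, p = NA_real_)
    )
    tibble::tibble(cutoff_label = lab, statistic = res$statistic,
                   df = res$df, p = res$p)
  }) |> dplyr::bind_rows()

  list(prevalence = prevalence, weight_status_chi_sq = chi_rows)
}
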