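#' Build an empirical ROC curve for a score against a binary label
#'
#' Candidate cut-offs are the distinct observed scores plus one sentinel
#' below the minimum; a subject is called positive when `score > cutoff`
#' (strictly greater, matching the "index above threshold" convention of
#' screening analyses; set `rule = ">="` for the inclusive variant). At
#' each cut-off sensitivity is the true-positive fraction and specificity
#' the true-negative fraction; the AUC is the trapezoidal area over
#' (1 - specificity, sensitivity), which with this candidate set equals
#' the tie-corrected pairwise-concordance (Mann-Whitney) probability.
#'
#' @param scores Numeric score per subject (e.g. HOMA-IR).
#' @param labels Logical (or 0/1) condition indicator; both classes must
#'   be present.
#' @param rule Positive-call rule, `">"` (default) or `">="`.
#'
#' @return An object of class `roc_curve`: list with `points` (tibble
#'   `cutoff`, `sensitivity`, `specificity`, ordered by increasing
#'   cutoff), `n_pos`, `n_neg`, `auc`, `rule`, and the input `scores` and
#'   `labels` (needed to evaluate off-grid cut-offs).
#' @export
build_roc <- function(scores, labels, rule = c(">", ">=")) {
  rule <- match.arg(rule)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  cutoffs <- c(min(scores) - 1, sort(unique(scores)))
  ss <- vapply(cutoffs, function(ct) {
    call_pos <- if (rule == ">") scores > ct else scores >= ct
    c(sum(call_pos & labels) / n_pos, sum(!call_pos & !labels) / n_neg)
  }, numeric(2))
  points <- tibble::tibble(
    cutoff = cutoffs, sensitivity = ss[1, ], specificity = ss[2, ]
  )
  # trapezoid over the ROC plane, traversed from (0,0) to (1,1)
  fpr <- rev(1 - points$specificity)
  tpr <- rev(points$sensitivity)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = points, n_pos = n_pos, n_neg = n_neg, auc = auc,
         rule = rule, scores = scores, labels = labels),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, %d pos / %d neg, AUC = %.4f\n",
              nrow(x$points), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Select the optimal cut-off on a ROC curve
#'
#' Two standard criteria: `"youden"` maximises the Youden index
#' `J = sensitivity + specificity - 1`; `"distance"` minimises the squared
#' distance to the ideal corner (0, 1) of the ROC plane,
#' `(1 - sensitivity)^2 + (1 - specificity)^2`. Ties on the chosen
#' criterion are broken by the other criterion, then by the smaller
#' cut-off, so the result is deterministic.
#'
#' @param roc A `roc_curve` from [build_roc()].
#' @param method `"youden"` or `"distance"`.
#'
#' @return A one-row tibble (`cutoff_result`): `method`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `distance_sq`.
#' @export
optimal_cutoff <- function(roc, method = c("youden", "distance")) {
  stopifnot(inherits(roc, "roc_curve"))
  method <- match.arg(method)
  pts <- roc$points
  youden <- pts$sensitivity + pts$specificity - 1
  dist_sq <- (1 - pts$sensitivity)^2 + (1 - pts$specificity)^2
  ord <- if (method == "youden") {
    order(-youden, dist_sq, pts$cutoff)
  } else {
    order(dist_sq, -youden, pts$cutoff)
  }
  i <- ord[1]
  tibble::tibble(
    method = method,
    cutoff = pts$cutoff[i],
    sensitivity = pts$sensitivity[i],
    specificity = pts$specificity[i],
    youden = youden[i],
    distance_sq = dist_sq[i]
  )
}

#' Sensitivity and specificity at an arbitrary cut-off
#'
#' Re-counts true-positive and true-negative fractions at any supplied
#' cut-off (not necessarily one of the ROC curve's candidates) under the
#' curve's positive-call rule. This is how externally derived thresholds
#' - e.g. a reference-population 95th percentile - are given operating
#' characteristics on the ROC curve.
#'
#' @param roc A `roc_curve`.
#' @param cutoff Numeric cut-off value(s).
#'
#' @return A tibble with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `distance_sq` (one row per cut-off).
#' @export
operating_characteristics <- function(roc, cutoff) {
  stopifnot(inherits(roc, "roc_curve"))
  rows <- purrr::map(cutoff, function(ct) {
    call_pos <- if (roc$rule == ">") roc$scores > ct else roc$scores >= ct
    sens <- sum(call_pos & roc$labels) / roc$n_pos
    spec <- sum(!call_pos & !roc$labels) / roc$n_neg
    tibble::tibble(
      cutoff = ct, sensitivity = sens, specificity = spec,
      youden = sens + spec - 1,
      distance_sq = (1 - sens)^2 + (1 - spec)^2
    )
  })
  dplyr::bind_rows(rows)
}

reference_strata <- function(cohort) {
  list(
    "total"      = rep(TRUE, nrow(cohort)),
    "male"       = cohort$sex == "M",
    "female"     = cohort$sex == "F",
    "age 6-9"    = cohort$age < 10,
    "age >=10"   = cohort$age >= 10,
    "age 10-15"  = cohort$age >= 10 & cohort$age < 16,
    "age >=16"   = cohort$age >= 16,
    "tanner I"   = cohort$tanner == 1L,
    "tanner >=II" = cohort$tanner >= 2L,
    "tanner II-IV" = cohort$tanner %in% 2:4,
    "tanner V"   = cohort$tanner == 5L
  )
}

#' Reference-population 95th-percentile HOMA-IR table
#'
#' For the healthy reference population (see
#' [select_reference_population()]), tabulates n, arithmetic mean, SD and
#' the 95th percentile of HOMA-IR overall and within the conventional
#' strata: sex, age bands 6-9 / >=10 / 10-15 / >=16, and Tanner bands I /
#' >=II / II-IV / V. The strata deliberately overlap (>=10 contains both
#' 10-15 and >=16), so row n's need not sum to the total. An empty
#' stratum yields a row with `n = 0` and `NA` statistics.
#'
#' @param reference Reference-population cohort tibble (must carry
#'   `sex`, `age`, `tanner`, `glucose`, `insulin`).
#'
#' @return A tibble of class `reference_threshold_table` with columns
#'   `stratum`, `n`, `mean`, `sd`, `p95`.
#' @export
derive_reference_p95_table <- function(reference) {
  if (nrow(reference) == 0L) {
    stop("reference population is empty", call. = FALSE)
  }
  ref <- dplyr::mutate(reference, sex = normalize_sex(.data$sex))
  hi <- homa_ir(ref$insulin, ref$glucose)
  strata <- reference_strata(ref)
  rows <- purrr::imap(strata, function(mask, label) {
    x <- hi[mask]
    n <- length(x)
    tibble::tibble(
      stratum = label,
      n = n,
      mean = if (n > 0) mean(x) else NA_real_,
      sd = if (n > 1) stats::sd(x) else NA_real_,
      p95 = if (n > 0) pct(x, 0.95) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reference_threshold_table", class(out))
  out
}
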