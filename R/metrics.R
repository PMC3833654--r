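#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' Computes the HOMA-IR surrogate index of insulin resistance from fasting
#' insulin and fasting glucose:
#' \deqn{HOMA\textrm{-}IR = \frac{insulin \,[mU/L] \times glucose \,[mmol/L]}{22.5}}
#'
#' @param insulin Fasting insulin in mU/L. Non-negative; vectorised.
#' @param glucose Fasting plasma glucose in mmol/L. Strictly positive;
#'   vectorised (recycled against `insulin` under the usual rules).
#'
#' @return A numeric vector of unitless HOMA-IR values.
#' @examples
#' homa_ir(10, 4.5) # 2.0
#' @export
homa_ir <- function(insulin, glucose) {
  if (!is.numeric(insulin) || !is.numeric(glucose)) {
    stop("`insulin` and `glucose` must be numeric", call. = FALSE)
  }
  if (any(insulin < 0, na.rm = TRUE)) {
    stop("`insulin` must be non-negative (mU/L)", call. = FALSE)
  }
  if (any(glucose <= 0, na.rm = TRUE)) {
    stop("`glucose` must be strictly positive (mmol/L)", call. = FALSE)
  }
  insulin * glucose / 22.5
}

#' Percentile by linear interpolation of order statistics
#'
#' The single quantile convention used throughout the package for every
#' percentile-based threshold (waist and blood-pressure cut-offs, reference
#' 95th percentiles, quintile bounds, growth-reference curves): linear
#' interpolation at rank `h = 1 + (n - 1) p` on the sorted values, i.e. the
#' default type-7 estimator of [stats::quantile()].
#'
#' @param x Numeric vector, non-empty after removing `NA` when
#'   `na.rm = TRUE`.
#' @param probs Probabilities in `[0, 1]`.
#' @param na.rm Drop missing values first?
#'
#' @return Numeric vector of quantiles, unnamed, same length as `probs`.
#' @examples
#' pct(c(1, 2, 3, 4), 0.5)  # 2.5
#' pct(1:100, 0.95)         # 95.05
#' @export
pct <- function(x, probs, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop("cannot take a quantile of an empty set of values", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("values contain NA; use `na.rm = TRUE` to drop them", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("`probs` must lie in [0, 1]", call. = FALSE)
  }
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Normalise assorted sex encodings to "M"/"F". Accepts M/F, male/female
# (any case), and the common 1 = male, 2 = female numeric coding.
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male", "boy", "1")] <- "M"
  out[s %in% c("f", "female", "girl", "2")] <- "F"
  bad <- !is.na(s) & is.na(out)
  if (any(bad)) {
    stop(
      "unrecognised sex encoding: ",
      paste(unique(s[bad]), collapse = ", "),
      " (expected M/F, male/female or 1/2)",
      call. = FALSE
    )
  }
  out
}

#' Build an empirical BMI growth reference from a cohort
#'
#' Derives an age- and sex-specific BMI percentile table (5th, 85th and 95th
#' percentiles by default, plus any extra probabilities requested) from
#' observed data, using the package quantile convention ([pct()]). Ages are
#' grouped into one-year bands keyed by their integer start (the band for
#' `age` is `floor(age)`).
#'
#' External references in the same layout (columns `age`, `sex`, `p05`,
#' `p85`, `p95`, ...) or in LMS form (columns `age`, `sex`, `L`, `M`, `S`)
#' can be loaded with [read_growth_reference()] and used interchangeably.
#'
#' @param cohort A cohort data frame with columns `sex`, `age`, `bmi`.
#' @param probs Probabilities for the percentile columns. Must include
#'   0.05, 0.85 and 0.95, which define the weight-status bands.
#'
#' @return A tibble with columns `age` (integer band start), `sex`
#'   (`"M"`/`"F"`), and one `pXX` column per probability.
#' @export
build_growth_reference <- function(cohort,
                                   probs = c(0.05, 0.25, 0.5, 0.75, 0.85,
                                             0.95)) {
  stopifnot(all(c("sex", "age", "bmi") %in% names(cohort)))
  if (!all(c(0.05, 0.85, 0.95) %in% probs)) {
    stop("`probs` must include 0.05, 0.85 and 0.95", call. = FALSE)
  }
  probs <- sort(unique(probs))
  cols <- sprintf("p%02d", round(100 * probs))
  cohort |>
    dplyr::mutate(
      age = floor(.data$age),
      sex = normalize_sex(.data$sex)
    ) |>
    dplyr::group_by(.data$age, .data$sex) |>
    dplyr::summarise(
      {
        q <- pct(.data$bmi, probs)
        tibble::as_tibble(stats::setNames(as.list(q), cols))
      },
      .groups = "drop"
    )
}

#' Load a BMI growth reference from CSV
#'
#' Two layouts are accepted and auto-detected from the header:
#' percentile columns (`age`, `sex`, `p05`, `p85`, `p95`, optionally more
#' `pXX` columns) or LMS parameters (`age`, `sex`, `L`, `M`, `S`), the
#' Box-Cox form used by national growth charts, from which any percentile
#' follows as `M (1 + L S z)^{1/L}`.
#'
#' @param path Path to a CSV file.
#' @return A growth-reference tibble usable by [classify_weight_status()].
#' @export
read_growth_reference <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(ref)
  if (!all(c("age", "sex") %in% nm)) {
    stop("growth reference must have `age` and `sex` columns", call. = FALSE)
  }
  is_lms <- all(c("L", "M", "S") %in% nm)
  is_pct <- all(c("p05", "p85", "p95") %in% nm)
  if (!is_lms && !is_pct) {
    stop(
      "growth reference must carry either p05/p85/p95 percentile columns ",
      "or L/M/S parameters",
      call. = FALSE
    )
  }
  ref$sex <- normalize_sex(ref$sex)
  ref$age <- as.integer(floor(ref$age))
  ref
}

lms_value_at <- function(L, M, S, p) {
  z <- stats::qnorm(p)
  ifelse(abs(L) < 1e-8, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

lms_percentile_of <- function(bmi, L, M, S) {
  z <- ifelse(
    abs(L) < 1e-8,
    log(bmi / M) / S,
    ((bmi / M)^L - 1) / (L * S)
  )
  100 * stats::pnorm(z)
}

# Interpolate an approximate percentile (0-100) for `bmi` from the available
# percentile columns of one reference row. Outside the tabulated range the
# estimate is clamped to the extreme tabulated probability.
percentile_from_columns <- function(bmi, row) {
  pc <- grep("^p[0-9]+$", names(row), value = TRUE)
  pr <- as.numeric(sub("^p", "", pc))
  vals <- as.numeric(row[pc])
  o <- order(pr)
  pr <- pr[o]; vals <- vals[o]
  stats::approx(vals, pr, xout = bmi, rule = 2, ties = "ordered")$y
}

#' Classify weight status from BMI against a growth reference
#'
#' Converts each BMI to an age- and sex-specific percentile using the
#' supplied growth reference and assigns the screening bands: `normal`
#' (5th-85th percentile, both ends included), `overweight` (above the 85th
#' up to and including the 95th), `obese` (strictly above the 95th).
#' Subjects below the 5th percentile are flagged `underweight`; they are
#' never labelled normal and are excluded when selecting the metabolic
#' reference population.
#'
#' @param cohort Cohort data frame with `id`, `sex`, `age`, `bmi`.
#' @param growth_reference A reference from [build_growth_reference()] or
#'   [read_growth_reference()] (percentile-column or LMS layout).
#'
#' @return A tibble with `id`, `bmi_percentile` (estimated, 0-100) and
#'   `category` (factor: underweight / normal / overweight / obese).
#' @export
classify_weight_status <- function(cohort, growth_reference) {
  stopifnot(all(c("id", "sex", "age", "bmi") %in% names(cohort)))
  if (any(cohort$bmi <= 0, na.rm = TRUE)) {
    stop("`bmi` must be positive", call. = FALSE)
  }
  sex <- normalize_sex(cohort$sex)
  band <- floor(cohort$age)
  key <- paste(band, sex)
  ref_key <- paste(growth_reference$age, growth_reference$sex)
  idx <- match(key, ref_key)
  if (anyNA(idx)) {
    missing <- unique(key[is.na(idx)])
    stop(
      "growth reference does not cover strata: ",
      paste(missing, collapse = "; "),
      call. = FALSE
    )
  }
  is_lms <- all(c("L", "M", "S") %in% names(growth_reference))
  if (is_lms) {
    L <- growth_reference$L[idx]
    M <- growth_reference$M[idx]
    S <- growth_reference$S[idx]
    perc <- lms_percentile_of(cohort$bmi, L, M, S)
    p05 <- lms_value_at(L, M, S, 0.05)
    p85 <- lms_value_at(L, M, S, 0.85)
    p95 <- lms_value_at(L, M, S, 0.95)
  } else {
    perc <- vapply(
      seq_len(nrow(cohort)),
      function(i) percentile_from_columns(cohort$bmi[i],
                                          growth_reference[idx[i], ]),
      numeric(1)
    )
    p05 <- growth_reference$p05[idx]
    p85 <- growth_reference$p85[idx]
    p95 <- growth_reference$p95[idx]
  }
  category <- dplyr::case_when(
    cohort$bmi < p05 ~ "underweight",
    cohort$bmi <= p85 ~ "normal",
    cohort$bmi <= p95 ~ "overweight",
    TRUE ~ "obese"
  )
  tibble::tibble(
    id = cohort$id,
    bmi_percentile = perc,
    category = factor(category,
                      levels = c("underweight", "normal", "overweight",
                                 "obese"))
  )
}
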