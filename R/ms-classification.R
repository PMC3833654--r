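# Fixed component cut-offs of the modified ATP III pediatric definition
# (mmol/L). TG and HDL-C cuts correspond to the 90th / 5th percentile of a
# healthy reference population; IFG is the usual impaired-fasting-glucose
# bound.
MS_FIXED_CUTS <- c(tg = 1.24, hdl = 1.03, glucose = 5.6)

age_band_start <- function(age, age_min, width) {
  age_min + floor((age - age_min) / width) * width
}

#' Derive cohort-based metabolic-syndrome component thresholds
#'
#' Computes the percentile thresholds of the modified ATP III definition
#' from a cohort: the waist-circumference 90th percentile within (age
#' group, sex) strata, and the systolic and diastolic blood-pressure 95th
#' percentiles within (age group, sex, height band) strata, height bands
#' being within-stratum quantile bands (tertiles by default;
#' `n_height_bands = 1` disables the height adjustment). The fixed cuts
#' (TG >= 1.24 mmol/L, HDL-C <= 1.03 mmol/L, glucose >= 5.6 mmol/L) are
#' attached verbatim. All percentiles use [pct()].
#'
#' @param cohort Cohort tibble (schema of [generate_cohort()]).
#' @param age_group_width Width of the age bands in years (default 1).
#' @param n_height_bands Number of height quantile bands for the BP
#'   thresholds (default 3).
#' @param min_stratum_n Minimum subjects required in every (age group,
#'   sex) stratum; an undersized stratum is an error naming it.
#'
#' @return An object of class `ms_thresholds`: a list with tibbles `wc`
#'   (`age_group`, `sex`, `n`, `wc_p90`) and `bp` (`age_group`, `sex`,
#'   `height_band`, `height_lo`, `height_hi`, `n`, `sbp_p95`, `dbp_p95`),
#'   the `fixed` cuts, and the banding parameters.
#' @export
derive_component_thresholds <- function(cohort,
                                        age_group_width = 1,
                                        n_height_bands = 3,
                                        min_stratum_n = 20) {
  stopifnot(all(c("sex", "age", "wc", "sbp", "dbp", "height") %in%
                  names(cohort)))
  age_min <- floor(min(cohort$age))
  dat <- cohort |>
    dplyr::mutate(
      sex = normalize_sex(.data$sex),
      age_group = age_band_start(.data$age, age_min, age_group_width)
    )
  sizes <- dplyr::count(dat, .data$age_group, .data$sex)
  small <- sizes[sizes$n < min_stratum_n, ]
  if (nrow(small) > 0L) {
    stop(
      "undersized strata (need >= ", min_stratum_n, " subjects): ",
      paste(sprintf("age %g sex %s (n=%d)", small$age_group, small$sex,
                    small$n), collapse = "; "),
      call. = FALSE
    )
  }
  wc_tab <- dat |>
    dplyr::group_by(.data$age_group, .data$sex) |>
    dplyr::summarise(n = dplyr::n(), wc_p90 = pct(.data$wc, 0.90),
                     .groups = "drop")

  band_one <- function(df) {
    k <- n_height_bands
    if (k <= 1L) {
      breaks <- c(-Inf, Inf)
    } else {
      inner <- pct(df$height, seq_len(k - 1) / k)
      breaks <- c(-Inf, inner, Inf)
      if (anyDuplicated(inner)) breaks <- unique(breaks)
    }
    band <- cut(df$height, breaks, labels = FALSE, right = TRUE)
    df |>
      dplyr::mutate(height_band = band) |>
      dplyr::group_by(.data$height_band) |>
      dplyr::summarise(
        height_lo = breaks[.data$height_band[1]],
        height_hi = breaks[.data$height_band[1] + 1L],
        n = dplyr::n(),
        sbp_p95 = pct(.data$sbp, 0.95),
        dbp_p95 = pct(.data$dbp, 0.95),
        .groups = "drop"
      )
  }
  bp_tab <- dat |>
    dplyr::group_by(.data$age_group, .data$sex) |>
    dplyr::group_modify(~ band_one(.x)) |>
    dplyr::ungroup()

  structure(
    list(
      wc = wc_tab,
      bp = bp_tab,
      fixed = MS_FIXED_CUTS,
      age_min = age_min,
      age_group_width = age_group_width,
      n_height_bands = n_height_bands
    ),
    class = "ms_thresholds"
  )
}

#' @export
print.ms_thresholds <- function(x, ...) {
  cat("<ms_thresholds>\n")
  cat("  fixed cuts (mmol/L): TG >=", x$fixed[["tg"]],
      " HDL <=", x$fixed[["hdl"]], " glucose >=", x$fixed[["glucose"]], "\n")
  cat("  WC p90 strata:", nrow(x$wc),
      "(age bands of", x$age_group_width, "y)\n")
  cat("  BP p95 strata:", nrow(x$bp),
      "(", x$n_height_bands, "height bands )\n")
  invisible(x)
}

#' Serialise component thresholds to / from JSON
#'
#' Round-trips an `ms_thresholds` object through JSON so thresholds derived
#' on one cohort can be reapplied to another.
#'
#' @param thresholds An `ms_thresholds` object.
#' @param path File path.
#' @return `read_thresholds_json()` returns an `ms_thresholds` object;
#'   `write_thresholds_json()` returns `path` invisibly.
#' @export
write_thresholds_json <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "ms_thresholds"))
  x <- unclass(thresholds)
  x$fixed <- as.list(x$fixed)  # keep names: named vectors drop them in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$wc <- tibble::as_tibble(x$wc)
  x$bp <- tibble::as_tibble(x$bp)
  # JSON has no Inf; unbounded height-band ends come back as NA
  x$bp$height_lo[is.na(x$bp$height_lo)] <- -Inf
  x$bp$height_hi[is.na(x$bp$height_hi)] <- Inf
  x$fixed <- unlist(x$fixed)
  structure(x, class = "ms_thresholds")
}

#' Classify metabolic-syndrome components per subject
#'
#' Applies the modified ATP III component rules to every subject:
#' central obesity (WC >= stratum 90th percentile), elevated blood pressure
#' (SBP and/or DBP >= stratum 95th percentile), hypertriglyceridemia
#' (TG >= 1.24 mmol/L), low HDL-C (<= 1.03 mmol/L) and impaired fasting
#' glucose (>= 5.6 mmol/L). All comparisons are inclusive. MS is the
#' presence of three or more components.
#'
#' @param cohort Cohort tibble; every subject's (age group, sex, height
#'   band) stratum must be covered by `thresholds`, and the used
#'   measurements must be non-missing (an error lists offending fields).
#' @param thresholds An `ms_thresholds` object from
#'   [derive_component_thresholds()] (or deserialised via
#'   [read_thresholds_json()]).
#'
#' @return A tibble with `id`, logical flags `central_obesity`, `high_bp`,
#'   `high_tg`, `low_hdl`, `ifg`, the component `count` (0-5) and `ms`
#'   (`count >= 3`).
#' @export
classify_components <- function(cohort, thresholds) {
  stopifnot(inherits(thresholds, "ms_thresholds"))
  need <- c("id", "sex", "age", "height", "wc", "sbp", "dbp", "tg", "hdl",
            "glucose")
  miss_cols <- setdiff(need, names(cohort))
  if (length(miss_cols)) {
    stop("cohort is missing columns: ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  na_fields <- need[vapply(cohort[need], anyNA, logical(1))]
  if (length(na_fields)) {
    stop("missing measurements in fields: ",
         paste(na_fields, collapse = ", "), call. = FALSE)
  }
  dat <- cohort |>
    dplyr::mutate(
      sex = normalize_sex(.data$sex),
      age_group = age_band_start(.data$age, thresholds$age_min,
                                 thresholds$age_group_width)
    )
  dat <- dplyr::left_join(dat, thresholds$wc, by = c("age_group", "sex"),
                          suffix = c("", ".thr"))
  if (anyNA(dat$wc_p90)) {
    bad <- unique(paste0("age ", dat$age_group[is.na(dat$wc_p90)],
                         " sex ", dat$sex[is.na(dat$wc_p90)]))
    stop("thresholds do not cover strata: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  bp <- thresholds$bp
  bp_join <- dplyr::left_join(
    dat[, c("id", "age_group", "sex", "height")], bp,
    by = c("age_group", "sex"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$height > .data$height_lo,
                  .data$height <= .data$height_hi) |>
    dplyr::distinct(.data$id, .keep_all = TRUE)
  dat <- dplyr::left_join(dat, bp_join[, c("id", "sbp_p95", "dbp_p95")],
                          by = "id")
  if (anyNA(dat$sbp_p95)) {
    stop("blood-pressure thresholds do not cover every subject's stratum",
         call. = FALSE)
  }
  fx <- thresholds$fixed
  out <- tibble::tibble(
    id = dat$id,
    central_obesity = dat$wc >= dat$wc_p90,
    high_bp = dat$sbp >= dat$sbp_p95 | dat$dbp >= dat$dbp_p95,
    high_tg = dat$tg >= fx[["tg"]],
    low_hdl = dat$hdl <= fx[["hdl"]],
    ifg = dat$glucose >= fx[["glucose"]]
  )
  out$count <- rowSums(out[, c("central_obesity", "high_bp", "high_tg",
                               "low_hdl", "ifg")])
  out$count <- as.integer(out$count)
  out$ms <- out$count >= 3L
  out
}

#' Select the healthy reference population
#'
#' The reference population against which normative HOMA-IR percentiles
#' are derived: subjects of normal weight status carrying none of the five
#' metabolic-syndrome components. Underweight, overweight and obese
#' subjects are excluded, as is anyone with a single component. Input
#' order is preserved.
#'
#' @param cohort Cohort tibble.
#' @param profiles Component profiles from [classify_components()].
#' @param weight Weight-status tibble from [classify_weight_status()].
#'
#' @return The qualifying subset of `cohort` (same columns, original
#'   order). Errors if no subject qualifies, since reference percentiles
#'   would be undefined.
#' @export
select_reference_population <- function(cohort, profiles, weight) {
  stopifnot(all(c("id", "count") %in% names(profiles)),
            all(c("id", "category") %in% names(weight)))
  ok_ids <- intersect(
    profiles$id[profiles$count == 0L],
    weight$id[weight$category == "normal"]
  )
  subset <- cohort[cohort$id %in% ok_ids, , drop = FALSE]
  if (nrow(subset) == 0L) {
    stop("reference population is empty; reference percentiles undefined",
         call. = FALSE)
  }
  subset
}
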