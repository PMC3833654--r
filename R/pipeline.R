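# Fixed cohort CSV schema: header names in file order, mapped to the
# internal column names used throughout the package.
COHORT_CSV_SCHEMA <- c(
  id = "id", sex = "sex", age = "age", tanner = "tanner",
  height_cm = "height", weight_kg = "weight", bmi = "bmi", wc_cm = "wc",
  fat_pct = "fat_pct", sbp = "sbp", dbp = "dbp", tc = "tc", tg = "tg",
  hdl = "hdl", ldl = "ldl", glucose = "glucose", insulin = "insulin"
)

#' Read / write a cohort CSV
#'
#' The on-disk schema is fixed: columns `id, sex, age, tanner, height_cm,
#' weight_kg, bmi, wc_cm, fat_pct, sbp, dbp, tc, tg, hdl, ldl, glucose,
#' insulin` (UTF-8, decimal point). Sex may be encoded `M`/`F`,
#' `male`/`female` or `1`/`2` (1 = male) and is normalised to `M`/`F` on
#' read. Writing then reading reproduces every field to full precision.
#'
#' @param path CSV file path.
#' @param cohort Cohort tibble (internal column names, as produced by
#'   [generate_cohort()] or [read_cohort_csv()]).
#'
#' @return `read_cohort_csv()` returns a cohort tibble;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  # read everything as character and convert with base R's strtod-backed
  # as.numeric(), which round-trips the %.17g representation written by
  # write_cohort_csv() to the exact double
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), show_col_types = FALSE)
  missing <- setdiff(names(COHORT_CSV_SCHEMA), names(raw))
  extra <- setdiff(names(raw), names(COHORT_CSV_SCHEMA))
  if (length(missing) || length(extra)) {
    stop(
      "cohort CSV schema mismatch",
      if (length(missing)) paste0("; missing columns: ",
                                  paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected columns: ",
                                paste(extra, collapse = ", ")),
      call. = FALSE
    )
  }
  out <- raw[, names(COHORT_CSV_SCHEMA)]
  names(out) <- unname(COHORT_CSV_SCHEMA)
  for (col in setdiff(names(out), c("id", "sex"))) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(val) & !is.na(out[[col]]))
    if (length(bad)) {
      stop("non-numeric `", col, "` at rows: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    out[[col]] <- val
  }
  out$sex <- normalize_sex(out$sex)
  out$tanner <- as.integer(out$tanner)
  if (anyDuplicated(out$id)) {
    stop("duplicate subject ids in cohort CSV", call. = FALSE)
  }
  out
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(unname(COHORT_CSV_SCHEMA), names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- cohort[, unname(COHORT_CSV_SCHEMA)]
  names(out) <- names(COHORT_CSV_SCHEMA)
  # %.17g preserves every double exactly across a write/read cycle
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' Exactly one input source: a cohort CSV path (`input`) or a generator
#' configuration (`generator`). The quantile convention is the single
#' package-wide one (linear interpolation at rank `1 + (n-1)p`), recorded
#' in the manifest.
#'
#' @param input Path to a cohort CSV, or `NULL` to generate.
#' @param generator A [cohort_config()], or `NULL` to read from `input`.
#' @param seed Integer seed; overrides `generator$seed` when set.
#' @param age_group_width Age band width (years) for percentile strata.
#' @param n_height_bands Height bands for blood-pressure thresholds.
#' @param cutoff_methods Which HOMA-IR cut-off derivations to run,
#'   subset of `c("youden", "distance", "p95")`.
#' @param out_dir Output directory for the report files, or `NULL` to
#'   return the bundle without writing.
#' @param quiet Suppress stage-boundary log messages?
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, seed = NULL,
                       age_group_width = 1, n_height_bands = 3,
                       cutoff_methods = c("youden", "distance", "p95"),
                       out_dir = NULL, quiet = FALSE) {
  if (is.null(input) == is.null(generator)) {
    stop("exactly one of `input` (CSV path) or `generator` must be given",
         call. = FALSE)
  }
  cutoff_methods <- match.arg(cutoff_methods,
                              c("youden", "distance", "p95"),
                              several.ok = TRUE)
  if (!is.null(generator) && !is.null(seed)) {
    generator$seed <- as.integer(seed)
  }
  structure(
    list(input = input, generator = generator, seed = seed,
         age_group_width = age_group_width,
         n_height_bands = n_height_bands,
         cutoff_methods = cutoff_methods, out_dir = out_dir,
         quiet = quiet),
    class = "run_config"
  )
}

pipeline_stage <- function(name, quiet, expr) {
  tryCatch(
    expr,
    error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    }
  )
}

log_stage <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

#' Run the full insulin-resistance / metabolic-syndrome analysis
#'
#' Orchestrates every stage on one cohort: ingest or generate -> HOMA-IR
#' -> component thresholds -> MS classification -> weight status ->
#' reference population -> reference 95th-percentile table -> ROC
#' cut-offs (total, Tanner I, Tanner >=II) -> quintile odds ratios ->
#' prevalence-of-IR tables. Deterministic given the seed; every threshold
#' applied anywhere is recorded in the manifest with its provenance
#' (fixed vs cohort-derived vs reference-derived vs ROC).
#'
#' @param config A [run_config()].
#'
#' @return A list of class `pipeline_report`: `cohort_summary`,
#'   `quintile_or`, `reference_table`, `roc_results`, `prevalence`,
#'   `thresholds`, and `manifest`. If `config$out_dir` is set the bundle
#'   is also written there (TSV tables + `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  q <- config$quiet

  cohort <- pipeline_stage("input", q, {
    if (!is.null(config$input)) read_cohort_csv(config$input)
    else generate_cohort(config$generator)
  })
  log_stage(q, "cohort: %d subjects", nrow(cohort))

  thresholds <- pipeline_stage("component_thresholds", q,
    derive_component_thresholds(cohort,
                                age_group_width = config$age_group_width,
                                n_height_bands = config$n_height_bands))
  profiles <- pipeline_stage("classification", q,
    classify_components(cohort, thresholds))
  log_stage(q, "metabolic syndrome: %d of %d subjects (%.1f%%)",
            sum(profiles$ms), nrow(cohort),
            100 * mean(profiles$ms))

  growth_ref <- pipeline_stage("growth_reference", q,
    build_growth_reference(cohort))
  weight <- pipeline_stage("weight_status", q,
    classify_weight_status(cohort, growth_ref))

  reference <- pipeline_stage("reference_population", q,
    select_reference_population(cohort, profiles, weight))
  log_stage(q, "reference population: %d subjects", nrow(reference))
  reference_table <- pipeline_stage("reference_p95", q,
    derive_reference_p95_table(reference))

  cohort_summary <- pipeline_stage("cohort_summary", q,
    summarize_by_component_count(cohort, profiles))

  homa <- homa_ir(cohort$insulin, cohort$glucose)
  qs <- pipeline_stage("quintiles", q, assign_quintiles(homa))

  outcomes <- list(
    "MS" = profiles$ms,
    "central obesity" = profiles$central_obesity,
    "low HDL-C" = profiles$low_hdl,
    "high TG" = profiles$high_tg,
    "IFG" = profiles$ifg,
    "high BP" = profiles$high_bp
  )
  covars <- cohort[, c("age", "sex", "tanner")]
  quintile_or <- pipeline_stage("quintile_or", q, {
    purrr::imap(outcomes, function(y, nm) {
      dplyr::mutate(fit_logistic_or(y, qs$quintile, covars),
                    outcome = nm, .before = 1)
    }) |> dplyr::bind_rows()
  })

  ref_p95_of <- function(stratum) {
    reference_table$p95[reference_table$stratum == stratum]
  }
  roc_strata <- list(
    "total" = rep(TRUE, nrow(cohort)),
    "tanner I" = cohort$tanner == 1L,
    "tanner >=II" = cohort$tanner >= 2L
  )
  roc_results <- pipeline_stage("roc_cutoffs", q, {
    purrr::imap(roc_strata, function(mask, nm) {
      roc <- build_roc(homa[mask], profiles$ms[mask])
      rows <- list()
      if ("youden" %in% config$cutoff_methods) {
        rows <- c(rows, list(optimal_cutoff(roc, "youden")))
      }
      if ("distance" %in% config$cutoff_methods) {
        rows <- c(rows, list(optimal_cutoff(roc, "distance")))
      }
      if ("p95" %in% config$cutoff_methods) {
        p95 <- ref_p95_of(nm)
        rows <- c(rows, list(
          dplyr::mutate(operating_characteristics(roc, p95),
                        method = "p95", .before = 1)
        ))
      }
      dplyr::bind_rows(rows) |>
        dplyr::mutate(stratum = nm, auc = roc$auc,
                      n_pos = roc$n_pos, n_neg = roc$n_neg, .before = 1)
    }) |> dplyr::bind_rows()
  })

  ir_cutoffs <- c()
  if ("youden" %in% config$cutoff_methods) {
    ir_cutoffs <- c(ir_cutoffs, "ROC (Youden), total" =
                      roc_results$cutoff[roc_results$stratum == "total" &
                                           roc_results$method == "youden"])
  }
  if ("p95" %in% config$cutoff_methods) {
    ir_cutoffs <- c(ir_cutoffs, "reference p95, total" = ref_p95_of("total"))
  }
  if (length(ir_cutoffs) == 0L) {
    ir_cutoffs <- c("reference p95, total" = ref_p95_of("total"))
  }
  prevalence <- pipeline_stage("prevalence", q,
    prevalence_of_ir(cohort, profiles, weight, ir_cutoffs))

  seed_used <- if (!is.null(config$generator)) config$generator$seed
               else config$seed
  manifest <- list(
    seed = seed_used,
    quantile_convention = "linear interpolation at rank 1 + (n-1)p (type 7)",
    n_subjects = nrow(cohort),
    n_ms = sum(profiles$ms),
    ms_prevalence_pct = 100 * mean(profiles$ms),
    n_reference = nrow(reference),
    age_group_width = config$age_group_width,
    n_height_bands = config$n_height_bands,
    fixed_cuts = list(
      tg_mmol_l = unname(thresholds$fixed[["tg"]]),
      hdl_mmol_l = unname(thresholds$fixed[["hdl"]]),
      glucose_mmol_l = unname(thresholds$fixed[["glucose"]]),
      provenance = "fixed modified-ATP III cuts"
    ),
    wc_p90 = list(values = thresholds$wc,
                  provenance = "cohort-derived 90th percentiles"),
    bp_p95 = list(values = thresholds$bp,
                  provenance = "cohort-derived 95th percentiles"),
    quintile_bounds = list(values = qs$bounds,
                           provenance = "cohort HOMA-IR 20/40/60/80th percentiles"),
    reference_p95 = list(values = reference_table,
                         provenance = "reference-population 95th percentiles"),
    roc_cutoffs = list(values = roc_results,
                       provenance = "ROC-optimal and p95 operating points"),
    ir_cutoffs = list(values = as.list(ir_cutoffs),
                      provenance = "cut-offs applied in prevalence tables"),
    quintile_or = quintile_or,
    cohort_summary = cohort_summary,
    prevalence = prevalence$prevalence,
    weight_status_chi_sq = prevalence$weight_status_chi_sq
  )

  report <- structure(
    list(
      cohort_summary = cohort_summary,
      quintile_or = quintile_or,
      reference_table = reference_table,
      roc_results = roc_results,
      prevalence = prevalence,
      thresholds = thresholds,
      quintile_bounds = qs$bounds,
      manifest = manifest
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    log_stage(q, "report written to %s", config$out_dir)
  }
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits the human-readable tables as TSV and the complete
#' machine-readable manifest as JSON. Every number in the TSV tables also
#' appears in the manifest.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$cohort_summary,
                   file.path(dir, "cohort_summary.tsv"))
  readr::write_tsv(report$quintile_or, file.path(dir, "quintile_or.tsv"))
  readr::write_tsv(report$reference_table,
                   file.path(dir, "reference_p95.tsv"))
  readr::write_tsv(report$roc_results, file.path(dir, "roc_cutoffs.tsv"))
  readr::write_tsv(report$prevalence$prevalence,
                   file.path(dir, "prevalence.tsv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  subjects: %d  MS: %d (%.1f%%)  reference: %d\n",
              x$manifest$n_subjects, x$manifest$n_ms,
              x$manifest$ms_prevalence_pct, x$manifest$n_reference))
  cat(sprintf("  HOMA-IR quintile bounds: %s\n",
              paste(signif(x$quintile_bounds, 3), collapse = ", ")))
  tot <- x$roc_results[x$roc_results$stratum == "total", ]
  if (nrow(tot)) {
    cat(sprintf("  total-cohort AUC: %.3f\n", tot$auc[1]))
  }
  invisible(x)
}
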