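# Smoothed age-sex median height curves (cm), linearly interpolated at
# continuous ages; anchors follow typical East-Asian school-age growth.
height_mean <- function(age, sex) {
  ages <- 6:18
  male <- c(117, 123, 128.5, 134, 139.5, 145, 151.5, 158.5, 165, 169.5,
            172, 173.5, 174.5)
  female <- c(116, 122, 128, 134, 140, 146.5, 152.5, 156.5, 158.5, 159.5,
              160, 160.5, 161)
  hm <- stats::approx(ages, male, xout = age, rule = 2)$y
  hf <- stats::approx(ages, female, xout = age, rule = 2)$y
  ifelse(sex == "M", hm, hf)
}

tanner_band <- function(tanner) {
  dplyr::case_when(
    tanner == 1L ~ "I",
    tanner %in% 2:4 ~ "II-IV",
    tanner == 5L ~ "V"
  )
}

#' Generate a seeded synthetic pediatric screening cohort
#'
#' Draws `n_subjects` children with the joint structure the downstream
#' analysis assumes: sex Bernoulli, age uniform over `age_range`, Tanner
#' stage sampled from the per-age probability table, and a latent
#' adiposity/insulin-resistance factor `Z ~ N(0,1)` on which BMI, waist
#' circumference, body fat, blood pressure, triglycerides (log scale),
#' HDL-C, fasting glucose and fasting insulin (log scale) all load. Insulin
#' is log-normal with a Tanner-band geometric mean, so the marginal
#' geometric mean per band equals the configured value. Height is drawn
#' around an age-sex growth curve and weight is back-computed from BMI, so
#' `bmi == weight / (height/100)^2` holds exactly.
#'
#' Identical configuration and seed reproduce the identical cohort,
#' field for field; the caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()]; its `seed` must be set.
#'
#' @return A tibble with one row per subject and columns `id`, `sex`
#'   (`"M"`/`"F"`), `age` (years), `tanner` (1-5), `height` (cm), `weight`
#'   (kg), `bmi` (kg/m2), `wc` (cm), `fat_pct` (%), `sbp`/`dbp` (mmHg),
#'   `tc`/`tg`/`hdl`/`ldl` (mmol/L), `glucose` (mmol/L, fasting),
#'   `insulin` (mU/L, fasting). The seed is carried in attribute `seed`
#'   and a free-text label in attribute `provenance`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1, n_subjects = 200))
#' dplyr::glimpse(cohort)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a `cohort_config` object", call. = FALSE)
  }
  if (is.null(config$seed)) {
    stop("`config$seed` is missing; generation must be seeded", call. = FALSE)
  }
  n <- config$n_subjects
  lam <- config$latent_effect_sizes
  nsd <- config$component_noise_sd
  withr::with_seed(config$seed, {
    sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    tam <- config$tanner_age_map
    rows <- match(as.character(floor(age)), rownames(tam))
    tanner <- vapply(
      rows,
      function(r) sample.int(5L, 1L, prob = tam[r, ]),
      integer(1)
    )
    z <- stats::rnorm(n)
    male <- as.numeric(sex == "M")

    bmi <- 15.8 + 0.40 * (age - 6) + 0.3 * male +
      lam[["bmi"]] * z + stats::rnorm(n, 0, nsd[["bmi"]])
    bmi <- pmax(bmi, 11)
    height <- pmax(height_mean(age, sex) + stats::rnorm(n, 0, nsd[["height"]]),
                   95)
    weight <- bmi * (height / 100)^2

    wc <- ifelse(sex == "M", 53 + 1.55 * (age - 6), 51.5 + 1.35 * (age - 6)) +
      lam[["wc"]] * z + stats::rnorm(n, 0, nsd[["wc"]])
    wc <- pmax(wc, 38)
    fat_pct <- ifelse(sex == "M", 17 + 0.15 * (age - 6),
                      21 + 0.45 * (age - 6)) +
      lam[["fat_pct"]] * z + stats::rnorm(n, 0, nsd[["fat_pct"]])
    fat_pct <- pmin(pmax(fat_pct, 3), 60)

    sbp <- 94 + 1.6 * (age - 6) + 1.5 * male +
      lam[["sbp"]] * z + stats::rnorm(n, 0, nsd[["sbp"]])
    dbp <- 57 + 0.95 * (age - 6) +
      lam[["dbp"]] * z + stats::rnorm(n, 0, nsd[["dbp"]])
    sbp <- pmax(sbp, 65); dbp <- pmax(dbp, 35)

    tc <- pmax(4.05 + 0.05 * z + stats::rnorm(n, 0, nsd[["tc"]]), 1.5)
    ldl <- pmax(2.45 + 0.08 * z + stats::rnorm(n, 0, nsd[["ldl"]]), 0.3)
    tg <- exp(log(0.92) + lam[["tg"]] * z + stats::rnorm(n, 0, nsd[["tg"]]))
    hdl <- pmax(1.42 + lam[["hdl"]] * z + stats::rnorm(n, 0, nsd[["hdl"]]),
                0.3)

    glucose <- pmax(
      config$glucose_mean_sd[["mean"]] + lam[["glucose"]] * z +
        stats::rnorm(n, 0, config$glucose_mean_sd[["sd"]]),
      2.5
    )
    gm <- config$insulin_stage_geomeans[tanner_band(tanner)]
    insulin <- exp(log(gm) + lam[["insulin"]] * z +
                     stats::rnorm(n, 0, nsd[["insulin"]]))

    cohort <- tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      sex = sex, age = age, tanner = as.integer(tanner),
      height = height, weight = weight, bmi = bmi,
      wc = wc, fat_pct = fat_pct, sbp = sbp, dbp = dbp,
      tc = tc, tg = tg, hdl = hdl, ldl = ldl,
      glucose = glucose, insulin = insulin
    )
    attr(cohort, "seed") <- config$seed
    attr(cohort, "provenance") <- sprintf(
      "homacut synthetic cohort (n=%d, seed=%d)", n, config$seed
    )
    cohort
  })
}

#' Summarise a cohort by number of metabolic-syndrome components
#'
#' Groups subjects into 0 / 1 / 2 / >=3 abnormal components and reports per
#' group: sex counts and mean and SD of age, Tanner stage, BMI, waist,
#' body fat, blood pressures, lipids, glucose, insulin and HOMA-IR. The
#' right-skewed variables (TG, insulin, HOMA-IR) are summarised on the log
#' scale and back-transformed, so their "mean" is the geometric mean and
#' their SD the back-transformed log-scale SD; these rows carry
#' `log_scale = TRUE`. Empty groups are emitted with `n = 0` and `NA`
#' summaries rather than dropped.
#'
#' @param cohort A cohort tibble (see [generate_cohort()] for the schema).
#' @param profiles Per-subject component profiles from
#'   [classify_components()], aligned to `cohort` by `id`.
#'
#' @return A tibble with one row per (component group, variable):
#'   `component_group` (ordered factor `0 < 1 < 2 < >=3`), `group_n`,
#'   `group_n_male`, `group_n_female`, `variable`, `mean`, `sd`,
#'   `log_scale`.
#' @export
summarize_by_component_count <- function(cohort, profiles) {
  if (!all(cohort$id %in% profiles$id) || nrow(profiles) != nrow(cohort)) {
    stop("`profiles` must align one-to-one with `cohort` by id",
         call. = FALSE)
  }
  dat <- dplyr::inner_join(cohort, profiles[, c("id", "count")], by = "id")
  dat$homa_ir <- homa_ir(dat$insulin, dat$glucose)
  grp_levels <- c("0", "1", "2", ">=3")
  dat$component_group <- factor(
    ifelse(dat$count >= 3, ">=3", as.character(dat$count)),
    levels = grp_levels, ordered = TRUE
  )
  vars_linear <- c("age", "tanner", "bmi", "wc", "fat_pct", "sbp", "dbp",
                   "tc", "hdl", "ldl", "glucose")
  vars_log <- c("tg", "insulin", "homa_ir")

  one_group <- function(g) {
    sub <- dat[dat$component_group == g, ]
    n <- nrow(sub)
    summarise_var <- function(v, log_scale) {
      x <- sub[[v]]
      if (n == 0L) {
        m <- s <- NA_real_
      } else if (log_scale) {
        m <- exp(mean(log(x)))
        s <- if (n > 1L) exp(stats::sd(log(x))) else NA_real_
      } else {
        m <- mean(x)
        s <- if (n > 1L) stats::sd(x) else NA_real_
      }
      tibble::tibble(variable = v, mean = m, sd = s, log_scale = log_scale)
    }
    rows <- dplyr::bind_rows(
      purrr::map(vars_linear, summarise_var, log_scale = FALSE),
      purrr::map(vars_log, summarise_var, log_scale = TRUE)
    )
    tibble::tibble(
      component_group = factor(g, levels = grp_levels, ordered = TRUE),
      group_n = n,
      group_n_male = sum(sub$sex == "M"),
      group_n_female = sum(sub$sex == "F"),
      rows
    )
  }
  dplyr::bind_rows(purrr::map(grp_levels, one_group))
}
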