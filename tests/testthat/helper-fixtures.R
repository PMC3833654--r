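# Hand-buildable subject rows with physiologically unremarkable defaults;
# override any field to construct a case.
make_subject <- function(id = "S1", sex = "M", age = 10, tanner = 2,
                         height = 140, bmi = 17.5, wc = 60, fat_pct = 20,
                         sbp = 100, dbp = 62, tc = 4.0, tg = 0.8,
                         hdl = 1.5, ldl = 2.4, glucose = 4.8,
                         insulin = 6) {
  tibble::tibble(
    id = id, sex = sex, age = age, tanner = as.integer(tanner),
    height = height, weight = bmi * (height / 100)^2, bmi = bmi,
    wc = wc, fat_pct = fat_pct, sbp = sbp, dbp = dbp, tc = tc, tg = tg,
    hdl = hdl, ldl = ldl, glucose = glucose, insulin = insulin
  )
}

make_cohort <- function(...) {
  dplyr::bind_rows(...)
}

# Thresholds object assembled by hand for single-stratum fixtures.
make_flat_thresholds <- function(wc_p90 = 70, sbp_p95 = 120, dbp_p95 = 80,
                                 age_min = 6, age_group_width = 20) {
  ages <- age_min
  structure(
    list(
      wc = tibble::tibble(
        age_group = rep(ages, 2), sex = c("M", "F"),
        n = 100L, wc_p90 = wc_p90
      ),
      bp = tibble::tibble(
        age_group = rep(ages, 2), sex = c("M", "F"), height_band = 1L,
        height_lo = -Inf, height_hi = Inf, n = 100L,
        sbp_p95 = sbp_p95, dbp_p95 = dbp_p95
      ),
      fixed = c(tg = 1.24, hdl = 1.03, glucose = 5.6),
      age_min = age_min, age_group_width = age_group_width,
      n_height_bands = 1
    ),
    class = "ms_thresholds"
  )
}

# Independent ROC oracles: plain loops over all positive-negative pairs
# and over all candidate cut-offs, kept free of the package's vectorised
# path.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

oracle_sens_spec <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  called <- scores > cutoff
  c(sens = sum(called & labels) / sum(labels),
    spec = sum(!called & !labels) / sum(!labels))
}

oracle_best_cutoff <- function(scores, labels, method) {
  cands <- c(min(scores) - 1, sort(unique(scores)))
  best <- NULL
  for (ct in cands) {
    ss <- oracle_sens_spec(scores, labels, ct)
    j <- ss[["sens"]] + ss[["spec"]] - 1
    d <- (1 - ss[["sens"]])^2 + (1 - ss[["spec"]])^2
    cand <- list(cutoff = ct, youden = j, dist = d)
    if (is.null(best)) { best <- cand; next }
    better <- if (method == "youden") {
      (j > best$youden + 1e-12) ||
        (abs(j - best$youden) <= 1e-12 && d < best$dist - 1e-12)
    } else {
      (d < best$dist - 1e-12) ||
        (abs(d - best$dist) <= 1e-12 && j > best$youden + 1e-12)
    }
    if (better) best <- cand
    # equal on both criteria keeps the smaller cutoff: cands are sorted
  }
  best
}
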