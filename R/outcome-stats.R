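#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator of the survival function (computed via
#' \pkg{survival}), returned as a tidy step-function table. The estimate
#' starts at S(0) = 1 and decreases only at observed event times; censored
#' follow-up reduces the risk set without a step.
#'
#' @param records Data frame with `time_months` (> 0) and `event`
#'   (1 = death observed, 0 = censored); an optional `group` column fits one
#'   curve per group.
#' @return Tibble: `group` (if any), `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`. Attribute `median` holds the median survival
#'   per group (NA when the curve never reaches 0.5).
#' @examples
#' km_estimate(tibble::tibble(time_months = 1:3, event = 1))$survival
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  has_group <- "group" %in% names(records)
  f <- if (has_group) {
    survival::survfit(survival::Surv(time_months, event) ~ group,
                      data = records)
  } else {
    survival::survfit(survival::Surv(time_months, event) ~ 1,
                      data = records)
  }
  s <- summary(f, censored = TRUE)
  out <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv
  )
  med <- summary(f)$table
  if (has_group) {
    out <- dplyr::mutate(out,
                         group = sub("^group=", "", as.character(s$strata)),
                         .before = 1)
    attr(out, "median") <- setNames(med[, "median"],
                                    sub("^group=", "", rownames(med)))
  } else {
    attr(out, "median") <- unname(med["median"])
  }
  out
}

check_survival_records <- function(records) {
  need <- c("time_months", "event")
  if (length(setdiff(need, names(records))) > 0) {
    abort("survival records need `time_months` and `event` columns.")
  }
  if (any(!is.finite(records$time_months)) || any(records$time_months <= 0)) {
    abort("survival times must be positive and finite.")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death observed).")
  }
  invisible(records)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank test of equal survival; the statistic is
#' chi-squared with 1 degree of freedom under the null.
#'
#' @param records Survival records (`time_months`, `event`).
#' @param group Two-level grouping vector aligned with `records` (or the
#'   name of a column of `records`).
#' @return Tibble: `statistic`, `p_value`, `n_low`/`n_high` per-group sizes
#'   (named after sorted group levels), `median` survival per group.
#' @export
logrank_test <- function(records, group = "group") {
  check_survival_records(records)
  g <- if (is.character(group) && length(group) == 1 &&
           group %in% names(records)) {
    records[[group]]
  } else {
    group
  }
  g <- factor(g)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    abort("logrank_test requires exactly 2 non-empty groups.")
  }
  df <- tibble::tibble(time_months = records$time_months,
                       event = records$event, g = g)
  if (sum(df$event) == 0) {
    warn("no events observed; log-rank statistic defined as 0.")
    stat <- 0
  } else {
    sd_fit <- survival::survdiff(survival::Surv(time_months, event) ~ g,
                                 data = df)
    stat <- sd_fit$chisq
  }
  med <- vapply(levels(g), function(lv) {
    unname(attr(km_estimate(df[df$g == lv, ]), "median"))
  }, numeric(1))
  tibble::tibble(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    group1 = levels(g)[1], group2 = levels(g)[2],
    n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2]),
    median1 = med[1], median2 = med[2]
  )
}

#' Dichotomize a patient-level covariate
#'
#' Splits patients into two groups for survival comparison.
#'
#' * `median_split` (default): values at or below the median are `"low"`,
#'   values above are `"high"` (ties go to `"low"`, deterministically).
#' * `threshold`: same split at a supplied cutoff.
#' * `short_long_term`: for follow-up times in months — `"short"` below 12
#'   months, `"long"` above 24 months, intermediate patients dropped (`NA`).
#'
#' @param values Numeric covariate, one per patient.
#' @param rule Splitting rule.
#' @param threshold Cutoff for `rule = "threshold"`.
#' @return Factor aligned with `values` (`low`/`high`, or `short`/`long`
#'   with `NA` for dropped patients).
#' @examples
#' dichotomize(c(1, 2, 3, 4))
#' @export
dichotomize <- function(values,
                        rule = c("median_split", "threshold",
                                 "short_long_term"),
                        threshold = NULL) {
  rule <- match.arg(rule)
  if (rule == "short_long_term") {
    lab <- dplyr::case_when(values < 12 ~ "short",
                            values > 24 ~ "long",
                            TRUE ~ NA_character_)
    return(factor(lab, levels = c("short", "long")))
  }
  cut_at <- if (rule == "median_split") {
    if (length(values) < 2) abort("median_split needs at least 2 patients.")
    stats::median(values)
  } else {
    if (is.null(threshold)) abort("`threshold` rule needs a cutoff value.")
    threshold
  }
  lab <- ifelse(values <= cut_at, "low", "high")
  if (length(unique(stats::na.omit(lab))) < 2) {
    abort("dichotomization produced a single group (no split exists).")
  }
  factor(lab, levels = c("low", "high"))
}

#' Group comparisons: t-tests and one-way ANOVA with Bonferroni correction
#'
#' Unpaired comparisons use two-tailed Student's t-tests (pooled variance);
#' paired data use the paired t-test; for more than two groups a one-way
#' ANOVA is followed by Bonferroni-adjusted pairwise t-tests (each pairwise
#' p multiplied by the number of comparisons, capped at 1). Groups with zero
#' variance and equal means return t = 0, p = 1 by convention (logged).
#'
#' @param values Numeric measurements.
#' @param group Grouping vector aligned with `values`.
#' @param design `"two_sample_t"`, `"paired_t"`, or `"anova_bonferroni"`.
#' @return Tibble, one row per comparison: `comparison`, `statistic`
#'   (t, or F for the ANOVA row), `p_value`, `p_adjusted`, `significance`.
#' @export
compare_groups <- function(values, group,
                           design = c("two_sample_t", "paired_t",
                                      "anova_bonferroni")) {
  design <- match.arg(design)
  g <- factor(group)
  if (design %in% c("two_sample_t", "paired_t") && nlevels(g) != 2) {
    abort("t-test designs require exactly 2 groups.")
  }
  safe_t <- function(x, y, paired = FALSE) {
    if (sd(c(x, y)) == 0) {
      inform("compare_groups: zero variance with equal means; p = 1 convention.")
      return(list(statistic = 0, p.value = 1))
    }
    stats::t.test(x, y, paired = paired, var.equal = TRUE)
  }
  lv <- levels(g)
  if (design != "anova_bonferroni") {
    x <- values[g == lv[1]]
    y <- values[g == lv[2]]
    tt <- safe_t(x, y, paired = design == "paired_t")
    out <- tibble::tibble(
      comparison = paste(lv[1], "vs", lv[2]),
      statistic = unname(tt$statistic),
      p_value = tt$p.value,
      p_adjusted = tt$p.value
    )
  } else {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1]]
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    m <- length(pairs)
    rows <- purrr::map(pairs, function(pr) {
      tt <- safe_t(values[g == pr[1]], values[g == pr[2]])
      tibble::tibble(
        comparison = paste(pr[1], "vs", pr[2]),
        statistic = unname(tt$statistic),
        p_value = tt$p.value,
        p_adjusted = min(1, m * tt$p.value)
      )
    })
    out <- dplyr::bind_rows(
      tibble::tibble(
        comparison = "ANOVA (overall)",
        statistic = an[["F value"]][1],
        p_value = an[["Pr(>F)"]][1],
        p_adjusted = an[["Pr(>F)"]][1]
      ),
      purrr::list_rbind(rows)
    )
  }
  dplyr::mutate(out, significance = significance_stars(.data$p_adjusted))
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (n >= 3, finite). Zero variance in either
#'   vector makes the correlation undefined; `NA` is returned with a
#'   warning.
#' @return Tibble: `r`, `p_value`, `n`, `significance`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("pearson_correlation needs paired vectors of length >= 3.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("pearson_correlation requires finite values.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined.")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                          significance = NA_character_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
    significance = significance_stars(ct$p.value)
  )
}
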