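#' Summarize a case-control cohort
#'
#' Counts, per-sex control-to-case ratios (controls per case, reported to one
#' decimal as "1:x"), the male balding-pattern distribution, and median /
#' interquartile-range age by sex and hospitalization status.
#'
#' @param phenotypes Phenotype data.frame as produced by
#'   [simulate_phenotypes()] or [read_phenotypes()].
#' @return An object of class `cohort_summary`.
#' @examples
#' ph <- data.frame(individual_id = 1:4, sex = c("male", "male", "female", "female"),
#'                  age_at_assessment = 60, age_at_event = 65,
#'                  aga_pattern = c(1L, 4L, NA, NA),
#'                  sars_cov2_positive = TRUE,
#'                  hospitalized = c(TRUE, FALSE, FALSE, TRUE))
#' summarize_cohort(ph)
#' @export
summarize_cohort <- function(phenotypes) {
  if (nrow(phenotypes) == 0L) stopf("empty phenotype table")
  male <- phenotypes[phenotypes$sex == "male", , drop = FALSE]
  female <- phenotypes[phenotypes$sex == "female", , drop = FALSE]
  ratio <- function(n_total, n_cases) {
    if (n_cases == 0L) return(NA_real_)  # undefined marker, not a crash
    round((n_total - n_cases) / n_cases, 1)
  }
  n_hosp_m <- sum(male$hospitalized)
  n_hosp_f <- sum(female$hospitalized)
  pat <- male$aga_pattern[!is.na(male$aga_pattern)]
  pattern_freq <- if (length(pat) > 0L) {
    as.vector(table(factor(pat, levels = 1:4)) / length(pat))
  } else rep(NA_real_, 4)
  age_stats <- function(x) {
    if (length(x) == 0L) return(c(median = NA_real_, iqr = NA_real_))
    c(median = stats::median(x), iqr = stats::IQR(x))
  }
  out <- list(
    n_total = nrow(phenotypes),
    n_male = nrow(male), n_female = nrow(female),
    n_hospitalized_male = n_hosp_m, n_hospitalized_female = n_hosp_f,
    control_case_ratio_male = ratio(nrow(male), n_hosp_m),
    control_case_ratio_female = ratio(nrow(female), n_hosp_f),
    aga_pattern_freq = stats::setNames(pattern_freq, paste0("pattern_", 1:4)),
    n_male_with_pattern = length(pat),
    age = list(
      male = age_stats(male$age_at_event),
      female = age_stats(female$age_at_event),
      male_hospitalized = age_stats(male$age_at_event[male$hospitalized]),
      female_hospitalized = age_stats(female$age_at_event[female$hospitalized]),
      male_non_hospitalized = age_stats(male$age_at_event[!male$hospitalized]),
      female_non_hospitalized = age_stats(female$age_at_event[!female$hospitalized])
    )
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_ratio <- function(r) if (is.na(r)) "undefined" else sprintf("1:%.1f", r)
  cat(sprintf("Cohort: %d individuals (%d men, %d women)\n",
              x$n_total, x$n_male, x$n_female))
  cat(sprintf("  hospitalized: %d men (ratio %s), %d women (ratio %s)\n",
              x$n_hospitalized_male, fmt_ratio(x$control_case_ratio_male),
              x$n_hospitalized_female, fmt_ratio(x$control_case_ratio_female)))
  if (x$n_male_with_pattern > 0L) {
    cat(sprintf("  AGA patterns 1-4 among %d men: %s\n", x$n_male_with_pattern,
                paste(sprintf("%.0f%%", 100 * x$aga_pattern_freq), collapse = " / ")))
  }
  cat(sprintf("  median age at event (men %.0f, women %.0f; hospitalized %.0f / %.0f)\n",
              x$age$male["median"], x$age$female["median"],
              x$age$male_hospitalized["median"], x$age$female_hospitalized["median"]))
  invisible(x)
}

#' Residualize the balding pattern on age at assessment
#'
#' First stage of the age-corrected association analysis: ordinary least
#' squares of the numeric pattern (1-4) on age at assessment, among males
#' with a non-missing pattern. The returned residuals (named by individual
#' id) carry no linear age trend and sum to zero.
#'
#' @param phenotypes Phenotype data.frame.
#' @return Named numeric vector of residuals for males with a pattern, with
#'   attributes `intercept` and `slope` from the first-stage fit.
#' @export
residualize_aga_on_age <- function(phenotypes) {
  d <- phenotypes[phenotypes$sex == "male" & !is.na(phenotypes$aga_pattern), ,
                  drop = FALSE]
  if (nrow(d) < 3L) stopf("need at least 3 males with a non-missing pattern")
  if (stats::var(d$age_at_assessment) == 0) {
    stopf("rank-deficient first stage: age at assessment is constant")
  }
  if (stats::var(as.numeric(d$aga_pattern)) == 0) {
    warnf("balding pattern is constant; all residuals are zero")
    res <- rep(0, nrow(d))
    names(res) <- d$individual_id
    attr(res, "intercept") <- d$aga_pattern[1]
    attr(res, "slope") <- 0
    return(res)
  }
  fit <- stats::lm(as.numeric(aga_pattern) ~ age_at_assessment, data = d)
  res <- stats::residuals(fit)
  names(res) <- d$individual_id
  attr(res, "intercept") <- unname(stats::coef(fit)[1])
  attr(res, "slope") <- unname(stats::coef(fit)[2])
  res
}

#' Age-corrected logistic regression of hospitalization on balding residuals
#'
#' Second stage of the two-stage analysis: maximum-likelihood logistic
#' regression of hospitalization on (intercept, age-residualized balding
#' pattern, age at event), among the males carrying residuals, optionally
#' restricted to an age-at-event window (e.g. `c(52, 59)` for the subset in
#' which the severe-balding prevalence ratio is largest). The reported
#' coefficient is the residual term; standard errors come from the observed
#' information and the p-value is a two-sided Wald test.
#'
#' @param phenotypes Phenotype data.frame.
#' @param residuals Named residual vector from [residualize_aga_on_age()].
#' @param age_window Optional length-2 inclusive age-at-event window.
#' @return An object of class `aga_covid_regression` with elements `beta`,
#'   `se`, `p`, `n`, `n_cases`, `age_window`.
#' @export
regress_severity_on_aga <- function(phenotypes, residuals, age_window = NULL) {
  d <- phenotypes[match(names(residuals), phenotypes$individual_id), ,
                  drop = FALSE]
  d$aga_residual <- as.numeric(residuals)
  if (!is.null(age_window)) {
    keep <- d$age_at_event >= age_window[1] & d$age_at_event <= age_window[2]
    d <- d[keep, , drop = FALSE]
    if (nrow(d) == 0L) stopf("age window [%g, %g] contains no individuals",
                             age_window[1], age_window[2])
  }
  if (sum(d$hospitalized) == 0L || sum(!d$hospitalized) == 0L) {
    stopf("need at least one case and one control in the analysis window")
  }
  fit <- stats::glm(hospitalized ~ aga_residual + age_at_event,
                    data = d, family = stats::binomial())
  if (!fit$converged) {
    stopf("logistic regression did not converge (possible complete separation)")
  }
  mu <- stats::fitted(fit)
  if (max(mu) > 1 - 1e-8 || min(mu) < 1e-8) {
    stopf("complete or quasi-complete separation in the logistic regression")
  }
  cf <- summary(fit)$coefficients["aga_residual", ]
  out <- list(beta = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
              p = unname(cf["Pr(>|z|)"]), n = nrow(d),
              n_cases = sum(d$hospitalized),
              age_window = age_window %||% "full")
  class(out) <- "aga_covid_regression"
  out
}

#' @export
print.aga_covid_regression <- function(x, ...) {
  win <- if (identical(x$age_window, "full")) "full cohort" else
    sprintf("ages %g-%g", x$age_window[1], x$age_window[2])
  cat(sprintf("Age-corrected AGA ~ severe COVID-19 regression (%s)\n", win))
  cat(sprintf("  beta = %.3f, se = %.3f, p = %.3g (n = %d, %d cases)\n",
              x$beta, x$se, x$p, x$n, x$n_cases))
  invisible(x)
}

default_age_bins <- function() {
  data.frame(lo = c(52, 55, 60, 65, 70, 75, 80),
             hi = c(54, 59, 64, 69, 74, 79, 83))
}

#' Prevalence of severe balding by age group
#'
#' Compares the prevalence of severe balding between hospitalized males and
#' a general male population, across age groups, under either of two
#' severity definitions: patterns 3 and 4 combined, or pattern 4 only (the
#' definition that matters when reconciling cohorts scored with different
#' pictogram criteria).
#'
#' @param phenotypes Phenotype data.frame; its hospitalized males form the
#'   case series.
#' @param general_population Phenotype data.frame for the reference
#'   population; all its males with a non-missing pattern are used.
#' @param definition `"patterns_3_and_4"` or `"pattern_4_only"`.
#' @param bins Data.frame with columns `lo`, `hi` of inclusive age bounds.
#'   Defaults to seven groups: 52-54, 55-59, then 5-year bins to 79, and
#'   80-83.
#' @return A `prevalence_table`: data.frame with one row per bin carrying
#'   prevalences and counts for both cohorts. Empty bins report `NA`
#'   prevalence with a zero count.
#' @export
prevalence_by_age_group <- function(phenotypes, general_population,
                                    definition = c("patterns_3_and_4",
                                                   "pattern_4_only"),
                                    bins = default_age_bins()) {
  definition <- match.arg(definition)
  if (any(bins$lo > bins$hi) || is.unsorted(bins$lo)) {
    stopf("age bins must be ordered and non-degenerate")
  }
  if (nrow(bins) > 1L && any(bins$lo[-1] <= bins$hi[-nrow(bins)])) {
    stopf("age bins must not overlap")
  }
  severe <- function(pat) {
    if (definition == "patterns_3_and_4") pat >= 3L else pat == 4L
  }
  extract <- function(d, hospitalized_only) {
    d <- d[d$sex == "male" & !is.na(d$aga_pattern), , drop = FALSE]
    if (hospitalized_only) d <- d[d$hospitalized, , drop = FALSE]
    d
  }
  hosp <- extract(phenotypes, TRUE)
  gen <- extract(general_population, FALSE)
  if (nrow(hosp) == 0L || nrow(gen) == 0L) {
    stopf("both cohorts must contain males with a non-missing pattern")
  }
  per_bin <- function(d, lo, hi) {
    in_bin <- d$age_at_event >= lo & d$age_at_event <= hi
    n <- sum(in_bin)
    prev <- if (n == 0L) NA_real_ else mean(severe(d$aga_pattern[in_bin]))
    c(n = n, prev = prev)
  }
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    h <- per_bin(hosp, bins$lo[i], bins$hi[i])
    g <- per_bin(gen, bins$lo[i], bins$hi[i])
    data.frame(age_group = sprintf("%g-%g", bins$lo[i], bins$hi[i]),
               lo = bins$lo[i], hi = bins$hi[i],
               n_hospitalized = h["n"], prev_hospitalized = h["prev"],
               n_general = g["n"], prev_general = g["prev"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "definition") <- definition
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Plot severe-balding prevalence by age group
#'
#' Grouped bar plot of the prevalence of severe balding among hospitalized
#' men versus the general male population, one bar pair per age group.
#'
#' @param x A `prevalence_table`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.prevalence_table <- function(x, ...) {
  mat <- rbind(hospitalized = x$prev_hospitalized,
               general = x$prev_general)
  graphics::barplot(mat, beside = TRUE, names.arg = x$age_group,
                    ylim = c(0, 1), ylab = "Prevalence of severe AGA",
                    xlab = "Age group (years)",
                    legend.text = rownames(mat),
                    main = sprintf("Severity definition: %s",
                                   attr(x, "definition")), ...)
  invisible(x)
}
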