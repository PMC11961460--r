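#' Annual eGFR slope by ordinary least squares
#'
#' Slope of eGFR regressed on time, the standard summary of kidney-function
#' decline (mL/min/1.73 m2 per year).
#'
#' @param times observation times in years (length >= 2, not all identical).
#' @param egfr_values eGFR values, same length.
#' @return OLS slope.
#' @export
egfr_slope <- function(times, egfr_values) {
  if (length(times) != length(egfr_values))
    stop("times and egfr_values must have equal length")
  if (length(times) < 2L) stop("at least 2 time points are required")
  if (stats::var(times) == 0) stop("all observation times are identical")
  unname(stats::coef(stats::lm(egfr_values ~ times))[2])
}

#' Progressor classification from the eGFR slope
#'
#' A patient is a progressor when the annual eGFR decline (`-slope`) exceeds
#' the cutoff. The default cutoff is 1.9 mL/min/1.73 m2/year, the decline
#' under which the packaged cohort yields exactly the four progressors whose
#' published group medians it reproduces; the alternative literal cutoff of
#' 1.0 (which yields five) is available via `cutoff`.
#'
#' @param slope annual eGFR slope (negative = declining).
#' @param cutoff decline cutoff, mL/min/1.73 m2/year.
#' @return Logical (vectorized over `slope`).
#' @export
classify_progressor <- function(slope, cutoff = 1.9) {
  if (any(!is.finite(slope))) stop("slope must be finite")
  -slope > cutoff
}

#' Descriptive summary of a continuous variable
#'
#' Mean with sample SD (n-1 denominator), median and quartiles by linear
#' interpolation at position `(n-1)*q` on the sorted sample (R quantile
#' type 7) -- the convention that reproduces the published IQRs of the
#' packaged cohort.
#'
#' @param values non-empty numeric vector.
#' @return List: `n`, `mean`, `sd` (`NA` for n = 1), `median`, `q1`, `q3`.
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("values must be non-empty and finite")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(values), mean = mean(values), sd = stats::sd(values),
       median = q[2], q1 = q[1], q3 = q[3])
}

#' Two-group comparison with normality-guided test choice
#'
#' Compares two groups with Student's t test (equal-variance, two-sided) when
#' the data look normal and the Kruskal-Wallis rank test (with tie
#' correction) otherwise. By default normality is screened with a
#' Shapiro-Wilk test at `alpha` on the pooled group-centered residuals -- the
#' residuals are what the t test assumes normal, and pooling is the only
#' option when a group is too small to screen on its own (Shapiro-Wilk needs
#' n >= 3). `normality = "per_group"` screens each group of size >= 3
#' separately instead; `test` forces a specific test.
#'
#' @param a,b numeric vectors (non-empty).
#' @param test `"auto"` (default), `"student_t"` or `"kruskal_wallis"`.
#' @param normality `"residuals"` or `"per_group"` screening for `"auto"`.
#' @param alpha significance level of the normality screen.
#' @return List of class `group_comparison`: `group_a`, `group_b`
#'   (descriptive summaries), `test_name`, `statistic`, `p_value`,
#'   `normality_p`.
#' @export
compare_groups <- function(a, b, test = c("auto", "student_t", "kruskal_wallis"),
                           normality = c("residuals", "per_group"),
                           alpha = 0.05) {
  test <- match.arg(test)
  normality <- match.arg(normality)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")

  sw <- function(x) {
    if (length(x) < 3L || stats::var(x) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  normality_p <- switch(normality,
    residuals = sw(c(a - mean(a), b - mean(b))),
    per_group = {
      ps <- c(sw(a), sw(b))
      if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
    })
  if (test == "auto")
    test <- if (!is.na(normality_p) && normality_p > alpha) "student_t"
            else "kruskal_wallis"

  if (test == "student_t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("Student t test requires at least 2 observations per group")
    ht <- stats::t.test(a, b, var.equal = TRUE)
  } else {
    if (stats::var(c(a, b)) == 0) {          # fully tied data: no difference
      ht <- list(statistic = c(chisq = 0), p.value = 1)
    } else {
      ht <- stats::kruskal.test(list(a, b))
    }
  }
  structure(list(group_a = describe(a), group_b = describe(b),
                 test_name = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 normality_p = normality_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test_name, ": statistic ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Correlation with normality-guided method choice
#'
#' Pearson's coefficient for normal-looking data, Spearman's rank coefficient
#' otherwise (screened per vector by Shapiro-Wilk at `alpha`); either can be
#' forced.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param alpha significance level of the normality screen.
#' @return Correlation coefficient in \[-1, 1\], with attribute `method`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  if (method == "auto") {
    px <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
    py <- tryCatch(stats::shapiro.test(y)$p.value, error = function(e) 0)
    method <- if (px > alpha && py > alpha) "pearson" else "spearman"
  }
  structure(stats::cor(x, y, method = method), method = method)
}

#' Full cohort characterization report
#'
#' Recomputes the package's entire cohort analysis from a cohort table:
#' clinical counts, overall volumetric summaries, Class 2A vs 2B group
#' summaries and tests, eGFR-slope summary, progressor classification and
#' progressor vs non-progressor comparisons, and the Class 2 prevalence given
#' the total number of MRI-staged patients.
#'
#' @param cohort a cohort `data.frame` as returned by [load_cohort()].
#' @param total_mri total MRI-evaluated ADPKD population the cohort was drawn
#'   from (for the prevalence figure), default 124.
#' @param progressor_cutoff decline cutoff for [classify_progressor()].
#' @return A nested list of class `cohort_report`; see Details.
#' @details The report contains: `n`, `prevalence_percent`, `class_counts`,
#'   `clinical` (counts/percentages and age/creatinine/eGFR summaries),
#'   `overall` (describe() of htTKV, TCV, TCV\%, RTV), `by_class` (per-variable
#'   2A/2B summaries and [compare_groups()] results, including the three
#'   volume ratios), `slope` (describe() of the annual eGFR slopes),
#'   `progressors` (ids, per-variable progressor vs non-progressor summaries
#'   and tests).
#' @export
summarize_cohort <- function(cohort, total_mri = 124,
                             progressor_cutoff = 1.9) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 2)
  cohort$rtv_over_tcv <- cohort$rtv / cohort$tcv
  cohort$rtv_over_tkv <- cohort$rtv / cohort$httkv
  cohort$tcv_over_tkv <- cohort$tcv / cohort$httkv

  pct <- function(k) 100 * k / nrow(cohort)
  clinical <- list(
    n = nrow(cohort),
    hypertension_n = sum(cohort$hypertension),
    hypertension_percent = pct(sum(cohort$hypertension)),
    family_history_n = sum(cohort$family_history_positive),
    family_history_percent = pct(sum(cohort$family_history_positive)),
    egfr_below_60_n = sum(cohort$egfr < 60),
    egfr_below_60_percent = pct(sum(cohort$egfr < 60)),
    extrarenal_n = sum(cohort$extrarenal_involvement),
    extrarenal_percent = pct(sum(cohort$extrarenal_involvement)),
    referral = as.list(table(cohort$referral_reason)),
    age = describe(cohort$age),
    serum_creatinine = describe(cohort$serum_creatinine),
    egfr = describe(cohort$egfr))

  vol_vars <- c("httkv", "tcv", "tcv_percent", "rtv")
  ratio_vars <- c("rtv_over_tcv", "rtv_over_tkv", "tcv_over_tkv")
  overall <- lapply(cohort[vol_vars], describe)

  is_a <- cohort$mayo_class == "2A"
  by_class <- lapply(cohort[c(vol_vars, ratio_vars)], function(x)
    list(class_2a = describe(x[is_a]), class_2b = describe(x[!is_a]),
         comparison = compare_groups(x[is_a], x[!is_a])))
  by_class$egfr <- list(class_2a = describe(cohort$egfr[is_a]),
                        class_2b = describe(cohort$egfr[!is_a]),
                        comparison = compare_groups(cohort$egfr[is_a],
                                                    cohort$egfr[!is_a]))
  by_class$egfr_slope <- list(
    class_2a = describe(cohort$egfr_slope[is_a]),
    class_2b = describe(cohort$egfr_slope[!is_a]),
    comparison = compare_groups(cohort$egfr_slope[is_a],
                                cohort$egfr_slope[!is_a]))

  prog <- classify_progressor(cohort$egfr_slope, cutoff = progressor_cutoff)
  progressors <- list(
    cutoff = progressor_cutoff,
    n_progressors = sum(prog),
    progressor_ids = cohort$patient_id[prog])
  for (v in c(vol_vars[vol_vars != "tcv_percent"], ratio_vars)) {
    progressors[[v]] <- list(
      progressor = describe(cohort[[v]][prog]),
      non_progressor = describe(cohort[[v]][!prog]),
      comparison = compare_groups(cohort[[v]][prog], cohort[[v]][!prog]))
  }

  structure(list(
    n = nrow(cohort),
    total_mri = total_mri,
    prevalence_percent = 100 * nrow(cohort) / total_mri,
    class_counts = as.list(table(cohort$mayo_class)),
    pattern_counts = as.list(table(cohort$pattern)),
    clinical = clinical,
    overall = overall,
    by_class = by_class,
    slope = describe(cohort$egfr_slope),
    progressors = progressors), class = "cohort_report")
}

#' Render a cohort table in Markdown
#'
#' A per-patient Markdown table of the imaging variables, mirroring the
#' layout of the package's reference cohort table, with a mean +/- SD footer.
#'
#' @param cohort cohort `data.frame` as from [load_cohort()].
#' @return Character vector of Markdown lines.
#' @export
cohort_table_md <- function(cohort) {
  f <- function(m, s) sprintf("%.1f ± %.1f", m, s)
  rows <- sprintf("| Pt%d | %s | %s | %d | %d | %.1f | %d |",
                  cohort$patient_id, gsub("_", " ", cohort$pattern),
                  cohort$mayo_class, cohort$httkv, cohort$tcv,
                  cohort$tcv_percent, cohort$rtv)
  c("| Patient | Type | Class | htTKV [mL/m] | TCV [mL/m] | TCV [%] | RTV [mL/m] |",
    "|---|---|---|---|---|---|---|",
    rows,
    sprintf("| Mean | | | %s | %s | %s | %s |",
            f(mean(cohort$httkv), stats::sd(cohort$httkv)),
            f(mean(cohort$tcv), stats::sd(cohort$tcv)),
            f(mean(cohort$tcv_percent), stats::sd(cohort$tcv_percent)),
            f(mean(cohort$rtv), stats::sd(cohort$rtv))))
}

#' Write a cohort report as JSON
#'
#' @param report a [summarize_cohort()] result.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  jsonlite::write_json(unclass_recursive(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}
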