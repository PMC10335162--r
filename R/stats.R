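#' Per-measurement cohort summary
#'
#' Sample mean, SD (n - 1 denominator) and n for every numeric measurement
#' column. With a single record the SD is reported as 0 and flagged.
#'
#' @param records data.frame of measurement records (one row per subject),
#'   e.g. rbind-ed output of [measure_subject()].
#' @return data.frame with columns `measurement`, `mean`, `sd`, `n`,
#'   `sd_defined`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1)
    fm_param_error("records must be a non-empty data.frame")
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  n <- nrow(records)
  out <- data.frame(
    measurement = num,
    mean = vapply(num, function(c) mean(records[[c]]), numeric(1)),
    sd = if (n > 1) vapply(num, function(c) stats::sd(records[[c]]),
                           numeric(1)) else rep(0, length(num)),
    n = n,
    sd_defined = n > 1,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Two-group comparison report
#'
#' One row per shared numeric measurement column: group means and SDs, the
#' two-sided test statistic and p-value, and a significance flag at
#' alpha = 0.05. The default test is Welch's t (robust to unequal
#' variances); Student's t and the Mann-Whitney U test are available.
#' Optionally appends Benjamini-Hochberg adjusted p-values.
#'
#' @param group_a,group_b data.frames of measurement records.
#' @param method `"welch_t"`, `"student_t"` or `"mann_whitney"`.
#' @param alpha Significance level for the flag.
#' @param adjust If `TRUE`, add a `p_adj` (Benjamini-Hochberg) column.
#' @return data.frame of comparison rows.
#' @export
compare_groups <- function(group_a, group_b,
                           method = c("welch_t", "student_t", "mann_whitney"),
                           alpha = 0.05, adjust = FALSE) {
  method <- match.arg(method)
  num_a <- names(group_a)[vapply(group_a, is.numeric, logical(1))]
  num_b <- names(group_b)[vapply(group_b, is.numeric, logical(1))]
  if (!setequal(num_a, num_b))
    fm_schema_error(paste0("column sets differ: ",
                           paste(union(setdiff(num_a, num_b),
                                       setdiff(num_b, num_a)),
                                 collapse = ", ")))
  if (nrow(group_a) < 2 || nrow(group_b) < 2)
    fm_param_error("each group needs n >= 2")
  rows <- lapply(num_a, function(col) {
    a <- group_a[[col]]; b <- group_b[[col]]
    res <- tryCatch(switch(method,
      welch_t = stats::t.test(a, b, var.equal = FALSE),
      student_t = stats::t.test(a, b, var.equal = TRUE),
      mann_whitney = suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))),
      error = function(e) NULL)
    if (!is.null(res) && is.nan(res$p.value)) res <- NULL
    if (is.null(res)) {
      # (near-)constant data in both groups: the t statistic is undefined.
      # Equal means are a perfect null (p = 1), unequal means a perfect
      # separation (p = 0).
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      res <- list(statistic = if (eq) 0 else Inf,
                  p.value = if (eq) 1 else 0)
    }
    data.frame(measurement = col,
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               test = method,
               statistic = unname(res$statistic),
               p_value = res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out
}

# Two-sided Wilcoxon signed-rank p-value. Zero differences are dropped
# (Wilcoxon convention); with no ties in |d| and n <= exact_max the exact
# null distribution (psignrank) is used, otherwise a normal approximation
# with tie correction and continuity correction.
signed_rank_p <- function(d, exact_max = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p = 1, statistic = NA_real_, n_used = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_max) {
    p <- if (W > n * (n + 1) / 4)
      stats::psignrank(W - 1, n, lower.tail = FALSE) * 2
    else
      stats::psignrank(W, n) * 2
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p = p, statistic = W, n_used = n)
}

#' Paired method-validation comparison
#'
#' Compares a set of measurements produced by this pipeline against paired
#' reference measurements (e.g. manual ruler measurements of the same
#' segments): reports the mean and SD of the absolute differences and a
#' two-sided Wilcoxon signed-rank p-value for the paired differences
#' (exact for n <= 25 when tie-free; zero differences dropped; all-zero
#' differences reported as p = 1).
#'
#' @param method_values,reference_values Equal-length numeric vectors
#'   (n >= 5), paired by index.
#' @return List with `mean_abs_diff`, `sd_abs_diff`, `p_value`,
#'   `statistic`, `n`, `n_used`.
#' @export
paired_validation <- function(method_values, reference_values) {
  if (length(method_values) != length(reference_values))
    fm_schema_error("paired vectors must have equal length")
  n <- length(method_values)
  if (n < 5) fm_param_error("paired validation needs n >= 5")
  d <- method_values - reference_values
  sr <- signed_rank_p(d)
  list(mean_abs_diff = mean(abs(d)),
       sd_abs_diff = stats::sd(abs(d)),
       p_value = sr$p,
       statistic = sr$statistic,
       n = n, n_used = sr$n_used)
}

#' Render a comparison report as a Markdown table
#'
#' Mirrors the published table layout: measurement, group A mean +/- SD,
#' group B mean +/- SD, P, with a star on significant rows.
#'
#' @param cmp Output of [compare_groups()].
#' @param label_a,label_b Column headers for the two groups.
#' @return Character vector of Markdown lines.
#' @export
comparison_markdown <- function(cmp, label_a = "Group A", label_b = "Group B") {
  fmt <- function(m, s) sprintf("%.3f ± %.3f", m, s)
  c(sprintf("| Measurement | %s | %s | P |", label_a, label_b),
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %.4g%s |",
            cmp$measurement,
            fmt(cmp$mean_a, cmp$sd_a), fmt(cmp$mean_b, cmp$sd_b),
            cmp$p_value, ifelse(cmp$significant, " *", "")))
}
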