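#' Two-sample Student t-test from summary statistics
#'
#' Pooled-variance two-sample t with `n1 + n2 - 2` degrees of freedom,
#' computed from group means, standard deviations and sizes (the form needed
#' to check published summary tables). Two-sided p-value.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p_value`.
#' @export
ttest_student <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p_value = 1))
    stop("zero variance in both groups with unequal means")
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test of a 2x2 table
#'
#' Pearson chi-square with one degree of freedom; the Yates continuity
#' correction is applied by default, matching common practice for 2x2
#' case-control heterogeneity tables.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return List with `statistic`, `p_value`.
#' @export
chisq_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square test undefined")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Case/control cohort description with heterogeneity tests
#'
#' Group-wise summaries (mean and SD for quantitative variables; counts and
#' one-decimal percentages for categorical ones), combined-cohort summaries,
#' and per-variable case/control heterogeneity p-values: pooled Student
#' t-test for quantitative variables, chi-square for categorical (Yates
#' correction when 2x2).
#'
#' @param samples Sample table with a `status` column.
#' @param quantitative Character vector of quantitative variable names.
#' @param categorical Character vector of categorical variable names.
#' @return An object of class `cohort_summary`: list with `n` (named counts),
#'   `quantitative` (data frame), `categorical` (data frame).
#' @export
cohort_summary <- function(samples, quantitative = "age",
                           categorical = "ethnicity") {
  samples <- validate_samples(samples)
  if (nrow(samples) == 0L) stop("empty cohort")
  vars <- c(quantitative, categorical)
  missing_vars <- setdiff(vars, names(samples))
  if (length(missing_vars))
    stop("variable(s) not in sample table: ",
         paste(missing_vars, collapse = ", "))
  cases <- samples[samples$status == 1, , drop = FALSE]
  controls <- samples[samples$status == 0, , drop = FALSE]
  qrows <- lapply(quantitative, function(v) {
    x1 <- cases[[v]]; x0 <- controls[[v]]
    if (length(x1) < 2 || length(x0) < 2)
      stop("variable '", v, "': standard deviation undefined with fewer ",
           "than 2 observations per group")
    tt <- ttest_student(mean(x1), stats::sd(x1), length(x1),
                        mean(x0), stats::sd(x0), length(x0))
    data.frame(variable = v,
               case_mean = mean(x1), case_sd = stats::sd(x1),
               control_mean = mean(x0), control_sd = stats::sd(x0),
               combined_mean = mean(samples[[v]]),
               combined_sd = stats::sd(samples[[v]]),
               p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  crows <- lapply(categorical, function(v) {
    tab <- table(factor(samples[[v]]), factor(samples$status,
                                              levels = c(1, 0)))
    counts1 <- tab[, 1]; counts0 <- tab[, 2]
    p <- if (nrow(tab) == 2)
      chisq_2x2(cbind(counts1, counts0))$p_value
    else
      suppressWarnings(stats::chisq.test(tab))$p.value
    data.frame(variable = v, level = rownames(tab),
               case_n = as.integer(counts1),
               case_pct = round(100 * counts1 / sum(counts1), 1),
               control_n = as.integer(counts0),
               control_pct = round(100 * counts0 / sum(counts0), 1),
               combined_n = as.integer(counts1 + counts0),
               combined_pct = round(100 * (counts1 + counts0) /
                                      sum(tab), 1),
               p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(list(n = c(cases = nrow(cases), controls = nrow(controls),
                       total = nrow(samples)),
                 quantitative = do.call(rbind, qrows),
                 categorical = do.call(rbind, crows)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary:", x$n["cases"], "cases /", x$n["controls"],
      "controls\n\n")
  print(x$quantitative, row.names = FALSE)
  cat("\n")
  print(x$categorical, row.names = FALSE)
  invisible(x)
}
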