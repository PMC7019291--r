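# Rest-versus-test comparison of each index: Kolmogorov-Smirnov normality
# screen, then a paired t-test for normal indices or a two-sided Wilcoxon
# rank sum test otherwise. p < 0.05 is reported significant, with no
# multiple-testing correction (matching the reporting convention of the
# study design this reproduces).

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the standardized values against the standard
#' normal. The sample is judged normal when p >= 0.05. Standardizing by
#' the sample mean/SD makes the test anti-conservative (the Lilliefors
#' issue), which is accepted here as the conventional screen.
#'
#' @param values numeric sample, n >= 4.
#' @return list with `normal` (logical), `p_value`, and `degenerate`
#'   (TRUE for zero-variance samples, judged non-normal by convention).
#' @export
test_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 values")
  if (stats::sd(values) == 0) {
    return(list(normal = FALSE, p_value = 0, degenerate = TRUE))
  }
  z <- (values - mean(values)) / stats::sd(values)
  p <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  list(normal = p >= 0.05, p_value = p, degenerate = FALSE)
}

#' Compare rest and test samples of one index
#'
#' Paired t-test when the index is normally distributed; two-sided
#' Wilcoxon rank sum test on the two samples otherwise. (The rank sum
#' variant is applied unpaired; `paired_t` switches the t-test between
#' paired and unpaired forms.)
#'
#' @param rest,test equal-length numeric samples (one value per subject).
#' @param normal treat the index as normally distributed.
#' @param paired_t use the paired form of the t-test.
#' @return list of class `comparison_result`: `test_used`, `p_value`,
#'   `significant` (p < 0.05).
#' @export
compare_rest_test <- function(rest, test, normal, paired_t = TRUE) {
  if (length(rest) < 2 || length(test) < 2) stop("need at least 2 values per sample")
  if (normal) {
    ht <- stats::t.test(rest, test, paired = paired_t)
    used <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(rest, test,
                                              alternative = "two.sided"))
    used <- "wilcoxon_rank_sum"
  }
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # identical constant samples
  structure(list(test_used = used, p_value = p, significant = p < 0.05),
            class = "comparison_result")
}

#' Rest-vs-test comparison report across indices and measurements
#'
#' For each index, pools all values (both stages, all measurements) for
#' the normality screen — so one test family is used consistently per
#' index — then compares rest against test within each measurement.
#'
#' @param rest_table,test_table feature tables (same row order; columns
#'   `subject`, `measurement` and the index columns).
#' @param indices index columns to compare.
#' @return data.frame with one row per (index, measurement): normality
#'   verdict, test used, p-value and significance flag.
#' @export
stats_report <- function(rest_table, test_table, indices = index_names()) {
  stopifnot(nrow(rest_table) == nrow(test_table),
            all(rest_table$subject == test_table$subject),
            all(rest_table$measurement == test_table$measurement))
  out <- list()
  for (ix in indices) {
    norm <- test_normality(c(rest_table[[ix]], test_table[[ix]]))
    for (m in sort(unique(rest_table$measurement))) {
      sel <- rest_table$measurement == m
      cmp <- compare_rest_test(rest_table[[ix]][sel], test_table[[ix]][sel],
                               normal = norm$normal)
      out[[length(out) + 1L]] <- data.frame(
        index = ix, measurement = m, normal = norm$normal,
        test_used = cmp$test_used, p_value = cmp$p_value,
        significant = cmp$significant,
        rest_mean = mean(rest_table[[ix]][sel]),
        test_mean = mean(test_table[[ix]][sel]))
    }
  }
  do.call(rbind, out)
}
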