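#' Significance label for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise
#' (the most significant applicable label).
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of labels.
#' @export
significance_label <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare a metric between the high- and low-nutrient stages
#'
#' Two-sided two-sample test of the metric values of the two stages. The
#' default is the Mann-Whitney U (Wilcoxon rank-sum) test, exact for small
#' tie-free samples and normal-approximated with tie correction otherwise;
#' `test = "welch"` uses Welch's t-test. Two identical groups (all values
#' tied) are reported as p = 1.
#'
#' @param high,low numeric vectors of metric values (each of length >= 3).
#' @param test `"mann_whitney"` (default) or `"welch"`.
#' @param metric optional metric name carried into the result.
#' @return object of class `group_comparison`: list with `metric`, `n_high`,
#'   `n_low`, `mean_high`, `mean_low`, `test`, `statistic`, `p_value`,
#'   `label`.
#' @export
compare_stages <- function(high, low, test = c("mann_whitney", "welch"),
                           metric = NULL) {
  test <- match.arg(test)
  high <- as.numeric(high[!is.na(high)])
  low <- as.numeric(low[!is.na(low)])
  if (length(high) < 3L || length(low) < 3L)
    stopf("each group needs at least 3 values (got %d and %d)",
          length(high), length(low))
  res <- if (test == "mann_whitney")
    suppressWarnings(stats::wilcox.test(high, low, exact = NULL))
  else
    stats::t.test(high, low)
  p <- res$p.value
  if (is.na(p)) p <- 1  # degenerate all-tied case: no evidence of difference
  out <- list(metric = metric %||% NA_character_,
              n_high = length(high), n_low = length(low),
              mean_high = mean(high), mean_low = mean(low),
              test = test, statistic = unname(res$statistic),
              p_value = p, label = significance_label(p))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: high (n=%d, mean %.4g) vs low (n=%d, mean %.4g), %s p = %.4g [%s]\n",
    x$metric, x$n_high, x$mean_high, x$n_low, x$mean_low, x$test,
    x$p_value, x$label))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(metric = x$metric, n_high = x$n_high, n_low = x$n_low,
             mean_high = x$mean_high, mean_low = x$mean_low,
             statistic = x$statistic, p_value = x$p_value, label = x$label,
             stringsAsFactors = FALSE)
}
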