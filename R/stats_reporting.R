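# Statistical summaries and reports: normal-approximation proportion CIs,
# chi-squared homogeneity tests of class distributions across conditions,
# two-proportion Z-tests, and a class-distribution report with CSV and plot
# export.

#' Normal-approximation 95% confidence interval for a proportion
#'
#' Wald interval `p_hat +/- 1.96 * sqrt(p_hat * (1 - p_hat) / n)`, clamped to
#' \[0, 1\].
#'
#' @param p_hat observed proportion in \[0, 1\].
#' @param n number of observations (positive).
#' @return numeric vector `c(lower, upper)`; attribute `half_width` carries
#'   the unclamped half-width.
#' @export
proportion_ci <- function(p_hat, n) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  stopifnot(p_hat >= 0, p_hat <= 1)
  hw <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  structure(c(max(0, p_hat - hw), min(1, p_hat + hw)), half_width = hw)
}

#' Chi-squared test of homogeneity of class distributions
#'
#' Tests whether class composition is the same across groups, on a
#' contingency table of counts (groups x classes), without continuity
#' correction. Zero-margin rows/columns are rejected with an informative
#' error rather than silently dropped.
#'
#' @param counts integer matrix of counts, rows = groups, columns = classes
#'   (or a data.frame coercible to one).
#' @return list: `statistic`, `df`, `p_value`, `expected` (all entries must
#'   be positive), `observed`.
#' @export
chi2_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stopf("need at least 2 groups and 2 classes")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("contingency table has an empty row or column margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stopf("expected counts must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = expected, observed = counts)
}

#' Two-proportion Z-test (pooled, two-sided)
#'
#' `Z = (p1 - p2) / sqrt(p * (1 - p) * (1/n1 + 1/n2))` with the pooled
#' proportion `p = (x1 + x2) / (n1 + n2)`; two-sided normal p-value. For a
#' 2-level comparison, `Z^2` equals the chi-squared homogeneity statistic
#' without continuity correction.
#'
#' @param x1,x2 success counts.
#' @param n1,n2 group sizes.
#' @return list: `statistic` (Z), `p_value`, `p1`, `p2`, `p_pooled`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(is_count(n1), is_count(n2), x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p <- (x1 + x2) / (n1 + n2)
  if (p == 0 || p == 1)
    stopf("pooled proportion is %g; the Z statistic is undefined", p)
  z <- (x1 / n1 - x2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       p1 = x1 / n1, p2 = x2 / n2, p_pooled = p)
}

#' Class-distribution report across condition groups
#'
#' Tabulates class counts and proportions per group, attaches per-proportion
#' 95% CIs, runs an overall chi-squared homogeneity test plus pairwise
#' group-vs-group tests, and optionally writes a CSV of the proportions and a
#' stacked-bar plot.
#'
#' @param classes class label per item.
#' @param groups condition label per item.
#' @param csv_path optional path for the proportions CSV.
#' @param plot_path optional path for a PDF stacked-proportion bar plot.
#' @return object of class `class_report`: `counts` (groups x classes),
#'   `proportions` (long data.frame with CIs), `overall_test`,
#'   `pairwise_tests`.
#' @export
class_distribution_report <- function(classes, groups, csv_path = NULL,
                                      plot_path = NULL) {
  stopifnot(length(classes) == length(groups), length(classes) > 0)
  classes <- as.character(classes); groups <- as.character(groups)
  counts <- table(group = groups, class = classes)
  cm <- matrix(as.integer(counts), nrow(counts), ncol(counts),
               dimnames = dimnames(counts))
  long <- do.call(rbind, lapply(rownames(cm), function(g) {
    n <- sum(cm[g, ])
    do.call(rbind, lapply(colnames(cm), function(cl) {
      k <- cm[g, cl]
      ci <- proportion_ci(k / n, n)
      data.frame(group = g, class = cl, n = n, count = k,
                 proportion = k / n, ci_lower = ci[1], ci_upper = ci[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  overall <- if (nrow(cm) >= 2 && ncol(cm) >= 2) chi2_homogeneity(cm) else NULL
  pw <- NULL
  gl <- rownames(cm)
  if (length(gl) >= 2 && ncol(cm) >= 2) {
    prs <- utils::combn(gl, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(prs, function(pr) {
      t2 <- chi2_homogeneity(cm[pr, , drop = FALSE])
      data.frame(group1 = pr[1], group2 = pr[2], statistic = t2$statistic,
                 df = t2$df, p_value = t2$p_value, stringsAsFactors = FALSE)
    }))
  }
  rep <- structure(list(counts = cm, proportions = long,
                        overall_test = overall, pairwise_tests = pw),
                   class = "class_report")
  if (!is.null(csv_path))
    utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::pdf(plot_path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    prop <- sweep(cm, 1, rowSums(cm), "/")
    graphics::barplot(t(prop), beside = FALSE, legend.text = colnames(cm),
                      ylab = "proportion", xlab = "condition",
                      main = "Class distribution by condition")
  }
  rep
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report: %d groups x %d classes>\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  if (!is.null(x$overall_test))
    cat(sprintf("overall chi-squared = %.3f, df = %d, p = %.3g\n",
                x$overall_test$statistic, x$overall_test$df,
                x$overall_test$p_value))
  invisible(x)
}
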