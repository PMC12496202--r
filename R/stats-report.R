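## Normality-gated statistical decision tree for group comparisons.

#' Compare two groups following the normality-gated decision tree
#'
#' Applies the analysis protocol used for all grouped measurements:
#' Shapiro-Wilk normality screening of each group at alpha = 0.05, then
#' \itemize{
#'   \item independent design, both groups normal: Welch two-sample
#'     t-test;
#'   \item independent design, any group non-normal: Mann-Whitney
#'     (Wilcoxon rank-sum) test;
#'   \item paired design: Wilcoxon signed-rank test.
#' }
#' All tests are two-sided. A Bonferroni correction for
#' \code{family_size} comparisons is applied:
#' \code{corrected_p = min(1, raw_p * family_size)}. The module's
#' contract is the decision logic and the report; the test procedures
#' themselves are delegated to the standard \pkg{stats} routines.
#'
#' An optional omnibus annotation (\code{omnibus_groups}) runs a
#' Kruskal-Wallis rank test across a wider set of groups and records its
#' p-value without gating the pairwise result, since pairwise p-values
#' are the primary report.
#'
#' @param samples List of exactly two numeric vectors (each n >= 3).
#' @param design "independent" or "paired" (paired requires equal
#'   lengths).
#' @param family_size Number of comparisons in the Bonferroni family
#'   (default 1).
#' @param test_override Optional: force "welch", "mann-whitney" or
#'   "wilcoxon-signed-rank" regardless of the normality gate.
#' @param omnibus_groups Optional list of >= 3 numeric vectors for the
#'   Kruskal-Wallis annotation.
#' @param alpha_normality Significance level of the Shapiro-Wilk gate
#'   (default 0.05).
#' @return A \code{"group_comparison"} object: \code{design},
#'   \code{normality_p}, \code{test}, \code{statistic}, \code{raw_p},
#'   \code{corrected_p}, \code{n_comparisons}, \code{omnibus_p}.
#' @export
#' @examples
#' compare_groups(list(a = rnorm(10), b = rnorm(10) + 2),
#'                design = "independent", family_size = 3)
compare_groups <- function(samples,
                           design = c("independent", "paired"),
                           family_size = 1,
                           test_override = NULL,
                           omnibus_groups = NULL,
                           alpha_normality = 0.05) {
  design <- match.arg(design)
  if (!is.list(samples) || length(samples) != 2L) {
    stop("`samples` must be a list of exactly two numeric vectors",
         call. = FALSE)
  }
  ns <- lengths(samples)
  if (any(ns < 3L)) stop("each group needs n >= 3", call. = FALSE)
  if (design == "paired" && ns[1] != ns[2]) {
    stop("paired design requires equal group lengths", call. = FALSE)
  }
  if (family_size < 1) stop("`family_size` must be >= 1", call. = FALSE)

  normality_p <- vapply(samples, function(v) {
    if (stats::sd(v) == 0) return(0) # constant data: not normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  all_normal <- all(normality_p >= alpha_normality)

  test <- if (!is.null(test_override)) {
    match.arg(test_override,
              c("welch", "mann-whitney", "wilcoxon-signed-rank"))
  } else if (design == "paired") {
    "wilcoxon-signed-rank"
  } else if (all_normal) {
    "welch"
  } else {
    "mann-whitney"
  }

  res <- if (test == "wilcoxon-signed-rank" &&
             all(samples[[1]] == samples[[2]])) {
    ## all paired differences zero: no evidence against the null
    list(statistic = c(V = 0), p.value = 1)
  } else {
    switch(test,
      "welch" = stats::t.test(samples[[1]], samples[[2]],
                              var.equal = FALSE),
      "mann-whitney" = stats::wilcox.test(samples[[1]], samples[[2]],
                                          exact = FALSE),
      "wilcoxon-signed-rank" = stats::wilcox.test(samples[[1]],
                                                  samples[[2]],
                                                  paired = TRUE,
                                                  exact = FALSE))
  }
  omnibus_p <- if (!is.null(omnibus_groups)) {
    stats::kruskal.test(omnibus_groups)$p.value
  } else {
    NA_real_
  }

  structure(
    list(design = design, normality_p = normality_p,
         test = test, statistic = unname(res$statistic),
         raw_p = res$p.value,
         corrected_p = min(1, res$p.value * family_size),
         n_comparisons = family_size,
         omnibus_p = omnibus_p),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (%s design): statistic = %.4g, raw p = %.3g, Bonferroni p (x%d) = %.3g\n",
    x$test, x$design, x$statistic, x$raw_p, x$n_comparisons,
    x$corrected_p))
  if (!is.na(x$omnibus_p)) {
    cat(sprintf("  omnibus (Kruskal-Wallis) p = %.3g\n", x$omnibus_p))
  }
  invisible(x)
}
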