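#' Normality gate
#'
#' The entry point of the statistical decision tree: a Shapiro-Wilk test
#' decides whether a sample is treated as normally distributed
#' (`p >= alpha`, parametric branch) or skewed (`p < alpha`,
#' rank-based branch).
#'
#' @param x numeric sample, `n >= 3`, not all equal.
#' @param alpha gate level (default 0.05).
#' @return `"normal"` or `"skewed"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stop("normality gate needs n >= 3")
  if (stats::sd(x) == 0) stop("constant sample: Shapiro-Wilk W undefined")
  if (stats::shapiro.test(x)$p.value >= alpha) "normal" else "skewed"
}

new_test_result <- function(method, statistic, df, p_value) {
  structure(list(method = method, statistic = unname(statistic),
                 df = if (is.null(df)) NA_real_ else unname(df),
                 p_value = unname(p_value), stars = star_map(p_value)),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g, df=%s, p=%.4g %s\n", x$method,
              x$statistic, format(x$df), x$p_value, x$stars))
  invisible(x)
}

#' One-sample location test with normality routing
#'
#' Compares one dataset against a hypothesised location (a mean of 0 for
#' log2 ratios, i.e. a 1:1 ratio): a two-sided single-sample t-test when
#' the sample passes the normality gate, otherwise a two-sided Wilcoxon
#' signed-rank test against the same null.
#'
#' @param x numeric sample, `n >= 3`.
#' @param null_value hypothesised mean/median (default 0).
#' @param alpha normality-gate level.
#' @return a `TestResult`.
#' @export
one_sample_location_test <- function(x, null_value = 0, alpha = 0.05) {
  if (length(x) < 3L) stop("need n >= 3")
  branch <- normality_gate(x, alpha)
  if (branch == "normal") {
    ht <- stats::t.test(x, mu = null_value)
    new_test_result("one-sample t", ht$statistic, ht$parameter, ht$p.value)
  } else {
    if (all(x == null_value))
      stop("all values equal the null: signed-rank test undefined")
    ht <- stats::wilcox.test(x, mu = null_value, exact = FALSE,
                             correct = FALSE)
    new_test_result("Wilcoxon signed-rank", ht$statistic, NULL, ht$p.value)
  }
}

#' Unpaired two-sample t-test
#'
#' Compares two independent datasets with a two-sided unpaired t-test;
#' equal-variance (Student) by default, Welch via `welch = TRUE`.
#'
#' @param x,y numeric samples, each `n >= 3`.
#' @param welch use the Welch unequal-variance form.
#' @return a `TestResult`.
#' @export
two_sample_test <- function(x, y, welch = FALSE) {
  if (length(x) < 3L || length(y) < 3L) stop("need n >= 3 in both samples")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both samples degenerate: t statistic undefined")
  ht <- stats::t.test(x, y, var.equal = !welch)
  new_test_result(if (welch) "Welch two-sample t" else "two-sample t",
                  ht$statistic, ht$parameter, ht$p.value)
}

#' Pearson chi-square test
#'
#' Compares category distributions.  Two modes: independence on an R x C
#' contingency table (`expected` omitted; expected counts from the
#' margins, `df = (R-1)(C-1)`), or goodness-of-fit of observed counts
#' against expected proportions (`df = C-1`).  No continuity correction in
#' either mode.
#'
#' @param observed matrix of counts (independence) or vector of counts
#'   (goodness-of-fit).
#' @param expected_proportions proportions summing to 1, goodness-of-fit
#'   mode only.
#' @return a `TestResult`.
#' @examples
#' chisq_test(matrix(c(10, 20, 20, 10), 2))      # X2 = 20/3
#' chisq_test(c(70, 30), c(0.5, 0.5))            # X2 = 16
#' @export
chisq_test <- function(observed, expected_proportions = NULL) {
  if (is.null(expected_proportions)) {
    observed <- as.matrix(observed)
    expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
    if (any(expected == 0)) stop("expected count of 0 in the table")
    ht <- stats::chisq.test(observed, correct = FALSE)
    new_test_result("chi-square-independence", ht$statistic, ht$parameter,
                    ht$p.value)
  } else {
    observed <- as.numeric(observed)
    if (length(observed) != length(expected_proportions))
      stop("observed and expected proportions differ in length")
    if (any(expected_proportions * sum(observed) == 0))
      stop("expected count of 0")
    ht <- stats::chisq.test(observed, p = expected_proportions)
    new_test_result("chi-square-gof", ht$statistic, ht$parameter,
                    ht$p.value)
  }
}

#' Significance stars
#'
#' The asterisk convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.  Cutoffs are strict, so a p-value
#' exactly equal to a cutoff takes the less significant label.
#'
#' @param p_value numeric in `[0, 1]`.
#' @return character scalar.
#' @export
star_map <- function(p_value) {
  if (is.na(p_value) || p_value < 0 || p_value > 1)
    stop("p-value must be in [0, 1]")
  if (p_value < 0.0001) "****"
  else if (p_value < 0.001) "***"
  else if (p_value < 0.01) "**"
  else if (p_value < 0.05) "*"
  else "ns"
}
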