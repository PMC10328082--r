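#' Sister-chromatid segregation ratio
#'
#' The anaphase/telophase segregation ratio: the background-corrected
#' old-histone total of the sister-chromatid set with the higher value
#' divided by the set with the lower value.  By construction the ratio is
#' `>= 1` and symmetric in its arguments.  Ratios are computed from the
#' old-histone channel only; new-histone signal is still being deposited in
#' mitosis and is not a reliable partition readout.
#'
#' @param total_a,total_b background-corrected old-histone totals of the
#'   two sister-chromatid sets; both must be positive (a non-positive total
#'   signals a failed background correction upstream).
#' @return numeric ratio `>= 1`.
#' @examples
#' chromatid_ratio(135, 100)  # 1.35
#' @export
chromatid_ratio <- function(total_a, total_b) {
  if (any(is.na(c(total_a, total_b))) || total_a <= 0 || total_b <= 0)
    stop("both chromatid totals must be positive ",
         "(non-positive totals signal a failed background correction)")
  max(total_a, total_b) / min(total_a, total_b)
}

#' Control-derived asymmetry thresholds
#'
#' Category boundaries for segregation ratios are derived from a control
#' ratio distribution (a histone expected to segregate symmetrically, e.g.
#' H2A): the symmetric range ends at `mean + 1 * sd` and the medium
#' asymmetric range at `mean + 2 * sd`.  The sample (n-1) standard
#' deviation is used.  Reported thresholds are conventionally quoted to two
#' decimals, but classification uses the unrounded values.
#'
#' @param control_ratios numeric vector of `>= 2` control segregation
#'   ratios.
#' @param control_label name of the control dataset (annotation only).
#' @return an `AsymmetryThresholds`: list with `mu`, `sigma`, `t_med`
#'   (`mu + sigma`), `t_high` (`mu + 2 sigma`), `n_control`,
#'   `control_label`.
#' @examples
#' derive_thresholds(c(1.0, 1.1, 1.2))  # t_med 1.20, t_high 1.30
#' @export
derive_thresholds <- function(control_ratios, control_label = "control") {
  control_ratios <- as.numeric(control_ratios)
  if (length(control_ratios) < 2L || any(is.na(control_ratios)))
    stop("need at least 2 non-missing control ratios")
  mu <- mean(control_ratios)
  sigma <- stats::sd(control_ratios)
  asymmetry_thresholds(mu, sigma, n_control = length(control_ratios),
                       control_label = control_label)
}

#' @rdname derive_thresholds
#' @param mu,sigma summary statistics of the control distribution, for when
#'   only the published mean and standard deviation are available.
#' @param n_control control sample size (may be `NA` when unknown).
#' @export
asymmetry_thresholds <- function(mu, sigma, n_control = NA_integer_,
                                 control_label = "control") {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(mu = mu, sigma = sigma,
                 t_med = mu + sigma, t_high = mu + 2 * sigma,
                 n_control = n_control, control_label = control_label),
            class = "AsymmetryThresholds")
}

#' @export
print.AsymmetryThresholds <- function(x, ...) {
  cat(sprintf(
    "AsymmetryThresholds (%s, n=%s): mu=%.3f sd=%.3f -> t_med=%.2f t_high=%.2f\n",
    x$control_label, x$n_control, x$mu, x$sigma, x$t_med, x$t_high))
  invisible(x)
}

#' Classify a segregation ratio
#'
#' Assigns a ratio to one of three asymmetry categories using
#' control-derived thresholds: `symmetric` for ratios `<= t_med`, `medium`
#' for ratios in `(t_med, t_high]`, `high` for ratios `> t_high`.  With the
#' canonical control thresholds (1.15, 1.22) this reads: symmetric
#' <= 1.15-fold, medium 1.16- to 1.22-fold, high > 1.22-fold.
#'
#' @param ratio numeric vector of segregation ratios (`>= 1`).
#' @param thresholds an [asymmetry_thresholds()] object.
#' @return character vector, levels `symmetric`, `medium`, `high`.
#' @export
classify_ratio <- function(ratio, thresholds) {
  stopifnot(inherits(thresholds, "AsymmetryThresholds"))
  if (any(ratio < 1, na.rm = TRUE))
    stop("segregation ratios are max/min and must be >= 1")
  ifelse(ratio <= thresholds$t_med, "symmetric",
         ifelse(ratio <= thresholds$t_high, "medium", "high"))
}

#' Category percentages of a ratio set
#'
#' Percentage of cells in each asymmetry category; percentages sum to 100
#' before rounding and are conventionally reported to one decimal.
#'
#' @param ratios numeric vector of segregation ratios.
#' @param thresholds an [asymmetry_thresholds()] object.
#' @return named numeric vector `c(symmetric=, medium=, high=)` in percent.
#' @export
category_percentages <- function(ratios, thresholds) {
  if (length(ratios) == 0L) stop("need at least one ratio")
  cls <- factor(classify_ratio(ratios, thresholds),
                levels = c("symmetric", "medium", "high"))
  pct <- 100 * as.vector(table(cls)) / length(ratios)
  names(pct) <- levels(cls)
  pct
}
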