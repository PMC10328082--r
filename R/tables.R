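# Synthetic stand-ins for per-cell supplementary value tables.
#
# The published per-cell measurement tables are not redistributable, so
# these generators plant deterministic tables that carry the published
# summary statistics exactly; the pipeline then has to *recompute* those
# summaries from the per-cell values.  They are synthetic constructions,
# not the original data.

#' Synthetic per-cell ratio and log2 tables with planted summaries
#'
#' Deterministic synthetic tables standing in for the per-cell
#' supplementary values behind the published anaphase/telophase and
#' postmitotic-pair summaries:
#'
#' * `synthetic_ratio_table_h3()`: 32 old-H3 segregation ratios with
#'   19/5/8 cells in the high/medium/symmetric categories (59.4% / 15.6% /
#'   25.0%) and mean exactly 1.35;
#' * `synthetic_ratio_table_h2a()`: 20 old-H2A control ratios with 18/1/1
#'   cells in the symmetric/medium/high categories (90% / 5% / 5%) and
#'   mean 1.08;
#' * `synthetic_pair_log2_table()`: 33 per-pair old-H3 log2 ratios with
#'   mean exactly 0.65.
#'
#' @return numeric vector of per-cell values.
#' @name synthetic_tables
NULL

#' @rdname synthetic_tables
#' @export
synthetic_ratio_table_h3 <- function() {
  sym <- seq(1.03, 1.15, length.out = 8)
  med <- seq(1.16, 1.22, length.out = 5)
  # high-band values chosen so the full-table mean is exactly 1.35
  high_mean <- (1.35 * 32 - sum(sym) - sum(med)) / 19
  high <- high_mean + seq(-0.18, 0.18, length.out = 19)
  c(sym, med, high)
}

#' @rdname synthetic_tables
#' @export
synthetic_ratio_table_h2a <- function() {
  med <- 1.19
  high <- 1.25
  sym_mean <- (1.08 * 20 - med - high) / 18
  sym <- sym_mean + seq(-0.04, 0.04, length.out = 18)
  c(sym, med, high)
}

#' @rdname synthetic_tables
#' @export
synthetic_pair_log2_table <- function() {
  0.65 + seq(-0.32, 0.32, length.out = 33)
}
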