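#' Postmitotic pair eligibility filter
#'
#' Applies the eligibility rules for postmitotic pairs of daughter cells:
#' the two nuclei must lie within `max_distance_um` (5 um) of each other,
#' neither cell may be more than `max_size_ratio` (1.5x) larger than the
#' other by diameter (excluding polyploid enterocytes), both cells must be
#' EdU negative (not in or just after S phase), and both must carry
#' quantifiable old- and new-histone totals (corrected totals above
#' `quant_floor`).  Every rejected pair is recorded with the first rule it
#' failed.
#'
#' @param cells list of `CellMeasurement`s (or a data.frame with columns
#'   `cell_id`, `x_um`, `y_um`, `diameter_um`, `edu_positive`, `old`,
#'   `new`, `delta`).
#' @param candidates two-column matrix/data.frame of candidate pair indices
#'   into `cells`, or `NULL` to consider every pair within
#'   `max_distance_um`.
#' @param max_distance_um maximum centroid separation (default 5).
#' @param max_size_ratio maximum diameter ratio (default 1.5).
#' @param quant_floor quantifiability floor on corrected totals
#'   (default 0: totals must be strictly positive).
#' @param old_channel,new_channel,delta_channel channel names in the
#'   measurements.
#' @return list with `eligible` (data.frame of index pairs `i`, `j`) and
#'   `rejected` (data.frame of `i`, `j`, `reason`).
#' @export
pair_filter <- function(cells, candidates = NULL,
                        max_distance_um = 5, max_size_ratio = 1.5,
                        quant_floor = 0,
                        old_channel = "old", new_channel = "new",
                        delta_channel = "DlnLacZ") {
  tab <- cells_to_table(cells, old_channel, new_channel, delta_channel)
  n <- nrow(tab)
  if (is.null(candidates)) {
    if (n < 2L)
      return(list(eligible = data.frame(i = integer(), j = integer()),
                  rejected = data.frame(i = integer(), j = integer(),
                                        reason = character())))
    cand <- t(utils::combn(n, 2L))
  } else {
    cand <- as.matrix(candidates)[, 1:2, drop = FALSE]
  }

  dist_um <- sqrt((tab$x_um[cand[, 1L]] - tab$x_um[cand[, 2L]])^2 +
                  (tab$y_um[cand[, 1L]] - tab$y_um[cand[, 2L]])^2)
  if (is.null(candidates)) {
    keep0 <- dist_um <= max_distance_um
    cand <- cand[keep0, , drop = FALSE]
    dist_um <- dist_um[keep0]
  }

  reasons <- character(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    d1 <- tab$diameter_um[i]; d2 <- tab$diameter_um[j]
    if (dist_um[k] > max_distance_um) {
      reasons[k] <- "distance"
    } else if (max(d1, d2) / min(d1, d2) > max_size_ratio) {
      reasons[k] <- "size"
    } else if (isTRUE(tab$edu_positive[i]) || isTRUE(tab$edu_positive[j])) {
      reasons[k] <- "EdU"
    } else if (is.na(tab$edu_positive[i]) || is.na(tab$edu_positive[j])) {
      reasons[k] <- "EdU_unknown"
    } else if (min(tab$old[i], tab$old[j], tab$new[i], tab$new[j]) <=
               quant_floor) {
      reasons[k] <- "quantifiability"
    }
  }
  ok <- reasons == ""
  list(eligible = data.frame(i = cand[ok, 1L], j = cand[ok, 2L]),
       rejected = data.frame(i = cand[!ok, 1L], j = cand[!ok, 2L],
                             reason = reasons[!ok]))
}

cells_to_table <- function(cells, old_channel = "old", new_channel = "new",
                           delta_channel = "DlnLacZ") {
  if (is.data.frame(cells)) {
    need <- c("cell_id", "x_um", "y_um", "diameter_um", "edu_positive",
              "old", "new", "delta")
    miss <- setdiff(need, names(cells))
    if (length(miss))
      stop("cell table missing columns: ", paste(miss, collapse = ", "))
    return(cells)
  }
  get_tot <- function(cm, ch) {
    if (!ch %in% names(cm$totals))
      stop("cell '", cm$cell_id, "' has no total for channel '", ch, "'")
    cm$totals[[ch]]
  }
  data.frame(
    cell_id = vapply(cells, `[[`, character(1L), "cell_id"),
    x_um = vapply(cells, function(c) c$centroid_um[["x"]], numeric(1L)),
    y_um = vapply(cells, function(c) c$centroid_um[["y"]], numeric(1L)),
    diameter_um = vapply(cells, `[[`, numeric(1L), "diameter_um"),
    edu_positive = vapply(cells, function(c) as.logical(c$edu_positive),
                          logical(1L)),
    old = vapply(cells, get_tot, numeric(1L), old_channel),
    new = vapply(cells, get_tot, numeric(1L), new_channel),
    delta = vapply(cells, get_tot, numeric(1L), delta_channel),
    stringsAsFactors = FALSE)
}

#' Delta-based division-mode classification
#'
#' Orders the two cells by Delta reporter level (the higher becomes
#' cell 1) and classifies the pair: a Delta ratio greater than 2 is an
#' asymmetric pair (presumptive stem + differentiating daughter), a ratio
#' less than 2 a symmetric pair.  A ratio of exactly 2 is assigned to the
#' conservative `symmetric` class.
#'
#' @param dl1,dl2 Delta reporter totals of the two cells (both `> 0`).
#' @return list with `delta_ratio` (`>= 1`) and `delta_class`
#'   (`"asymmetric"` or `"symmetric"`).
#' @export
classify_pair_delta <- function(dl1, dl2) {
  if (any(is.na(c(dl1, dl2))) || dl1 <= 0 || dl2 <= 0)
    stop("Delta totals must be positive")
  ratio <- max(dl1, dl2) / min(dl1, dl2)
  list(delta_ratio = ratio,
       delta_class = if (ratio > 2) "asymmetric" else "symmetric")
}

#' Old/new histone log2 inheritance ratios of a pair
#'
#' log2 of the cell1/cell2 total for the old- and new-histone channels,
#' where cell 1 is the Delta-high cell; a positive old value with a
#' negative new value means the Delta-high daughter inherited more old and
#' less new histone.
#'
#' @param old1,old2,new1,new2 corrected histone totals, cell 1 first; all
#'   must be positive.
#' @return named numeric `c(old_log2=, new_log2=)`.
#' @export
pair_log2_ratios <- function(old1, old2, new1, new2) {
  v <- c(old1, old2, new1, new2)
  if (any(is.na(v)) || any(v <= 0))
    stop("histone totals must be positive for log2 ratios")
  c(old_log2 = log2(old1 / old2), new_log2 = log2(new1 / new2))
}

#' Fold change implied by a mean log2 ratio
#'
#' The geometric-mean fold change `2^|mean_log2|` (magnitude).  A mean
#' log2 ratio of 0.65 corresponds to a ~1.57-fold difference.
#'
#' @param mean_log2 numeric mean of per-pair log2 ratios.
#' @return numeric fold change `>= 1`.
#' @export
fold_from_log2 <- function(mean_log2) {
  if (any(!is.finite(mean_log2))) stop("mean_log2 must be finite")
  2^abs(mean_log2)
}

#' Quadrant of a pair in the (old, new) log2 plane
#'
#' Quadrant assignment for the 2D presentation with x = old log2 ratio and
#' y = new log2 ratio: I (+,+), II (-,+), III (-,-), IV (+,-); a pair at
#' exactly (0, 0) is labelled `origin`.  Values on an axis (one coordinate
#' exactly 0) are assigned by treating 0 as positive, so the mapping is
#' total.  Quadrant IV is the signature of the Delta-high cell inheriting
#' more old and less new histone.
#'
#' @param old_log2,new_log2 finite log2 ratios.
#' @return character scalar in `c("I","II","III","IV","origin")`.
#' @export
quadrant <- function(old_log2, new_log2) {
  if (!is.finite(old_log2) || !is.finite(new_log2))
    stop("log2 ratios must be finite")
  if (old_log2 == 0 && new_log2 == 0) return("origin")
  if (old_log2 >= 0 && new_log2 >= 0) "I"
  else if (old_log2 < 0 && new_log2 >= 0) "II"
  else if (old_log2 < 0 && new_log2 < 0) "III"
  else "IV"
}

#' Build pair records from measured cells
#'
#' Runs [pair_filter()], orders each eligible pair by Delta (ties broken
#' by cell id for determinism), and assembles the full `PairRecord` table:
#' Delta ratio and class, old/new log2 ratios, and quadrant.
#'
#' @inheritParams pair_filter
#' @param specimen_id identifier of the source specimen (midgut), recycled
#'   over pairs.
#' @return data.frame with one row per eligible pair: `specimen_id`,
#'   `cell1`, `cell2`, `delta_ratio`, `delta_class`, `old_log2`,
#'   `new_log2`, `quadrant`; the rejection log is attached as
#'   `attr(, "rejected")`.
#' @export
pair_records <- function(cells, candidates = NULL, specimen_id = "specimen1",
                         max_distance_um = 5, max_size_ratio = 1.5,
                         quant_floor = 0, old_channel = "old",
                         new_channel = "new", delta_channel = "DlnLacZ") {
  tab <- cells_to_table(cells, old_channel, new_channel, delta_channel)
  flt <- pair_filter(cells, candidates, max_distance_um, max_size_ratio,
                     quant_floor, old_channel, new_channel, delta_channel)
  el <- flt$eligible
  out <- data.frame(specimen_id = character(0L), cell1 = character(0L),
                    cell2 = character(0L), delta_ratio = numeric(0L),
                    delta_class = character(0L), old_log2 = numeric(0L),
                    new_log2 = numeric(0L), quadrant = character(0L))
  for (k in seq_len(nrow(el))) {
    i <- el$i[k]; j <- el$j[k]
    hi <- i; lo <- j
    if (tab$delta[j] > tab$delta[i] ||
        (tab$delta[j] == tab$delta[i] &&
         tab$cell_id[j] < tab$cell_id[i])) { hi <- j; lo <- i }
    cls <- classify_pair_delta(tab$delta[hi], tab$delta[lo])
    lr <- pair_log2_ratios(tab$old[hi], tab$old[lo],
                           tab$new[hi], tab$new[lo])
    out[nrow(out) + 1L, ] <- list(specimen_id, tab$cell_id[hi],
                                  tab$cell_id[lo], cls$delta_ratio,
                                  cls$delta_class, lr[["old_log2"]],
                                  lr[["new_log2"]],
                                  quadrant(lr[["old_log2"]],
                                           lr[["new_log2"]]))
  }
  attr(out, "rejected") <- flt$rejected
  out
}

#' Summaries of a pair cohort
#'
#' Class proportions are computed per specimen and then averaged across
#' specimens (mean +- SEM of per-specimen percentages, the "avg." reporting
#' convention); pooled counts are reported alongside for chi-square use.
#' Per-class means +- SEM of the old/new log2 ratios are pooled across
#' pairs.
#'
#' @param pairs data.frame as returned by [pair_records()] (needs columns
#'   `specimen_id`, `delta_class`, `old_log2`, `new_log2`).
#' @return list with `per_specimen` (data.frame of per-specimen percent
#'   asymmetric), `prop_asymmetric` / `prop_symmetric` (each
#'   `c(mean=, sem=)` in percent), `pooled_counts` (named vector), and
#'   `log2_by_class` (data.frame of class, n, old/new mean and SEM).
#' @export
pair_summary <- function(pairs) {
  stopifnot(all(c("specimen_id", "delta_class", "old_log2", "new_log2")
                %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("no pairs to summarise")
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                     else NA_real_

  spl <- split(pairs, pairs$specimen_id)
  empty <- vapply(spl, function(d) nrow(d) == 0L, logical(1L))
  if (any(empty)) {
    warning("excluding specimens with zero pairs: ",
            paste(names(spl)[empty], collapse = ", "))
    spl <- spl[!empty]
  }
  per_spec <- data.frame(
    specimen_id = names(spl),
    n_pairs = vapply(spl, nrow, integer(1L)),
    pct_asymmetric = vapply(spl, function(d)
      100 * mean(d$delta_class == "asymmetric"), numeric(1L)),
    row.names = NULL)
  per_spec$pct_symmetric <- 100 - per_spec$pct_asymmetric

  prop_asym <- c(mean = mean(per_spec$pct_asymmetric),
                 sem = sem(per_spec$pct_asymmetric))
  prop_sym <- c(mean = mean(per_spec$pct_symmetric),
                sem = sem(per_spec$pct_symmetric))
  pooled <- c(asymmetric = sum(pairs$delta_class == "asymmetric"),
              symmetric = sum(pairs$delta_class == "symmetric"))

  log2_by_class <- do.call(rbind, lapply(
    split(pairs, pairs$delta_class), function(d)
      data.frame(delta_class = d$delta_class[1L], n = nrow(d),
                 old_log2_mean = mean(d$old_log2),
                 old_log2_sem = sem(d$old_log2),
                 new_log2_mean = mean(d$new_log2),
                 new_log2_sem = sem(d$new_log2))))
  rownames(log2_by_class) <- NULL

  list(per_specimen = per_spec,
       prop_asymmetric = prop_asym,
       prop_symmetric = prop_sym,
       pooled_counts = pooled,
       log2_by_class = log2_by_class)
}
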