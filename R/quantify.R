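#' Integrated density over an ROI
#'
#' The raw integrated density: the sum of the channel's intensities over
#' every ROI pixel on every slice of the ROI's z-range.  All slices
#' containing the cell contribute, and their values are added into one
#' total.  Accumulation is in double precision (exact for integer totals up
#' to 2^53, far beyond any 16-bit stack).
#'
#' @param stack an [image_stack()].
#' @param roi the signal `Roi`.
#' @param channel channel name.
#' @return numeric scalar, the summed intensity in detector units.
#' @export
integrated_density <- function(stack, roi, channel) {
  sum(roi_values(stack, roi, channel))
}

#' Background-corrected integrated density
#'
#' Measures the signal ROI and an equal-area background ROI placed in a
#' region with no fluorescence signal, and subtracts the background total
#' from the raw total.  The two ROIs must select the same number of pixels
#' (the same outline moved to an empty area) and span z-ranges of equal
#' depth; a mismatch beyond one pixel per slice aborts, since it signals a
#' mis-specified background ROI.
#'
#' Negative corrected totals are returned as-is with a warning flag rather
#' than clamped: clamping would bias ratio denominators upward.
#'
#' @param stack an [image_stack()].
#' @param signal_roi,background_roi equal-area `Roi`s.
#' @param channel channel name.
#' @return an object of class `RoiTotal`: list with `raw_total`,
#'   `background_total`, `corrected_total`, `n_slices`, `roi_area_px`, and
#'   `flags` (character vector, contains `"negative_corrected"` when
#'   applicable).
#' @export
background_corrected_total <- function(stack, signal_roi, background_roi,
                                       channel) {
  sig_px <- roi_pixels(signal_roi, stack)
  bg_px <- roi_pixels(background_roi, stack)
  n_slices_sig <- signal_roi$z_range[2L] - signal_roi$z_range[1L] + 1L
  n_slices_bg <- background_roi$z_range[2L] - background_roi$z_range[1L] + 1L
  area_sig <- nrow(sig_px) / n_slices_sig
  area_bg <- nrow(bg_px) / n_slices_bg
  if (n_slices_sig != n_slices_bg)
    stop("signal and background ROIs span different z depths (",
         n_slices_sig, " vs ", n_slices_bg, ")")
  if (abs(area_sig - area_bg) > 1)
    stop("background ROI area (", area_bg, " px) does not match signal ROI ",
         "area (", area_sig, " px): same outline must be used")

  raw_total <- integrated_density(stack, signal_roi, channel)
  background_total <- integrated_density(stack, background_roi, channel)
  corrected <- raw_total - background_total
  flags <- character(0L)
  if (corrected < 0) {
    warning("negative corrected total for ROI '", signal_roi$name,
            "' channel '", channel, "'")
    flags <- "negative_corrected"
  }
  structure(list(raw_total = raw_total,
                 background_total = background_total,
                 corrected_total = corrected,
                 n_slices = n_slices_sig,
                 roi_area_px = area_sig,
                 flags = flags),
            class = "RoiTotal")
}

#' Measure one cell
#'
#' Aggregates background-corrected totals for the requested channels into a
#' `CellMeasurement`, with physical geometry derived from the ROI: the
#' centroid of the selected pixel centres (in um) and the equivalent-circle
#' diameter `2 * sqrt(area_px / pi) * pixel_size_um`.  EdU status is decided
#' by comparing the mean EdU intensity over the cell ROI with
#' `edu_cutoff`; by default the cutoff is self-calibrated as the background
#' ROI's per-pixel mean plus five per-pixel standard deviations.
#'
#' @param stack an [image_stack()].
#' @param cell_roi,background_roi equal-area `Roi`s.
#' @param channels channel names to total.
#' @param cell_id identifier; defaults to the ROI name.
#' @param edu_channel channel carrying the EdU signal, or `NULL` to skip
#'   EdU scoring (then `edu_positive` is `NA`).
#' @param edu_cutoff mean-intensity cutoff for EdU positivity, or `NULL`
#'   for the self-calibrated default.
#' @return a `CellMeasurement`: list with `cell_id`, `centroid_um`,
#'   `diameter_um`, `totals` (named numeric), `edu_positive`, `flags`.
#' @export
measure_cell <- function(stack, cell_roi, background_roi, channels,
                         cell_id = cell_roi$name, edu_channel = NULL,
                         edu_cutoff = NULL) {
  totals <- numeric(0L)
  flags <- character(0L)
  for (ch in channels) {
    rt <- background_corrected_total(stack, cell_roi, background_roi, ch)
    totals[[ch]] <- rt$corrected_total
    if (length(rt$flags)) flags <- c(flags, paste0(ch, ":", rt$flags))
  }
  px <- roi_pixels(cell_roi, stack)
  area_px <- nrow(px) / (cell_roi$z_range[2L] - cell_roi$z_range[1L] + 1L)
  centroid_um <- c(x = mean(px[, "x"]), y = mean(px[, "y"])) *
    stack$pixel_size_um
  diameter_um <- 2 * sqrt(area_px / pi) * stack$pixel_size_um

  edu_positive <- NA
  if (!is.null(edu_channel)) {
    channel_index(stack, edu_channel)  # errors early if absent
    edu_vals <- roi_values(stack, cell_roi, edu_channel)
    if (is.null(edu_cutoff)) {
      bg_vals <- roi_values(stack, background_roi, edu_channel)
      edu_cutoff <- mean(bg_vals) + 5 * stats::sd(bg_vals)
    }
    edu_positive <- mean(edu_vals) > edu_cutoff
  }

  structure(list(cell_id = cell_id,
                 centroid_um = centroid_um,
                 diameter_um = diameter_um,
                 totals = totals,
                 edu_positive = edu_positive,
                 flags = flags),
            class = "CellMeasurement")
}

#' @export
print.CellMeasurement <- function(x, ...) {
  cat(sprintf("CellMeasurement '%s': d=%.2f um, EdU %s\n", x$cell_id,
              x$diameter_um,
              if (is.na(x$edu_positive)) "n/a" else x$edu_positive))
  for (ch in names(x$totals))
    cat(sprintf("  %-10s %12.1f\n", ch, x$totals[[ch]]))
  invisible(x)
}

#' Threshold-and-label helper for synthetic fields
#'
#' A deliberately simple segmentation helper for the synthetic generator's
#' single-z fields (real-image nucleus segmentation is out of scope; ROIs
#' are inputs there).  Pixels above `cutoff` are labelled by 4-connected
#' components.
#'
#' @param img numeric matrix `(y, x)`.
#' @param cutoff intensity threshold.
#' @return integer matrix of labels (0 = background).
#' @export
threshold_label <- function(img, cutoff) {
  mask <- img > cutoff
  lab <- matrix(0L, nrow(img), ncol(img))
  cur <- 0L
  h <- nrow(img); w <- ncol(img)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), ncol = 2L)
      lab[i, j] <- cur
      while (nrow(queue) > 0L) {
        p <- queue[1L, , drop = FALSE]; queue <- queue[-1L, , drop = FALSE]
        for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ni <- p[1L] + dd[1L]; nj <- p[2L] + dd[2L]
          if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue <- rbind(queue, c(ni, nj))
          }
        }
      }
    }
  }
  lab
}
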