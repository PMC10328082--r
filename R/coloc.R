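#' Colocalization of two channels over an ROI
#'
#' Pearson and Spearman correlation between two channels computed over all
#' voxels of an ROI, by default pooled across the ROI's z-range (set
#' `mode = "per-slice"` to correlate slice by slice and average).  No
#' intensity thresholding is applied: every ROI voxel enters the
#' correlation.  A coefficient of 1 indicates complete colocalization, 0 no
#' colocalization, negative values spatial exclusion.
#'
#' If either channel has zero variance over the ROI the coefficient is
#' undefined and `NA` is returned with a warning (an explicit undefined
#' marker — silently returning 0 would bias downstream means).
#'
#' @param stack an [image_stack()].
#' @param roi a `Roi` covering the nucleus or region to analyse.
#' @param channel_a,channel_b channel names to correlate.
#' @param mode `"pooled"` (default) or `"per-slice"`.
#' @return a `ColocResult`: list with `pearson_r` or `spearman_rho`,
#'   `n_voxels`, `roi_name`.
#' @export
pearson_coloc <- function(stack, roi, channel_a, channel_b,
                          mode = c("pooled", "per-slice")) {
  mode <- match.arg(mode)
  coloc_engine(stack, roi, channel_a, channel_b, mode, method = "pearson")
}

#' @rdname pearson_coloc
#' @export
spearman_coloc <- function(stack, roi, channel_a, channel_b,
                           mode = c("pooled", "per-slice")) {
  mode <- match.arg(mode)
  coloc_engine(stack, roi, channel_a, channel_b, mode, method = "spearman")
}

coloc_engine <- function(stack, roi, channel_a, channel_b, mode, method) {
  ca <- channel_index(stack, channel_a)
  cb <- channel_index(stack, channel_b)
  px <- roi_pixels(roi, stack)
  if (nrow(px) < 2L) stop("ROI must contain at least 2 voxels")

  corr1 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero variance in a channel over ROI '", roi$name,
              "': correlation undefined")
      return(NA_real_)
    }
    if (method == "spearman") {
      a <- rank(a, ties.method = "average")
      b <- rank(b, ties.method = "average")
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("all-tied channel over ROI '", roi$name,
                "': rank correlation undefined")
        return(NA_real_)
      }
    }
    stats::cor(a, b)
  }

  idx <- function(ci) stack$data[cbind(ci, px[, "z"] + 1L,
                                       px[, "y"] + 1L, px[, "x"] + 1L)]
  if (mode == "pooled") {
    r <- corr1(idx(ca), idx(cb))
  } else {
    zs <- unique(px[, "z"])
    rs <- vapply(zs, function(z) {
      sel <- px[, "z"] == z
      a <- stack$data[cbind(ca, z + 1L, px[sel, "y"] + 1L, px[sel, "x"] + 1L)]
      b <- stack$data[cbind(cb, z + 1L, px[sel, "y"] + 1L, px[sel, "x"] + 1L)]
      corr1(a, b)
    }, numeric(1L))
    r <- mean(rs, na.rm = TRUE)
    if (is.nan(r)) r <- NA_real_
  }

  res <- list(n_voxels = nrow(px), roi_name = roi$name)
  if (method == "pearson") res$pearson_r <- r else res$spearman_rho <- r
  structure(res, class = "ColocResult")
}

#' Tile a field into fixed-size square regions
#'
#' Non-overlapping axis-aligned squares of physical side `side_um`
#' (default 150 um, the census-region convention) tiling the field from the
#' top-left corner; partial tiles at the right/bottom edge are excluded so
#' every returned region has the identical pixel count.
#'
#' @param stack an [image_stack()] (a 2D field uses `n_z = 1`).
#' @param side_um physical side length of each square in micrometres.
#' @return list of polygon `Roi`s spanning the stack's full z-range.
#' @export
region_grid <- function(stack, side_um = 150) {
  d <- stack_dim(stack)
  side_px <- round(side_um / stack$pixel_size_um)
  if (side_px < 1L) stop("region side smaller than one pixel")
  nx <- d$width %/% side_px
  ny <- d$height %/% side_px
  if (nx < 1L || ny < 1L)
    stop("field smaller than one ", side_um, " um region")
  rois <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny) - 1L) for (ix in seq_len(nx) - 1L) {
    k <- k + 1L
    x0 <- ix * side_px; y0 <- iy * side_px
    # rectangle enclosing pixel centres x0 .. x0+side_px-1
    rois[[k]] <- polygon_roi(
      sprintf("region_%02d_%02d", iy, ix),
      cbind(x = c(x0 - 0.5, x0 + side_px - 0.5, x0 + side_px - 0.5, x0 - 0.5),
            y = c(y0 - 0.5, y0 - 0.5, y0 + side_px - 0.5, y0 + side_px - 0.5)),
      c(0L, d$n_z - 1L))
  }
  rois
}
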