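#' Cluster marker-positive cells by proximity
#'
#' Single-linkage connected components over cell centroids: two cells are
#' adjacent when their centroid distance is at most `adjacency_radius_um`,
#' and clusters are the transitive closure of adjacency (a chain A-B-C with
#' only AB and BC adjacent is one cluster of three).  The default radius of
#' 10 um is roughly one stem-cell nucleus diameter; it is a parameter, not
#' a constant of nature, and is recorded in the result.
#'
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um` (one row
#'   per marker-positive cell); extra columns are carried through.
#' @param adjacency_radius_um linkage distance in micrometres.
#' @return a `ClusterSet`: list with `cells` (the input plus a `cluster`
#'   column), `adjacency_radius_um`, `sizes` (cluster sizes),
#'   `size_histogram` (counts of clusters of size 1, 2, >= 3).
#' @export
cluster_cells <- function(cells, adjacency_radius_um = 10) {
  if (adjacency_radius_um <= 0) stop("adjacency radius must be positive")
  n <- nrow(cells)
  if (n == 0L) {
    return(structure(list(cells = cbind(cells, cluster = integer(0L)),
                          adjacency_radius_um = adjacency_radius_um,
                          sizes = integer(0L),
                          size_histogram = c(`1` = 0L, `2` = 0L,
                                             `>=3` = 0L)),
                     class = "ClusterSet"))
  }
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      f <- frontier[1L]; frontier <- frontier[-1L]
      d2 <- (cells$x_um - cells$x_um[f])^2 + (cells$y_um - cells$y_um[f])^2
      nb <- which(lab == 0L & d2 <= adjacency_radius_um^2)
      lab[nb] <- cur
      frontier <- c(frontier, nb)
    }
  }
  sizes <- as.integer(table(lab))
  out <- cells
  out$cluster <- lab
  structure(list(cells = out,
                 adjacency_radius_um = adjacency_radius_um,
                 sizes = sizes,
                 size_histogram = c(`1` = sum(sizes == 1L),
                                    `2` = sum(sizes == 2L),
                                    `>=3` = sum(sizes >= 3L))),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d cells in %d clusters (radius %.1f um); ",
              nrow(x$cells), length(x$sizes), x$adjacency_radius_um))
  cat(sprintf("sizes 1/2/>=3: %d/%d/%d\n", x$size_histogram[[1L]],
              x$size_histogram[[2L]], x$size_histogram[[3L]]))
  invisible(x)
}

#' Cluster size distribution
#'
#' Percentages of clusters containing 1, 2, or >= 3 marker-positive cells;
#' the denominator is the number of clusters, and the three percentages
#' sum to 100.
#'
#' @param cs a [cluster_cells()] result.
#' @return named numeric `c("1"=, "2"=, ">=3"=)` in percent.
#' @export
cluster_size_distribution <- function(cs) {
  stopifnot(inherits(cs, "ClusterSet"))
  n_clusters <- length(cs$sizes)
  if (n_clusters == 0L) stop("empty ClusterSet")
  100 * cs$size_histogram / n_clusters
}

#' Fraction of marker-positive cells that are single
#'
#' Percentage of marker-positive cells that sit in size-1 clusters; unlike
#' [cluster_size_distribution()], the denominator is cells, not clusters.
#'
#' @param cs a [cluster_cells()] result.
#' @return numeric percentage.
#' @export
single_cell_fraction <- function(cs) {
  stopifnot(inherits(cs, "ClusterSet"))
  total_cells <- sum(cs$sizes)
  if (total_cells == 0L) stop("no marker-positive cells")
  100 * sum(cs$sizes[cs$sizes == 1L]) / total_cells
}

#' Count marker-positive cells in a region
#'
#' Counts the cells of a cell table whose marker flag is set and whose
#' centroid lies inside the region.  The mitotic index is this count for
#' the H3S10ph marker over a whole midgut.
#'
#' @param cells data.frame with columns `x_um`, `y_um` and one logical (or
#'   0/1) column per marker.
#' @param marker marker column name.
#' @param region a `Roi` in pixel coordinates, or `NULL` for the whole
#'   field.
#' @param pixel_size_um calibration used to place centroids in the region
#'   (required when `region` is given).
#' @return integer count.
#' @export
count_positive <- function(cells, marker, region = NULL,
                           pixel_size_um = NULL) {
  if (!marker %in% names(cells))
    stop("unknown marker '", marker, "'; columns: ",
         paste(names(cells), collapse = ", "))
  pos <- as.logical(cells[[marker]])
  if (is.null(region)) return(sum(pos))
  if (is.null(pixel_size_um))
    stop("pixel_size_um required to test centroids against a region")
  px <- cells$x_um / pixel_size_um
  py <- cells$y_um / pixel_size_um
  inside <- switch(region$type,
    polygon = points_in_polygon(px, py, region$vertices),
    ellipse = ((px - region$center[1L]) / region$radii[1L])^2 +
              ((py - region$center[2L]) / region$radii[2L])^2 <= 1,
    stop("region must be a polygon or ellipse ROI"))
  sum(pos & inside)
}

#' Per-region percentage positive with summary
#'
#' Per-region percentages `100 * positives / totals`, plus their mean and
#' SEM across regions.  Regions with zero total are excluded with a
#' warning.
#'
#' @param positives,totals integer vectors, one entry per region.
#' @return list with `per_region` (numeric vector), `mean`, `sem`.
#' @export
percent_positive <- function(positives, totals) {
  stopifnot(length(positives) == length(totals))
  bad <- totals == 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " region(s) with zero total")
    positives <- positives[!bad]; totals <- totals[!bad]
  }
  if (length(totals) == 0L) stop("no regions with cells")
  pct <- 100 * positives / totals
  list(per_region = pct,
       mean = mean(pct),
       sem = if (length(pct) > 1L) stats::sd(pct) / sqrt(length(pct))
             else NA_real_)
}

#' Intensity profile along a midline path
#'
#' Walks the polyline in unit-pixel steps and, at each step, averages the
#' channel intensity over a perpendicular segment `width_px` wide (default
#' 500 px, approximately one intestine width) centred on the path.  The
#' stack is maximum-projected across z first.  Samples falling outside the
#' field are excluded from the mean (not zero-padded, which would bias
#' edge values downward).
#'
#' @param stack an [image_stack()].
#' @param path numeric matrix/data.frame with columns `x`, `y` (0-based
#'   pixel coordinates) and at least 2 vertices.
#' @param channel channel to profile.
#' @param width_px sampling width perpendicular to the path.
#' @return a `ProfileTrace`: list with `positions_px` (arc length at each
#'   sample), `mean_intensity`, `width_px`, `channel`.
#' @export
profile_trace <- function(stack, path, channel, width_px = 500) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("path needs at least 2 vertices")
  img <- max_project(stack, channel)
  h <- nrow(img); w <- ncol(img)

  seg_len <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  total_len <- sum(seg_len)
  n_steps <- max(2L, floor(total_len) + 1L)
  s <- seq(0, total_len, length.out = n_steps)
  cum <- c(0, cumsum(seg_len))

  offsets <- seq_len(width_px) - (width_px + 1) / 2
  means <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    seg <- min(max(findInterval(s[k], cum, rightmost.closed = TRUE), 1L),
               length(seg_len))
    t <- if (seg_len[seg] > 0) (s[k] - cum[seg]) / seg_len[seg] else 0
    cx <- path[seg, 1L] + t * (path[seg + 1L, 1L] - path[seg, 1L])
    cy <- path[seg, 2L] + t * (path[seg + 1L, 2L] - path[seg, 2L])
    dx <- (path[seg + 1L, 1L] - path[seg, 1L]) / seg_len[seg]
    dy <- (path[seg + 1L, 2L] - path[seg, 2L]) / seg_len[seg]
    # unit normal to the path direction
    sx <- round(cx - offsets * dy)
    sy <- round(cy + offsets * dx)
    keep <- sx >= 0 & sx < w & sy >= 0 & sy < h
    if (!any(keep)) { means[k] <- NA_real_; next }
    means[k] <- mean(img[cbind(sy[keep] + 1L, sx[keep] + 1L)])
  }
  structure(list(positions_px = s, mean_intensity = means,
                 width_px = width_px, channel = channel),
            class = "ProfileTrace")
}

#' Block-average a profile trace
#'
#' Averages every `block` consecutive positions of the trace into one
#' value (default 1,000), discarding the trailing partial block.  When the
#' trace length is an exact multiple of the block size, the mean of the
#' block means equals the trace mean.
#'
#' @param trace a [profile_trace()] result, or a numeric vector.
#' @param block block length in positions.
#' @return numeric vector of block means.
#' @export
block_average <- function(trace, block = 1000) {
  x <- if (inherits(trace, "ProfileTrace")) trace$mean_intensity else trace
  n_blocks <- length(x) %/% block
  if (n_blocks < 1L)
    stop("trace shorter (", length(x), ") than one block (", block, ")")
  vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1L) * block + 1L):(b * block)]), numeric(1L))
}
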