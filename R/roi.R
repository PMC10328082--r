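#' Regions of interest
#'
#' A `Roi` is a named spatial selection used both for signal and background
#' measurement.  Three geometries are supported: polygon (vertex list),
#' ellipse (centre + radii), and label (a value in a label-mask image).
#' Coordinates are 0-based pixel coordinates with pixel centres at integer
#' positions and y increasing downward; `z_range` is the inclusive
#' `(first, last)` slice pair, 0-based.  A pixel belongs to a polygon or
#' ellipse ROI iff its centre is inside the geometry (pixel-centre
#' semantics), which makes pixel counts invariant under integer-pixel
#' translation.
#'
#' @param name identifier for the ROI.
#' @param vertices numeric matrix or data.frame with columns `x`, `y`
#'   (0-based pixel coordinates) listing the polygon vertices in order.
#' @param z_range integer vector `c(first, last)`, inclusive 0-based slice
#'   indices.
#' @return an object of class `Roi`.
#' @examples
#' sq <- polygon_roi("cell1", cbind(x = c(-.5, 2.5, 2.5, -.5),
#'                                  y = c(-.5, -.5, 2.5, 2.5)), c(0, 0))
#' @name roi
NULL

new_roi <- function(name, type, fields, z_range) {
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || any(is.na(z_range)) || z_range[1L] > z_range[2L])
    stop("`z_range` must be c(first, last) with first <= last")
  structure(c(list(name = as.character(name), type = type,
                   z_range = z_range), fields),
            class = "Roi")
}

#' @rdname roi
#' @export
polygon_roi <- function(name, vertices, z_range) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("`vertices` must be an n x 2 matrix (x, y) with n >= 3")
  colnames(vertices) <- c("x", "y")
  new_roi(name, "polygon", list(vertices = vertices), z_range)
}

#' @rdname roi
#' @param center numeric `c(x, y)` ellipse centre in pixel coordinates.
#' @param radii numeric `c(rx, ry)` semi-axes in pixels.
#' @export
ellipse_roi <- function(name, center, radii, z_range) {
  if (length(center) != 2L || length(radii) != 2L || any(radii <= 0))
    stop("`center` and `radii` must each have length 2, radii > 0")
  new_roi(name, "ellipse",
          list(center = as.numeric(center), radii = as.numeric(radii)),
          z_range)
}

#' @rdname roi
#' @param mask integer matrix `(y, x)` of labels, or path to a label-mask
#'   TIFF.
#' @param value the label value selecting this ROI's pixels.
#' @export
label_roi <- function(name, mask, value, z_range) {
  if (is.character(mask)) mask <- read_tiff(mask)$planes[[1L]]
  mask <- as.matrix(mask)
  if (!any(mask == value)) stop("label value ", value, " absent from mask")
  new_roi(name, "label", list(mask = mask, value = value), z_range)
}

#' @export
print.Roi <- function(x, ...) {
  cat(sprintf("Roi '%s' (%s), z %d..%d\n", x$name, x$type,
              x$z_range[1L], x$z_range[2L]))
  invisible(x)
}

# Even-odd ray-casting containment test for pixel centres (px, py).
# Vectorised over points; boundary handling follows the standard half-open
# crossing rule so integer-translates select identical pixel counts.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

roi_mask_2d <- function(roi, height, width) {
  px <- rep(0:(width - 1L), each = height)
  py <- rep(0:(height - 1L), times = width)
  inside <- switch(roi$type,
    polygon = points_in_polygon(px, py, roi$vertices),
    ellipse = ((px - roi$center[1L]) / roi$radii[1L])^2 +
              ((py - roi$center[2L]) / roi$radii[2L])^2 <= 1,
    label = {
      m <- roi$mask
      if (nrow(m) != height || ncol(m) != width)
        stop("label mask dimensions do not match the stack")
      as.vector(m == roi$value)
    },
    stop("unknown ROI type: ", roi$type))
  matrix(inside, nrow = height, ncol = width)
}

#' Pixels selected by an ROI
#'
#' Deterministically enumerates the `(z, y, x)` indices (0-based) of every
#' pixel whose centre lies inside the ROI geometry, replicated over the
#' ROI's inclusive z-range.
#'
#' @param roi a [polygon_roi()], [ellipse_roi()] or [label_roi()].
#' @param stack the [image_stack()] the ROI indexes into.
#' @return integer matrix with columns `z`, `y`, `x` (0-based).
#' @export
roi_pixels <- function(roi, stack) {
  d <- stack_dim(stack)
  if (roi$z_range[1L] < 0L || roi$z_range[2L] >= d$n_z)
    stop("ROI '", roi$name, "' z_range outside stack bounds")
  m <- roi_mask_2d(roi, d$height, d$width)
  yx <- which(m, arr.ind = TRUE) - 1L
  if (nrow(yx) == 0L)
    stop("ROI '", roi$name, "' selects no pixels")
  zs <- roi$z_range[1L]:roi$z_range[2L]
  out <- cbind(z = rep(zs, each = nrow(yx)),
               y = rep(yx[, 1L], times = length(zs)),
               x = rep(yx[, 2L], times = length(zs)))
  out
}

# Intensity values of one channel over an ROI, pooled across its z-range.
roi_values <- function(stack, roi, channel) {
  ci <- channel_index(stack, channel)
  px <- roi_pixels(roi, stack)
  stack$data[cbind(ci, px[, "z"] + 1L, px[, "y"] + 1L, px[, "x"] + 1L)]
}

# --- ROI JSON sidecar I/O ---------------------------------------------------

#' Read and write ROI sidecar files
#'
#' ROIs travel alongside images as a JSON sidecar:
#' `{"rois": [{"name": ..., "type": "polygon"|"ellipse"|"label",
#'   "coordinates"/"center"+"radii"/"mask"+"value": ..., "z_range": [a, b]}]}`.
#' Label entries reference a label-mask TIFF by path relative to the sidecar.
#'
#' @param rois list of `Roi` objects.
#' @param path file path of the JSON sidecar.
#' @return `read_rois()` returns a named list of `Roi` objects.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "Roi")) rois <- list(rois)
  entries <- lapply(rois, function(r) {
    e <- list(name = r$name, type = r$type, z_range = r$z_range)
    if (r$type == "polygon")
      e$coordinates <- lapply(seq_len(nrow(r$vertices)),
                              function(i) as.numeric(r$vertices[i, ]))
    if (r$type == "ellipse") { e$center <- r$center; e$radii <- r$radii }
    if (r$type == "label") {
      mask_path <- paste0(tools::file_path_sans_ext(path), "_",
                          gsub("[^A-Za-z0-9_.-]", "_", r$name), "_mask.tif")
      write_tiff(mask_path, list(r$mask))
      e$mask <- basename(mask_path); e$value <- r$value
    }
    e
  })
  jsonlite::write_json(list(rois = entries), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  doc <- jsonlite::read_json(path)
  rois <- lapply(doc$rois, function(e) {
    zr <- unlist(e$z_range)
    switch(e$type,
      polygon = polygon_roi(e$name,
        do.call(rbind, lapply(e$coordinates, unlist)), zr),
      ellipse = ellipse_roi(e$name, unlist(e$center), unlist(e$radii), zr),
      label = label_roi(e$name, file.path(dirname(path), e$mask),
                        e$value, zr),
      stop("unknown ROI type in sidecar: ", e$type))
  })
  names(rois) <- vapply(rois, `[[`, character(1L), "name")
  rois
}
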