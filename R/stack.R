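#' Calibrated multi-channel z-stack
#'
#' The measurement substrate of the pipeline: a 4-dimensional intensity
#' array indexed `(channel, z, y, x)` in detector units, together with the
#' physical pixel calibration.  Calibration is mandatory because the
#' pair-eligibility (5 um) and census-region (150 um) rules are physical
#' distances; there is no silent 1 um default.
#'
#' @param data numeric array with dimensions `(channel, z, y, x)`, all
#'   intensities `>= 0`.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param z_step_um spacing between consecutive z slices in micrometres.
#' @param channel_names character vector naming the channels, in order.
#' @return an object of class `ImageStack`.
#' @examples
#' a <- array(0, dim = c(2, 3, 8, 8))
#' s <- image_stack(a, pixel_size_um = 0.2, z_step_um = 0.5,
#'                  channel_names = c("old", "new"))
#' dim(s$data)
#' @export
image_stack <- function(data, pixel_size_um, z_step_um, channel_names) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-d array indexed (channel, z, y, x)")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(z_step_um) || length(z_step_um) != 1L ||
      is.na(z_step_um) || z_step_um <= 0)
    stop("`z_step_um` must be a single positive number")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[1L])
    stop("`channel_names` length (", length(channel_names),
         ") must equal the channel dimension (", dim(data)[1L], ")")
  structure(list(data = data,
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 channel_names = channel_names),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageStack: %d channel(s) [%s], %d z-slice(s), %d x %d px @ %.4g um/px, dz %.4g um\n",
    d[1L], paste(x$channel_names, collapse = ", "), d[2L], d[3L], d[4L],
    x$pixel_size_um, x$z_step_um))
  invisible(x)
}

channel_index <- function(stack, channel) {
  i <- match(channel, stack$channel_names)
  if (is.na(i))
    stop("channel '", channel, "' not found; available: ",
         paste(stack$channel_names, collapse = ", "))
  i
}

stack_dim <- function(stack) {
  d <- dim(stack$data)
  list(n_channels = d[1L], n_z = d[2L], height = d[3L], width = d[4L])
}

#' Maximum-intensity projection of one channel
#'
#' Per-pixel maximum across z, as used before tissue-level profile and field
#' analyses.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, channel) {
  ci <- channel_index(stack, channel)
  apply(stack$data[ci, , , , drop = FALSE], c(3L, 4L), max)
}
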