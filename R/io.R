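#' Read and write calibrated image stacks
#'
#' Stacks are stored as 16-bit unsigned multi-page TIFF, one page per
#' `(channel, z)` plane, with a JSON ImageDescription recording the axis
#' order, shape, channel names, and calibration.  `read_stack()` normalises
#' any supported page order to the package convention `(channel, z, y, x)`.
#'
#' Calibration is mandatory: a file without embedded metadata must be
#' accompanied by a sidecar (either the `sidecar` argument or
#' `<path>.json`) supplying `pixel_size_um` and `z_step_um`, otherwise the
#' read fails rather than silently defaulting.  A single-page TIFF with
#' sidecar calibration is read as a `(1, 1, H, W)` stack.
#'
#' @param path TIFF file path.
#' @param sidecar optional path to a JSON sidecar with fields
#'   `pixel_size_um`, `z_step_um` and optionally `axes`, `shape`,
#'   `channel_names`.
#' @return `read_stack()` returns an [image_stack()].
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  tf <- read_tiff(path)

  meta <- NULL
  if (!is.null(tf$description)) {
    parsed <- tryCatch(jsonlite::fromJSON(tf$description),
                       error = function(e) NULL)
    if (!is.null(parsed$asymhist)) meta <- parsed$asymhist
  }
  if (is.null(sidecar)) {
    auto <- paste0(path, ".json")
    if (file.exists(auto)) sidecar <- auto
  }
  if (!is.null(sidecar)) {
    sc <- jsonlite::fromJSON(sidecar)
    meta <- utils::modifyList(if (is.null(meta)) list() else meta, sc)
  }
  if (is.null(meta) || is.null(meta$pixel_size_um) || is.null(meta$z_step_um))
    stop("missing calibration for ", path,
         ": supply embedded metadata or a JSON sidecar with ",
         "pixel_size_um and z_step_um")
  if (meta$pixel_size_um <= 0 || meta$z_step_um <= 0)
    stop("calibration must be positive for ", path)

  n_pages <- length(tf$planes)
  axes <- meta$axes
  shape <- unlist(meta$shape)
  if (is.null(axes)) {
    if (n_pages == 1L) { axes <- "CZYX"; shape <- c(1L, 1L) }
    else stop("ambiguous axis order for multi-page file ", path,
              ": metadata must name `axes` and `shape`")
  }
  axes <- toupper(axes)
  if (!axes %in% c("CZYX", "ZCYX"))
    stop("unsupported axes '", axes, "' (expected CZYX or ZCYX)")
  if (length(shape) != 2L || prod(shape) != n_pages)
    stop("metadata shape ", paste(shape, collapse = "x"),
         " does not match ", n_pages, " pages in ", path)

  if (axes == "CZYX") { nc <- shape[1L]; nz <- shape[2L] }
  else { nz <- shape[1L]; nc <- shape[2L] }
  h <- nrow(tf$planes[[1L]]); w <- ncol(tf$planes[[1L]])

  data <- array(0, dim = c(nc, nz, h, w))
  for (p in seq_len(n_pages)) {
    if (axes == "CZYX") {       # page index = (c - 1) * nz + z
      ci <- (p - 1L) %/% nz + 1L; zi <- (p - 1L) %% nz + 1L
    } else {                    # page index = (z - 1) * nc + c
      zi <- (p - 1L) %/% nc + 1L; ci <- (p - 1L) %% nc + 1L
    }
    data[ci, zi, , ] <- tf$planes[[p]]
  }

  ch <- unlist(meta$channel_names)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nc))
  image_stack(data, as.numeric(meta$pixel_size_um),
              as.numeric(meta$z_step_um), ch)
}

#' @rdname read_stack
#' @param stack an [image_stack()]; intensities must already lie in
#'   `[0, 65535]` (the simulator's clipping contract) — values outside that
#'   range signal an upstream bug and abort the write.
#' @return `write_stack()` invisibly returns `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- stack_dim(stack)
  if (max(stack$data) > 65535 || min(stack$data) < 0)
    stop("stack intensities outside [0, 65535]: upstream clipping contract ",
         "violated")
  planes <- vector("list", d$n_channels * d$n_z)
  p <- 0L
  for (ci in seq_len(d$n_channels)) for (zi in seq_len(d$n_z)) {
    p <- p + 1L
    planes[[p]] <- matrix(stack$data[ci, zi, , ], nrow = d$height)
  }
  # top-level `shape` keeps the description compatible with tifffile's
  # "shaped" series detection
  meta <- list(shape = c(d$n_channels, d$n_z, d$height, d$width),
               asymhist = list(
    axes = "CZYX",
    shape = c(d$n_channels, d$n_z),
    channel_names = stack$channel_names,
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um))
  desc <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  write_tiff(path, planes, description = desc,
             resolution_ppcm = 10000 / stack$pixel_size_um)
  invisible(path)
}
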