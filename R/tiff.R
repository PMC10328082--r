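# Minimal baseline TIFF codec (uncompressed, grayscale, 8/16-bit).
#
# No TIFF reader is available in the supported dependency set, so the small
# subset of the format the pipeline needs is implemented here directly:
# multi-page, single-sample-per-pixel, strip-organised images with an
# ImageDescription tag carrying JSON metadata.  Files written here are valid
# baseline TIFF readable by ImageJ/tifffile; the reader also accepts
# little/big-endian files written by those tools as long as they are
# uncompressed grayscale.

TIFF_TAG <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, description = 270L, strip_offsets = 273L,
  samples_per_pixel = 277L, rows_per_strip = 278L,
  strip_byte_counts = 279L, x_resolution = 282L, y_resolution = 283L,
  resolution_unit = 296L, sample_format = 339L
)

# --- low-level byte helpers -------------------------------------------------

u16_to_raw <- function(x) {
  x <- as.integer(round(x))
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

raw_to_u16 <- function(r, endian = "little") {
  v <- readBin(r, "integer", n = length(r) %/% 2L, size = 2L,
               signed = FALSE, endian = endian)
  v
}

raw_to_u32 <- function(r, endian = "little") {
  v <- readBin(r, "integer", n = length(r) %/% 4L, size = 4L,
               signed = TRUE, endian = endian)
  # reinterpret negative 32-bit values as unsigned
  ifelse(v < 0, v + 4294967296, v)
}

# --- writer -----------------------------------------------------------------

# planes: list of integer matrices [y, x], all same dim, values in [0, 65535].
# description: character scalar stored on the first IFD (or NULL).
# resolution_ppcm: pixels per centimetre (X and Y), or NULL.
write_tiff <- function(path, planes, description = NULL,
                       resolution_ppcm = NULL) {
  stopifnot(length(planes) >= 1L)
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  for (p in planes) {
    if (nrow(p) != h || ncol(p) != w)
      stop("all planes must share the same dimensions")
    rng <- range(p)
    if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 65535)
      stop("plane intensities outside the 16-bit range [0, 65535]")
  }

  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))  # NUL-terminated ASCII
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  n_tags_first <- 9L + (!is.null(desc_raw)) + 3L * (!is.null(resolution_ppcm))
  n_tags_rest  <- 9L

  ifd_size <- function(n_tags) 2L + 12L * n_tags + 4L
  plane_bytes <- 2L * h * w

  # layout: header | [IFD extra data strip]* sequentially
  offs <- 8L
  n <- length(planes)
  ifd_off <- extra_off <- data_off <- numeric(n)
  for (i in seq_len(n)) {
    n_tags <- if (i == 1L) n_tags_first else n_tags_rest
    extra_len <- if (i == 1L)
      length(desc_raw) + (if (!is.null(resolution_ppcm)) 16L else 0L) else 0L
    ifd_off[i] <- offs
    extra_off[i] <- offs + ifd_size(n_tags)
    data_off[i] <- extra_off[i] + extra_len
    offs <- data_off[i] + plane_bytes
  }

  tag_raw <- function(id, type, count, value_raw) {
    # value_raw must already be padded to exactly 4 bytes (inline) or be a
    # 4-byte offset
    c(u16_to_raw(id), u16_to_raw(type), u32_to_raw(count), value_raw)
  }
  short_val <- function(x) c(u16_to_raw(x), as.raw(c(0L, 0L)))
  long_val <- function(x) u32_to_raw(x)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16_to_raw(42L), u32_to_raw(ifd_off[1L])), con)

  for (i in seq_len(n)) {
    tags <- list(
      tag_raw(TIFF_TAG[["width"]], 3L, 1L, short_val(w)),
      tag_raw(TIFF_TAG[["length"]], 3L, 1L, short_val(h)),
      tag_raw(TIFF_TAG[["bits"]], 3L, 1L, short_val(16L)),
      tag_raw(TIFF_TAG[["compression"]], 3L, 1L, short_val(1L)),
      tag_raw(TIFF_TAG[["photometric"]], 3L, 1L, short_val(1L))
    )
    cur_extra <- extra_off[i]
    if (i == 1L && !is.null(desc_raw)) {
      tags <- c(tags, list(tag_raw(TIFF_TAG[["description"]], 2L,
                                   length(desc_raw), long_val(cur_extra))))
      cur_extra <- cur_extra + length(desc_raw)
    }
    tags <- c(tags, list(
      tag_raw(TIFF_TAG[["strip_offsets"]], 4L, 1L, long_val(data_off[i])),
      tag_raw(TIFF_TAG[["samples_per_pixel"]], 3L, 1L, short_val(1L)),
      tag_raw(TIFF_TAG[["rows_per_strip"]], 3L, 1L, short_val(h)),
      tag_raw(TIFF_TAG[["strip_byte_counts"]], 4L, 1L, long_val(plane_bytes))
    ))
    if (i == 1L && !is.null(resolution_ppcm)) {
      # RATIONAL stored as numerator/denominator; use ppcm * 10000 / 10000
      num <- round(resolution_ppcm * 10000)
      tags <- c(tags, list(
        tag_raw(TIFF_TAG[["x_resolution"]], 5L, 1L, long_val(cur_extra)),
        tag_raw(TIFF_TAG[["y_resolution"]], 5L, 1L, long_val(cur_extra + 8L)),
        tag_raw(TIFF_TAG[["resolution_unit"]], 3L, 1L, short_val(3L))
      ))
    }

    ids <- vapply(tags, function(t) raw_to_u16(t[1:2]), numeric(1L))
    tags <- tags[order(ids)]  # TIFF requires ascending tag order

    next_off <- if (i < n) ifd_off[i + 1L] else 0L
    writeBin(c(u16_to_raw(length(tags)), unlist(tags), u32_to_raw(next_off)),
             con)
    if (i == 1L && !is.null(desc_raw)) writeBin(desc_raw, con)
    if (i == 1L && !is.null(resolution_ppcm)) {
      num <- round(resolution_ppcm * 10000)
      writeBin(c(u32_to_raw(num), u32_to_raw(10000L),
                 u32_to_raw(num), u32_to_raw(10000L)), con)
    }
    writeBin(u16_to_raw(as.vector(t(planes[[i]]))), con)
  }
  invisible(path)
}

# --- reader -----------------------------------------------------------------

# Returns list(planes = list of numeric matrices [y, x],
#              description = character or NULL,
#              resolution_ppcm = numeric or NULL)
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (raw_to_u16(raw[3:4], endian) != 42L)
    stop("not a TIFF file (bad magic): ", path)

  rd16 <- function(off, n = 1L) raw_to_u16(raw[(off + 1L):(off + 2L * n)], endian)
  rd32 <- function(off, n = 1L) raw_to_u32(raw[(off + 1L):(off + 4L * n)], endian)

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

  read_entry_values <- function(off) {
    type <- rd16(off + 2L)
    count <- rd32(off + 4L)
    sz <- type_size[as.character(type)]
    if (is.na(sz)) return(NULL)
    total <- sz * count
    val_off <- if (total <= 4L) off + 8L else rd32(off + 8L)
    if (type == 3L) rd16(val_off, count)
    else if (type == 4L || type == 1L) rd32(val_off, count)
    else if (type == 2L) {
      bytes <- raw[(val_off + 1L):(val_off + count)]
      bytes <- bytes[bytes != as.raw(0L)]
      rawToChar(bytes)
    } else if (type == 5L) {
      v <- rd32(val_off, 2L * count)
      v[seq(1L, 2L * count, 2L)] / v[seq(2L, 2L * count, 2L)]
    } else NULL
  }

  planes <- list()
  description <- NULL
  resolution_ppcm <- NULL
  ifd_off <- rd32(4L)
  while (ifd_off != 0L) {
    n_tags <- rd16(ifd_off)
    entry <- setNames(vector("list", n_tags), NULL)
    tagval <- list()
    for (k in seq_len(n_tags)) {
      eoff <- ifd_off + 2L + 12L * (k - 1L)
      id <- rd16(eoff)
      tagval[[as.character(id)]] <- read_entry_values(eoff)
    }
    gv <- function(id, default = NULL) {
      v <- tagval[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- gv(256L); h <- gv(257L)
    if (is.null(w) || is.null(h)) stop("TIFF IFD missing image dimensions")
    bits <- gv(258L, 1L)[1L]
    if (!bits %in% c(8L, 16L))
      stop("unsupported bit depth: ", bits, " (only 8/16-bit grayscale)")
    if (gv(259L, 1L) != 1L) stop("compressed TIFF not supported")
    if (gv(277L, 1L) != 1L) stop("multi-sample (RGB) TIFF not supported")
    strip_offs <- gv(273L)
    strip_counts <- gv(279L, (h * w * bits) %/% 8L)
    pix_raw <- raw(0L)
    for (s in seq_along(strip_offs)) {
      pix_raw <- c(pix_raw,
                   raw[(strip_offs[s] + 1L):(strip_offs[s] + strip_counts[s])])
    }
    vals <- if (bits == 16L) raw_to_u16(pix_raw, endian)
            else as.integer(pix_raw)
    planes[[length(planes) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                            byrow = TRUE)
    if (is.null(description)) description <- gv(270L)
    if (is.null(resolution_ppcm)) {
      xres <- gv(282L)
      if (!is.null(xres)) {
        unit <- gv(296L, 2L)
        resolution_ppcm <- switch(as.character(unit),
                                  `2` = xres / 2.54, `3` = xres, xres)
      }
    }
    ifd_off <- rd32(ifd_off + 2L + 12L * n_tags)
  }
  if (length(planes) == 0L) stop("TIFF contains no images: ", path)
  list(planes = planes, description = description,
       resolution_ppcm = resolution_ppcm)
}
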