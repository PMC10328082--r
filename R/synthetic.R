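#' Noise model parameters
#'
#' The simulator's voxel noise model is
#' `Poisson(gain * signal) / gain + Normal(0, read_sd) + baseline`,
#' clipped to `[0, 65535]`.  `signal` is the planted expected photon count
#' per voxel, `gain` the photon gain, `read_sd` the Gaussian read noise in
#' detector units, and `baseline` a constant detector offset.  The
#' expected ROI total is therefore the planted total plus
#' `baseline * n_voxels`, which is what equal-area background subtraction
#' removes.  Pass `NULL` as the noise argument of a generator for a
#' noiseless (and unquantised) stack.
#'
#' @param gain photon gain (> 0).
#' @param read_sd Gaussian read-noise standard deviation (>= 0).
#' @param baseline constant offset in detector units (>= 0).
#' @return a `NoiseParams` list.
#' @export
noise_params <- function(gain = 1, read_sd = 2, baseline = 100) {
  stopifnot(gain > 0, read_sd >= 0, baseline >= 0)
  structure(list(gain = gain, read_sd = read_sd, baseline = baseline),
            class = "NoiseParams")
}

# Applies the noise model to an array of expected signal.  Caller is
# responsible for the RNG seed.  Returns integer-quantised intensities.
apply_noise <- function(signal, noise) {
  n <- length(signal)
  shot <- stats::rpois(n, noise$gain * as.vector(signal)) / noise$gain
  v <- shot + stats::rnorm(n, 0, noise$read_sd) + noise$baseline
  v <- round(pmin(pmax(v, 0), 65535))
  array(v, dim = dim(signal))
}

finalize_stack <- function(signal, noise, seed, pixel_size_um, z_step_um,
                           channel_names) {
  if (!is.null(noise)) {
    set.seed(seed)
    signal <- apply_noise(signal, noise)
  }
  image_stack(signal, pixel_size_um, z_step_um, channel_names)
}

# Soft-edged ellipsoid weight on the (z, y, x) grid: a Gaussian profile of
# the normalised radius, truncated at 1.5 radii.  Returns an array
# (z, y, x) of non-negative weights.
ellipsoid_weight <- function(nz, ny, nx, center_zyx, radii_zyx) {
  z <- (seq_len(nz) - 1 - center_zyx[1L]) / radii_zyx[1L]
  y <- (seq_len(ny) - 1 - center_zyx[2L]) / radii_zyx[2L]
  x <- (seq_len(nx) - 1 - center_zyx[3L]) / radii_zyx[3L]
  r2 <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  w <- exp(-2 * r2)
  w[r2 > 1] <- 0  # hard edge at the stated radius: ROIs capture all mass
  w
}

scale_to_total <- function(w, total) {
  s <- sum(w)
  if (s <= 0) stop("degenerate weight field")
  w * (total / s)
}

#' Synthetic prophase/prometaphase nucleus with controllable overlap
#'
#' One nucleus imaged in two channels ("old" and "new" histone) whose
#' spatial co-occupancy is controlled by `overlap_mix`: at 1 both channels
#' share identical spatial weights (complete colocalization), at 0 they
#' occupy disjoint half-nucleus domains (spatial separation); intermediate
#' values mix the two configurations linearly, so the expected Pearson
#' coefficient over the nucleus increases monotonically with
#' `overlap_mix`.
#'
#' @param overlap_mix fraction in `[0, 1]`.
#' @param total_old,total_new planted channel totals (photon counts).
#' @param frame `c(nz, ny, nx)` stack dimensions.
#' @param nucleus_radius_px in-plane nucleus radius.
#' @param pixel_size_um,z_step_um calibration.
#' @param noise a [noise_params()] or `NULL` for noiseless.
#' @param seed RNG seed; fixed seed and parameters give a bit-identical
#'   stack.
#' @return list with `stack` (an [image_stack()]) and `truth` (scenario
#'   parameters, the nucleus `roi`, a matched equal-area `background_roi`,
#'   and the planted totals).
#' @export
make_mitotic_early <- function(overlap_mix, total_old = 200000,
                               total_new = 200000,
                               frame = c(5, 48, 64),
                               nucleus_radius_px = 10,
                               pixel_size_um = 0.25, z_step_um = 0.5,
                               noise = noise_params(), seed = 1) {
  if (overlap_mix < 0 || overlap_mix > 1)
    stop("overlap_mix must be in [0, 1]")
  nz <- frame[1L]; ny <- frame[2L]; nx <- frame[3L]
  cz <- (nz - 1) / 2; cy <- (ny - 1) / 2; cx <- nx / 3
  if (nucleus_radius_px * 2 > min(ny, nx) / 2)
    stop("nucleus larger than frame")
  radii <- c(max((nz - 1) / 2, 1), nucleus_radius_px, nucleus_radius_px)

  u <- ellipsoid_weight(nz, ny, nx, c(cz, cy, cx), radii)
  xs <- array(rep(seq_len(nx) - 1, each = nz * ny), dim = c(nz, ny, nx))
  dom_a <- u * (xs < cx)
  dom_b <- u * (xs >= cx)

  w_old <- overlap_mix * u / sum(u) + (1 - overlap_mix) * dom_a / sum(dom_a)
  w_new <- overlap_mix * u / sum(u) + (1 - overlap_mix) * dom_b / sum(dom_b)

  signal <- array(0, dim = c(2L, nz, ny, nx))
  signal[1L, , , ] <- w_old * total_old
  signal[2L, , , ] <- w_new * total_new

  stack <- finalize_stack(signal, noise, seed, pixel_size_um, z_step_um,
                          c("old", "new"))
  margin <- nucleus_radius_px
  roi <- ellipse_roi("nucleus", c(cx, cy), c(margin, margin),
                     c(0L, nz - 1L))
  # integer-pixel translate of the signal ROI: identical pixel count
  bg <- ellipse_roi("background",
                    c(cx + round(nx - 1 - margin - cx), cy),
                    c(margin, margin), c(0L, nz - 1L))
  truth <- list(scenario = "mitotic_early", overlap_mix = overlap_mix,
                total_old = total_old, total_new = total_new,
                roi = roi, background_roi = bg, seed = seed)
  list(stack = stack, truth = truth)
}

#' Synthetic anaphase/telophase with controllable old-histone partition
#'
#' Two sister-chromatid masses whose old-histone signal is split
#' `f : (1 - f)` between mass A and mass B (new histone splits 1:1).  The
#' ground truth records the planted segregation ratio
#' `max(f, 1-f) / min(f, 1-f)`; a partition fraction of 0.574 plants the
#' canonical ratio 1.35.
#'
#' @param partition_fraction_f fraction of old-histone signal in mass A,
#'   strictly between 0 and 1.
#' @param total_old,total_new planted totals summed over both masses; the
#'   planted per-mass totals sum to these exactly (before noise).
#' @param separation_px centre-to-centre distance of the two masses; must
#'   be at least `2.5 * mass_radius_px` so the masses stay resolvable.
#' @param mass_radius_px in-plane radius of each chromatid mass.
#' @inheritParams make_mitotic_early
#' @return list with `stack` and `truth`; the truth carries per-mass ROIs
#'   (`roi_a`, `roi_b`), a matched `background_roi`, planted per-mass
#'   totals and `planted_ratio`.
#' @export
make_mitotic_late <- function(partition_fraction_f, total_old = 200000,
                              total_new = 200000, separation_px = 18,
                              mass_radius_px = 6,
                              frame = c(5, 48, 72),
                              pixel_size_um = 0.25, z_step_um = 0.5,
                              noise = noise_params(), seed = 1) {
  f <- partition_fraction_f
  if (!(f > 0 && f < 1)) stop("partition fraction must be in (0, 1)")
  if (separation_px < 2.5 * mass_radius_px)
    stop("chromatid masses overlap: separation_px must be >= 2.5 * ",
         "mass_radius_px")
  nz <- frame[1L]; ny <- frame[2L]; nx <- frame[3L]
  cz <- (nz - 1) / 2; cy <- (ny - 1) / 2
  cx_a <- nx / 2 - separation_px / 2
  cx_b <- nx / 2 + separation_px / 2
  radii <- c(max((nz - 1) / 2, 1), mass_radius_px, mass_radius_px)

  w_a <- ellipsoid_weight(nz, ny, nx, c(cz, cy, cx_a), radii)
  w_b <- ellipsoid_weight(nz, ny, nx, c(cz, cy, cx_b), radii)

  old_a <- f * total_old; old_b <- (1 - f) * total_old
  signal <- array(0, dim = c(2L, nz, ny, nx))
  signal[1L, , , ] <- scale_to_total(w_a, old_a) + scale_to_total(w_b, old_b)
  signal[2L, , , ] <- scale_to_total(w_a, total_new / 2) +
    scale_to_total(w_b, total_new / 2)

  stack <- finalize_stack(signal, noise, seed, pixel_size_um, z_step_um,
                          c("old", "new"))
  r <- mass_radius_px
  roi_a <- ellipse_roi("chromatids_A", c(cx_a, cy), c(r, r), c(0L, nz - 1L))
  roi_b <- ellipse_roi("chromatids_B", c(cx_b, cy), c(r, r), c(0L, nz - 1L))
  bg <- ellipse_roi("background",
                    c(cx_a - round(cx_a - r - 1), cy - round(cy - r - 1)),
                    c(r, r), c(0L, nz - 1L))
  truth <- list(scenario = "mitotic_late", partition_fraction_f = f,
                old_a = old_a, old_b = old_b,
                planted_ratio = max(f, 1 - f) / min(f, 1 - f),
                roi_a = roi_a, roi_b = roi_b, background_roi = bg,
                seed = seed)
  list(stack = stack, truth = truth)
}

#' Synthetic postmitotic cell pair
#'
#' Two adjacent postmitotic nuclei imaged in four channels (old and new
#' histone, the Delta reporter Dl-nLacZ, and EdU).  Delta levels, histone
#' totals, centroid separation, diameters and EdU status of both cells are
#' planted; the ground truth records the implied Delta ratio, division
#' class (ratio > 2 means asymmetric), old/new log2 ratios ordered by the
#' Delta-high cell, and quadrant.
#'
#' @param delta planted Delta totals `c(cell1, cell2)`.
#' @param old,new planted old/new histone totals `c(cell1, cell2)`.
#' @param separation_um centroid separation; must be at least the mean of
#'   the two diameters (nuclei must not overlap).
#' @param diameters_um nucleus diameters `c(cell1, cell2)`.
#' @param edu logical `c(cell1, cell2)` EdU status; positive cells are
#'   planted with `edu_total` in the EdU channel.
#' @param edu_total planted EdU total of a positive cell.
#' @inheritParams make_mitotic_early
#' @return list with `stack` and `truth`; the truth carries per-cell ROIs,
#'   a `background_roi`, and the planted pair statistics.
#' @export
make_pair <- function(delta = c(3000, 1000), old = c(30000, 19100),
                      new = c(13600, 20000), separation_um = 4,
                      diameters_um = c(4, 4), edu = c(FALSE, FALSE),
                      edu_total = 50000, frame = c(5, 48, 72),
                      pixel_size_um = 0.25, z_step_um = 0.5,
                      noise = noise_params(), seed = 1) {
  stopifnot(length(delta) == 2L, length(old) == 2L, length(new) == 2L,
            length(diameters_um) == 2L, length(edu) == 2L)
  if (separation_um < mean(diameters_um))
    stop("nuclei overlap: separation smaller than the mean diameter")
  nz <- frame[1L]; ny <- frame[2L]; nx <- frame[3L]
  sep_px <- separation_um / pixel_size_um
  r_px <- diameters_um / 2 / pixel_size_um
  cz <- (nz - 1) / 2; cy <- (ny - 1) / 2
  cx <- c(nx / 2 - sep_px / 2, nx / 2 + sep_px / 2)
  if (any(cx - 1.1 * r_px < 0) || any(cx + 1.1 * r_px > nx - 1) ||
      cy + 1.1 * max(r_px) > ny - 1)
    stop("nuclei not fully inside the frame")

  w <- lapply(1:2, function(i)
    ellipsoid_weight(nz, ny, nx, c(cz, cy, cx[i]),
                     c(max((nz - 1) / 2, 1), r_px[i], r_px[i])))

  signal <- array(0, dim = c(4L, nz, ny, nx))
  for (i in 1:2) {
    signal[1L, , , ] <- signal[1L, , , ] + scale_to_total(w[[i]], old[i])
    signal[2L, , , ] <- signal[2L, , , ] + scale_to_total(w[[i]], new[i])
    signal[3L, , , ] <- signal[3L, , , ] + scale_to_total(w[[i]], delta[i])
    if (edu[i])
      signal[4L, , , ] <- signal[4L, , , ] + scale_to_total(w[[i]],
                                                            edu_total)
  }

  stack <- finalize_stack(signal, noise, seed, pixel_size_um, z_step_um,
                          c("old", "new", "DlnLacZ", "EdU"))
  rois <- lapply(1:2, function(i)
    ellipse_roi(paste0("cell", i), c(cx[i], cy),
                c(r_px[i], r_px[i]), c(0L, nz - 1L)))
  # one background outline per cell (outlines may differ in size), each an
  # integer-pixel translate of its cell ROI into the empty bottom corners
  bgs <- lapply(1:2, function(i) {
    r_bg <- r_px[i]
    tx <- if (i == 1L) round(r_bg + 1 - cx[i]) else round(nx - 2 - r_bg - cx[i])
    ellipse_roi(paste0("background", i),
                c(cx[i] + tx, cy + round(ny - 2 - r_bg - cy)),
                c(r_bg, r_bg), c(0L, nz - 1L))
  })
  bg <- bgs[[1L]]

  hi <- which.max(delta); lo <- 3L - hi
  cls <- classify_pair_delta(delta[hi], delta[lo])
  lr <- pair_log2_ratios(old[hi], old[lo], new[hi], new[lo])
  truth <- list(scenario = "pair", delta = delta, old = old, new = new,
                separation_um = separation_um, diameters_um = diameters_um,
                edu = edu, roi1 = rois[[1L]], roi2 = rois[[2L]],
                background_roi = bg, background_rois = bgs,
                delta_ratio = cls$delta_ratio,
                delta_class = cls$delta_class,
                old_log2 = unname(lr["old_log2"]),
                new_log2 = unname(lr["new_log2"]),
                quadrant = quadrant(lr[["old_log2"]], lr[["new_log2"]]),
                seed = seed)
  list(stack = stack, truth = truth)
}

#' Synthetic midgut field with planted clusters and profile
#'
#' A single-z, multi-channel 2D field emulating a marker-stained midgut:
#' Delta-positive cells planted in clusters with a requested size
#' distribution, optional enteroendocrine (pros), mitotic (H3S10ph) and
#' polyploid (large-DAPI) cells, and an eYFP channel whose amplitude
#' follows a requested profile along x.  Cluster sites are laid out on a
#' jittered grid so distinct clusters are separated by more than
#' `cluster_spread_um + adjacency guarantee`, while cells within a cluster
#' stay within `cluster_spread_um` of the site centre.
#'
#' @param n_clusters number of Delta-positive cell clusters to plant.
#' @param size_probs probabilities of cluster sizes 1, 2, 3 (sizes are
#'   drawn i.i.d.).
#' @param n_ee,n_mitotic,n_polyploid counts of planted pros-positive,
#'   H3S10ph-positive, and polyploid (large) cells, placed on free grid
#'   sites.
#' @param eyfp_profile `NULL`, or a numeric vector of per-column eYFP
#'   amplitudes (length = field width in px), or a function of the
#'   0-based x pixel coordinate.
#' @param field_px `c(ny, nx)` field size in pixels.
#' @param pixel_size_um calibration (z step is nominal for a single-z
#'   field).
#' @param cluster_spread_um maximum offset of a cell from its cluster
#'   site.
#' @param cell_radius_px rendered nucleus radius (polyploid cells are
#'   rendered and recorded at twice this radius).
#' @param cell_total planted per-cell marker total.
#' @param render if `FALSE`, skip image synthesis and return only the
#'   ground-truth table (for large table-level simulations).
#' @inheritParams make_mitotic_early
#' @return list with `stack` (or `NULL` when `render = FALSE`) and
#'   `truth`; `truth$cells` is a data.frame with `cell_id`, `x_um`,
#'   `y_um`, `diameter_um`, logical marker columns (`delta_pos`, `ee`,
#'   `mitotic`, `polyploid`) and the planted `cluster` id (`NA` for
#'   non-Delta cells).
#' @export
make_midgut_field <- function(n_clusters = 40,
                              size_probs = c(0.877, 0.119, 0.004),
                              n_ee = 0, n_mitotic = 0, n_polyploid = 0,
                              eyfp_profile = NULL,
                              field_px = c(360, 360), pixel_size_um = 0.5,
                              cluster_spread_um = 4,
                              cell_radius_px = 3, cell_total = 20000,
                              render = TRUE,
                              noise = noise_params(), seed = 1) {
  stopifnot(length(size_probs) == 3L, abs(sum(size_probs) - 1) < 1e-9)
  ny <- field_px[1L]; nx <- field_px[2L]
  set.seed(seed)

  # grid of candidate sites; spacing guarantees clusters never merge under
  # the default 10 um adjacency radius
  spacing_um <- 2 * cluster_spread_um + 12
  spacing_px <- spacing_um / pixel_size_um
  margin_px <- spacing_px / 2
  gx <- seq(margin_px, nx - 1 - margin_px, by = spacing_px)
  gy <- seq(margin_px, ny - 1 - margin_px, by = spacing_px)
  sites <- expand.grid(x = gx, y = gy)
  n_other <- n_ee + n_mitotic + n_polyploid
  if (n_clusters + n_other > nrow(sites))
    stop("field too small for ", n_clusters, " clusters + ", n_other,
         " extra cells (", nrow(sites), " sites); enlarge field_px")
  picked <- sample.int(nrow(sites), n_clusters + n_other)

  cells <- data.frame(cell_id = character(0L), x_um = numeric(0L),
                      y_um = numeric(0L), diameter_um = numeric(0L),
                      delta_pos = logical(0L), ee = logical(0L),
                      mitotic = logical(0L), polyploid = logical(0L),
                      cluster = integer(0L))
  add_cell <- function(cells, x_px, y_px, d_um, delta_pos, ee, mitotic,
                       polyploid, cluster) {
    cells[nrow(cells) + 1L, ] <- list(
      sprintf("cell%04d", nrow(cells) + 1L), x_px * pixel_size_um,
      y_px * pixel_size_um, d_um, delta_pos, ee, mitotic, polyploid,
      cluster)
    cells
  }
  d_um <- 2 * cell_radius_px * pixel_size_um

  sizes <- sample.int(3L, n_clusters, replace = TRUE, prob = size_probs)
  spread_px <- cluster_spread_um / pixel_size_um
  for (k in seq_len(n_clusters)) {
    sx <- sites$x[picked[k]]; sy <- sites$y[picked[k]]
    for (m in seq_len(sizes[k])) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- if (sizes[k] == 1L) 0 else stats::runif(1, 0.5, 1) * spread_px
      cells <- add_cell(cells, sx + rad * cos(ang), sy + rad * sin(ang),
                        d_um, TRUE, FALSE, FALSE, FALSE, k)
    }
  }
  extra_types <- rep(c("ee", "mitotic", "polyploid"),
                     times = c(n_ee, n_mitotic, n_polyploid))
  for (t in seq_along(extra_types)) {
    sx <- sites$x[picked[n_clusters + t]]
    sy <- sites$y[picked[n_clusters + t]]
    ty <- extra_types[t]
    cells <- add_cell(cells, sx, sy,
                      if (ty == "polyploid") 2 * d_um else d_um,
                      FALSE, ty == "ee", ty == "mitotic",
                      ty == "polyploid", NA_integer_)
  }

  stack <- NULL
  if (render) {
    channels <- c("DlnLacZ", "eYFP", "pros", "H3S10ph", "DAPI")
    signal <- array(0, dim = c(length(channels), 1L, ny, nx))
    for (i in seq_len(nrow(cells))) {
      r_px <- cells$diameter_um[i] / 2 / pixel_size_um
      w <- ellipsoid_weight(1L, ny, nx,
                            c(0, cells$y_um[i] / pixel_size_um,
                              cells$x_um[i] / pixel_size_um),
                            c(1, r_px, r_px))
      blob <- matrix(scale_to_total(w, cell_total), ny, nx)
      signal[5L, 1L, , ] <- signal[5L, 1L, , ] + blob      # DAPI: all nuclei
      if (cells$delta_pos[i])
        signal[1L, 1L, , ] <- signal[1L, 1L, , ] + blob
      if (cells$ee[i]) signal[3L, 1L, , ] <- signal[3L, 1L, , ] + blob
      if (cells$mitotic[i])
        signal[4L, 1L, , ] <- signal[4L, 1L, , ] + blob
    }
    if (!is.null(eyfp_profile)) {
      amp <- if (is.function(eyfp_profile)) eyfp_profile(0:(nx - 1))
             else rep_len(as.numeric(eyfp_profile), nx)
      signal[2L, 1L, , ] <- matrix(amp, nrow = ny, ncol = nx, byrow = TRUE)
    }
    stack <- finalize_stack(signal, noise, seed + 1L, pixel_size_um, 1,
                            channels)
  }
  truth <- list(scenario = "midgut_field", cells = cells,
                cluster_sizes = sizes, size_probs = size_probs,
                eyfp_profile = eyfp_profile,
                pixel_size_um = pixel_size_um, seed = seed)
  list(stack = stack, truth = truth)
}
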