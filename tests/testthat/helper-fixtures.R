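# Shared fixture builders; everything is generated in code at test time.

# Small deterministic stack with distinct values per voxel.
tiny_stack <- function(nc = 2, nz = 3, ny = 6, nx = 7, pixel_size_um = 0.5,
                       z_step_um = 1, seed = 42) {
  set.seed(seed)
  a <- array(as.numeric(sample.int(65536L, nc * nz * ny * nx,
                                   replace = TRUE) - 1L),
             dim = c(nc, nz, ny, nx))
  image_stack(a, pixel_size_um, z_step_um,
              paste0("ch", seq_len(nc)))
}

# Axis-aligned square polygon ROI covering pixel centres x0..x1, y0..y1.
square_roi <- function(name, x0, x1, y0, y1, z_range) {
  polygon_roi(name,
              cbind(x = c(x0 - 0.5, x1 + 0.5, x1 + 0.5, x0 - 0.5),
                    y = c(y0 - 0.5, y0 - 0.5, y1 + 0.5, y1 + 0.5)),
              z_range)
}

# Brute-force union-find over all pairs: the independent clustering oracle.
uf_clusters <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

# Direct textbook Pearson correlation (the formula oracle).
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# Mid-rank assignment by brute force (ties get the average of the
# positions they occupy).
midrank_oracle <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) {
    less <- sum(v < v[i])
    eq <- sum(v == v[i])
    r[i] <- less + (1 + eq) / 2
  }
  r
}

measure_pair_cells <- function(p) {
  lapply(1:2, function(i)
    measure_cell(p$stack, p$truth[[paste0("roi", i)]],
                 p$truth$background_rois[[i]],
                 c("old", "new", "DlnLacZ"), edu_channel = "EdU"))
}
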