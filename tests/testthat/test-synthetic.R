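test_that("fixed seed and parameters give bit-identical output", {
  a <- make_mitotic_late(0.6, seed = 11)
  b <- make_mitotic_late(0.6, seed = 11)
  expect_identical(a$stack$data, b$stack$data)
  c <- make_mitotic_late(0.6, seed = 12)
  expect_false(identical(a$stack$data, c$stack$data))

  f1 <- make_midgut_field(n_clusters = 10, seed = 5)
  f2 <- make_midgut_field(n_clusters = 10, seed = 5)
  expect_identical(f1$stack$data, f2$stack$data)
  expect_identical(f1$truth$cells, f2$truth$cells)
})

test_that("noise model expectation: ROI total = planted + baseline * voxels", {
  # zero read noise, gain 1: ROI total is Poisson(planted) + constant
  n_rep <- 40
  planted <- 50000
  tot <- vapply(seq_len(n_rep), function(sd) {
    m <- make_mitotic_late(0.5, total_old = planted,
                           noise = noise_params(read_sd = 0), seed = sd)
    px_a <- nrow(roi_pixels(m$truth$roi_a, m$stack))
    px_b <- nrow(roi_pixels(m$truth$roi_b, m$stack))
    integrated_density(m$stack, m$truth$roi_a, "old") +
      integrated_density(m$stack, m$truth$roi_b, "old") -
      100 * (px_a + px_b)
  }, numeric(1))
  # Poisson sd of the total is sqrt(50000) ~ 224; mean of 40 reps has
  # se ~ 35.  5 se band.
  expect_lt(abs(mean(tot) - planted), 5 * sqrt(planted / n_rep))
})

test_that("planted chromatid totals are conserved exactly before noise", {
  m <- make_mitotic_late(0.574, total_old = 123456, noise = NULL)
  expect_equal(m$truth$old_a + m$truth$old_b, 123456)
  expect_equal(m$truth$planted_ratio, 0.574 / 0.426)
  # noiseless integrated density equals the planted per-mass total
  a <- integrated_density(m$stack, m$truth$roi_a, "old")
  b <- integrated_density(m$stack, m$truth$roi_b, "old")
  expect_equal(a, m$truth$old_a, tolerance = 1e-10)
  expect_equal(b, m$truth$old_b, tolerance = 1e-10)
})

test_that("overlap_mix monotonicity: mean Pearson increases over the sweep", {
  mixes <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(mixes, function(mx) {
    mean(vapply(1:20, function(sd) {
      s <- make_mitotic_early(mx, seed = sd)
      pearson_coloc(s$stack, s$truth$roi, "old", "new")$pearson_r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # extremes behave as stated
  s1 <- make_mitotic_early(1, noise = NULL)
  expect_equal(pearson_coloc(s1$stack, s1$truth$roi, "old", "new")$pearson_r,
               1, tolerance = 1e-12)
  s0 <- make_mitotic_early(0, noise = NULL)
  expect_lt(pearson_coloc(s0$stack, s0$truth$roi, "old", "new")$pearson_r, 0)
})

test_that("invalid generator parameters are rejected", {
  expect_error(make_mitotic_early(1.2), "overlap_mix")
  expect_error(make_mitotic_early(0.5, nucleus_radius_px = 40),
               "larger than frame")
  expect_error(make_mitotic_late(0), "\\(0, 1\\)")
  expect_error(make_mitotic_late(0.5, separation_px = 5), "overlap")
  expect_error(make_pair(separation_um = 2, diameters_um = c(4, 4)),
               "overlap")
})

test_that("pair generator records the planted pair statistics", {
  p <- make_pair(delta = c(1000, 1000), old = c(20000, 20000),
                 new = c(20000, 20000), noise = NULL)
  expect_identical(p$truth$delta_class, "symmetric")
  expect_equal(p$truth$old_log2, 0)
  expect_equal(p$truth$new_log2, 0)
  expect_identical(p$truth$quadrant, "origin")

  p2 <- make_pair(delta = c(3000, 1000), old = c(31400, 20000),
                  new = c(13600, 20000), noise = NULL)
  expect_identical(p2$truth$delta_class, "asymmetric")
  expect_equal(p2$truth$old_log2, log2(1.57), tolerance = 1e-12)
  expect_identical(p2$truth$quadrant, "IV")
  # EdU channel present with planted amplitude only for positive cells
  p3 <- make_pair(edu = c(TRUE, FALSE), noise = NULL)
  e1 <- integrated_density(p3$stack, p3$truth$roi1, "EdU")
  e2 <- integrated_density(p3$stack, p3$truth$roi2, "EdU")
  expect_gt(e1, 1000)
  expect_equal(e2, 0)
})

test_that("midgut field plants the requested cells and clusters", {
  f <- make_midgut_field(n_clusters = 12, size_probs = c(1, 0, 0),
                         n_ee = 3, n_mitotic = 2, n_polyploid = 1,
                         seed = 2)
  cells <- f$truth$cells
  expect_identical(sum(cells$delta_pos), 12L)
  expect_identical(sum(cells$ee), 3L)
  expect_identical(sum(cells$mitotic), 2L)
  expect_identical(sum(cells$polyploid), 1L)
  # all-singleton field: every planted cluster has one cell
  cs <- cluster_cells(cells[cells$delta_pos, ], 10)
  expect_identical(unname(cluster_size_distribution(cs)),
                   c(100, 0, 0))
  # planted cluster ids agree with recovered components
  expect_identical(length(unique(cs$cells$cluster)), 12L)
})

test_that("planted cluster-size distribution is recovered within multinomial error", {
  probs <- c(0.877, 0.119, 0.004)
  f <- make_midgut_field(n_clusters = 250, size_probs = probs,
                         field_px = c(1200, 1200), render = FALSE, seed = 9)
  cs <- cluster_cells(f$truth$cells[f$truth$cells$delta_pos, ], 10)
  got <- cluster_size_distribution(cs) / 100
  # recovered clustering must equal the planted size draw exactly
  # (placement guarantees separation), so compare against the draw
  expect_identical(length(cs$sizes), 250L)
  planted_tab <- tabulate(pmin(f$truth$cluster_sizes, 3L), 3L) / 250
  expect_equal(unname(got), planted_tab, tolerance = 1e-12)
  # and the draw itself is within ~4 sd of the multinomial expectation
  se <- sqrt(probs * (1 - probs) / 250)
  expect_true(all(abs(planted_tab - probs) < 4 * se + 1e-9))
})

test_that("step-function eYFP profile is reproduced by block averaging", {
  nx <- 240
  amp <- c(rep(2000, 120), rep(6000, 120))
  f <- make_midgut_field(n_clusters = 0, eyfp_profile = amp,
                         field_px = c(120, nx),
                         noise = noise_params(read_sd = 1), seed = 3)
  tr <- profile_trace(f$stack, cbind(x = c(0, nx - 1), y = c(60, 60)),
                      "eYFP", width_px = 80)
  bm <- block_average(tr, block = 100)
  # first block fully in the low phase, second straddles, low < high
  expect_equal(bm[1], 2100, tolerance = 0.02)  # +100 baseline
  expect_gt(bm[2], bm[1])
})
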