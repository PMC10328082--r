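test_that("single-linkage clustering: singletons, chains, and the union-find oracle", {
  far <- data.frame(cell_id = c("a", "b", "c"),
                    x_um = c(0, 50, 100), y_um = 0)
  cs <- cluster_cells(far, 10)
  expect_identical(length(cs$sizes), 3L)
  expect_identical(unname(cs$size_histogram), c(3L, 0L, 0L))

  chain <- data.frame(cell_id = c("a", "b", "c"),
                      x_um = c(0, 9, 18), y_um = 0)  # AC = 18 > 10
  cs2 <- cluster_cells(chain, 10)
  expect_identical(length(cs2$sizes), 1L)
  expect_identical(cs2$sizes, 3L)

  set.seed(33)
  rnd <- data.frame(cell_id = paste0("c", 1:200),
                    x_um = runif(200, 0, 150), y_um = runif(200, 0, 150))
  cs3 <- cluster_cells(rnd, 8)
  oracle <- uf_clusters(rnd$x_um, rnd$y_um, 8)
  # identical partitions up to label permutation
  expect_identical(length(unique(cs3$cells$cluster)),
                   length(unique(oracle)))
  cross <- table(cs3$cells$cluster, oracle)
  expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))

  # partition property: sizes sum to the cell count
  expect_identical(sum(cs3$sizes), 200L)
  # radius monotonicity: growing the radius never splits clusters
  for (r in c(2, 4, 8, 16)) {
    n_r <- length(cluster_cells(rnd, r)$sizes)
    n_r2 <- length(cluster_cells(rnd, r * 2)$sizes)
    expect_lte(n_r2, n_r)
  }
})

test_that("cluster size distribution and single-cell fraction denominators", {
  cells <- data.frame(cell_id = paste0("c", 1:9),
                      x_um = c(0, 100, 101, 200, 201, 202, 203, 204, 300),
                      y_um = 0)
  cs <- cluster_cells(cells, 2)
  # sizes: 1, 2, 5, 1
  expect_identical(sort(cs$sizes), c(1L, 1L, 2L, 5L))
  expect_equal(unname(cluster_size_distribution(cs)), c(50, 25, 25))
  expect_equal(single_cell_fraction(cs), 100 * 2 / 9)

  # identity: sum over sizes of size * count = total cells
  expect_identical(sum(cs$sizes), 9L)
  # all-singleton field
  solo <- data.frame(cell_id = c("a", "b"), x_um = c(0, 50), y_um = 0)
  expect_equal(single_cell_fraction(cluster_cells(solo, 5)), 100)
  expect_error(cluster_size_distribution(cluster_cells(solo[0, ], 5)),
               "empty")
})

test_that("count_positive respects markers and regions", {
  cells <- data.frame(cell_id = paste0("c", 1:6),
                      x_um = c(5, 15, 25, 35, 45, 55), y_um = 10,
                      mitotic = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                      delta_pos = TRUE)
  expect_identical(count_positive(cells, "mitotic"), 4L)
  expect_error(count_positive(cells, "nope"), "unknown marker")
  # region in pixel coords at 1 um/px: x in [0, 30)
  region <- polygon_roi("r", cbind(x = c(-0.5, 29.5, 29.5, -0.5),
                                   y = c(-0.5, -0.5, 20, 20)), c(0, 0))
  expect_identical(count_positive(cells, "mitotic", region,
                                  pixel_size_um = 1), 2L)
  empty <- polygon_roi("e", cbind(x = c(100, 110, 110, 100),
                                  y = c(100, 100, 110, 110)), c(0, 0))
  expect_identical(count_positive(cells, "mitotic", empty,
                                  pixel_size_um = 1), 0L)
})

test_that("percent_positive summarises regions and excludes empty ones", {
  r <- percent_positive(c(100, 50), c(100, 50))
  expect_equal(r$per_region, c(100, 100))
  expect_equal(r$mean, 100)

  r2 <- percent_positive(c(2, 3), c(100, 100))
  expect_equal(r2$mean, 2.5)
  expect_equal(r2$sem, 0.5)

  expect_warning(r3 <- percent_positive(c(2, 0), c(100, 0)), "zero total")
  expect_equal(r3$mean, 2)
  # planted 95% positivity over 25 regions within binomial error
  set.seed(12)
  pos <- rbinom(25, 100, 0.95)
  r4 <- percent_positive(pos, rep(100, 25))
  expect_lt(abs(r4$mean - 95), 4 * sqrt(0.95 * 0.05 / 25) * 100)
})

test_that("profile tracing: constant field, width collapse, and step response", {
  a <- array(7, dim = c(1, 1, 40, 200))
  s <- image_stack(a, 1, 1, "eYFP")
  tr <- profile_trace(s, cbind(x = c(0, 199), y = c(20, 20)), "eYFP",
                      width_px = 10)
  expect_true(all(abs(tr$mean_intensity - 7) < 1e-12))

  # field varying only along x: any width reproduces the single-row profile
  a2 <- array(0, dim = c(1, 1, 40, 200))
  for (x in 1:200) a2[1, 1, , x] <- x
  s2 <- image_stack(a2, 1, 1, "eYFP")
  tr2 <- profile_trace(s2, cbind(x = c(0, 199), y = c(20, 20)), "eYFP",
                       width_px = 30)
  expect_equal(tr2$mean_intensity, as.numeric(1:200), tolerance = 1e-12)

  # step at x = 100 recovered within half the width
  a3 <- array(1000, dim = c(1, 1, 60, 200))
  a3[1, 1, , 101:200] <- 3000
  s3 <- image_stack(a3, 1, 1, "eYFP")
  tr3 <- profile_trace(s3, cbind(x = c(0, 199), y = c(30, 30)), "eYFP",
                       width_px = 20)
  crossing <- min(which(tr3$mean_intensity > 2000))
  expect_lt(abs(crossing - 101), 10 + 1)
  expect_error(profile_trace(s3, cbind(x = 1, y = 1), "eYFP"), "2 vertices")

  # profiling a z-stack equals profiling its max projection
  szm <- tiny_stack(nc = 1, nz = 4, ny = 30, nx = 80, seed = 6)
  names(szm$channel_names) <- NULL
  proj <- image_stack(array(max_project(szm, "ch1"),
                            dim = c(1, 1, 30, 80)), 0.5, 1, "ch1")
  p1 <- profile_trace(szm, cbind(x = c(0, 79), y = c(15, 15)), "ch1",
                      width_px = 9)
  p2 <- profile_trace(proj, cbind(x = c(0, 79), y = c(15, 15)), "ch1",
                      width_px = 9)
  expect_identical(p1$mean_intensity, p2$mean_intensity)
})

test_that("block averaging: exact blocks, closed-form ramp, trailing drop", {
  expect_equal(block_average(rep(5, 3000), 1000), c(5, 5, 5))
  expect_equal(block_average(as.numeric(1:2000), 1000), c(500.5, 1500.5))
  expect_length(block_average(rep(1, 2999), 1000), 2)
  expect_error(block_average(rep(1, 500), 1000), "shorter")
  # global-mean preservation on exact multiples
  set.seed(3)
  v <- runif(4000)
  expect_equal(mean(block_average(v, 1000)), mean(v), tolerance = 1e-12)
})
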