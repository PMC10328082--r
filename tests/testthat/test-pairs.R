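mk_cells <- function(n, dist = 3, diam = c(8, 8), edu = c(FALSE, FALSE),
                     old = c(200, 100), new = c(100, 200),
                     delta = c(300, 100)) {
  data.frame(cell_id = paste0("c", seq_len(n)),
             x_um = c(0, dist, 40, 60, 80)[seq_len(n)],
             y_um = 0,
             diameter_um = rep_len(diam, n),
             edu_positive = rep_len(edu, n),
             old = rep_len(old, n), new = rep_len(new, n),
             delta = rep_len(delta, n))
}

test_that("pair filter applies each eligibility rule with a reason", {
  # distance 6 um > 5 -> rejected (distance)
  cells <- mk_cells(2, dist = 6)
  flt <- pair_filter(cells, candidates = cbind(1, 2))
  expect_identical(nrow(flt$eligible), 0L)
  expect_identical(flt$rejected$reason, "distance")

  # diameters 12 and 7.5 um: ratio 1.6 -> rejected (size)
  cells <- mk_cells(2, dist = 3, diam = c(12, 7.5))
  flt <- pair_filter(cells, candidates = cbind(1, 2))
  expect_identical(flt$rejected$reason, "size")

  # one EdU-positive cell -> rejected (EdU)
  cells <- mk_cells(2, edu = c(TRUE, FALSE))
  flt <- pair_filter(cells, candidates = cbind(1, 2))
  expect_identical(flt$rejected$reason, "EdU")

  # non-quantifiable old histone -> rejected (quantifiability)
  cells <- mk_cells(2, old = c(0, 100))
  flt <- pair_filter(cells, candidates = cbind(1, 2))
  expect_identical(flt$rejected$reason, "quantifiability")

  # all rules pass
  cells <- mk_cells(2)
  flt <- pair_filter(cells, candidates = cbind(1, 2))
  expect_identical(nrow(flt$eligible), 1L)

  # boundary: exactly 5 um and exactly 1.5x are eligible
  cells <- mk_cells(2, dist = 5, diam = c(9, 6))
  flt <- pair_filter(cells, candidates = cbind(1, 2))
  expect_identical(nrow(flt$eligible), 1L)

  # auto-candidate mode only considers cells within range
  cells <- mk_cells(5)
  flt <- pair_filter(cells)
  expect_identical(nrow(flt$eligible), 1L)
})

test_that("Delta classification: rule, boundary, and relabeling invariance", {
  expect_identical(classify_pair_delta(300, 100),
                   list(delta_ratio = 3, delta_class = "asymmetric"))
  expect_identical(classify_pair_delta(150, 100)$delta_class, "symmetric")
  expect_identical(classify_pair_delta(200, 100)$delta_class, "symmetric")
  expect_identical(classify_pair_delta(100, 300),
                   classify_pair_delta(300, 100))
  expect_error(classify_pair_delta(0, 10), "positive")
})

test_that("log2 ratios: arithmetic oracle, antisymmetry, fold composition", {
  expect_identical(unname(pair_log2_ratios(100, 100, 100, 100)), c(0, 0))
  lr <- pair_log2_ratios(157, 100, 100, 147)
  expect_equal(unname(lr), c(log2(1.57), -log2(1.47)), tolerance = 1e-12)

  set.seed(14)
  for (i in 1:20) {
    v <- runif(4, 10, 1000)
    lr <- pair_log2_ratios(v[1], v[2], v[3], v[4])
    expect_equal(unname(lr),
                 c(log2(v[1] / v[2]), log2(v[3] / v[4])), tolerance = 1e-12)
    swapped <- pair_log2_ratios(v[2], v[1], v[4], v[3])
    expect_equal(unname(swapped), -unname(lr), tolerance = 1e-12)
    # fold_from_log2 inverts a planted pure ratio
    expect_equal(fold_from_log2(lr[["old_log2"]]),
                 max(v[1] / v[2], v[2] / v[1]), tolerance = 1e-12)
  }
  expect_error(pair_log2_ratios(0, 1, 1, 1), "positive")
})

test_that("fold changes match the published correspondences", {
  expect_equal(round(fold_from_log2(0.65), 2), 1.57)
  expect_equal(round(fold_from_log2(-0.56), 2), 1.47)
  expect_equal(round(fold_from_log2(0.45), 2), 1.37)
  expect_equal(round(fold_from_log2(-0.50), 2), 1.41)
  expect_identical(fold_from_log2(0), 1)
})

test_that("quadrant assignment covers the plane", {
  expect_identical(quadrant(0.65, -0.56), "IV")
  expect_identical(quadrant(0.3, 0.2), "I")
  expect_identical(quadrant(-0.3, 0.2), "II")
  expect_identical(quadrant(-0.3, -0.2), "III")
  expect_identical(quadrant(0, 0), "origin")
  expect_error(quadrant(Inf, 0), "finite")
})

test_that("pair records order cells by Delta with deterministic ties", {
  cells <- mk_cells(2, delta = c(100, 300))   # cell2 is Delta-high
  pr <- pair_records(cells)
  expect_identical(pr$cell1, "c2")
  expect_identical(pr$delta_class, "asymmetric")
  # tie: ordered by cell id
  cells_tie <- mk_cells(2, delta = c(100, 100))
  pr_tie <- pair_records(cells_tie)
  expect_identical(pr_tie$cell1, "c1")
  expect_identical(pr_tie$quadrant, quadrant(pr_tie$old_log2,
                                             pr_tie$new_log2))
})

test_that("pair summary: per-specimen averaging with pooled counts", {
  pairs <- data.frame(
    specimen_id = rep(c("g1", "g2"), times = c(5, 5)),
    delta_class = c(rep("asymmetric", 4), "symmetric",
                    rep("asymmetric", 3), rep("symmetric", 2)),
    old_log2 = rnorm(10), new_log2 = rnorm(10))
  sm <- pair_summary(pairs)
  expect_equal(unname(sm$prop_asymmetric["mean"]), 70)
  expect_equal(unname(sm$prop_asymmetric["sem"]), 10)
  expect_identical(unname(sm$pooled_counts), c(7L, 3L))
  expect_identical(sum(sm$log2_by_class$n), 10L)

  all_sym <- data.frame(specimen_id = "g1",
                        delta_class = rep("symmetric", 4),
                        old_log2 = 0, new_log2 = 0)
  sm2 <- pair_summary(all_sym)
  expect_equal(unname(sm2$prop_asymmetric["mean"]), 0)
  expect_equal(unname(sm2$prop_symmetric["mean"]), 100)
})

test_that("planted pair classes and quadrants are recovered >= 95% end-to-end", {
  n_ok_class <- 0L
  n_ok_quad <- 0L
  n <- 60L
  for (k in seq_len(n)) {
    asym <- k %% 2L == 0L
    p <- make_pair(
      delta = if (asym) c(3000, 1000) else c(1600, 1100),
      old = if (asym) c(30000, 19100) else c(21000, 20000),
      new = if (asym) c(13600, 20000) else c(20500, 20000),
      seed = 1000L + k)
    pr <- pair_records(measure_pair_cells(p))
    if (nrow(pr) == 1L) {
      if (pr$delta_class == p$truth$delta_class)
        n_ok_class <- n_ok_class + 1L
      if (pr$quadrant == p$truth$quadrant) n_ok_quad <- n_ok_quad + 1L
    }
  }
  expect_gte(n_ok_class, ceiling(0.95 * n))
  expect_gte(n_ok_quad, ceiling(0.95 * n))
})

test_that("simulated cohort recovers a planted per-specimen asymmetric share", {
  # 4 specimens x 30 pairs, planted 80% asymmetric
  set.seed(17)
  pairs <- do.call(rbind, lapply(1:4, function(g) {
    asym <- rbinom(30, 1, 0.8) == 1
    data.frame(specimen_id = paste0("g", g),
               delta_class = ifelse(asym, "asymmetric", "symmetric"),
               old_log2 = rnorm(30, ifelse(asym, 0.65, 0), 0.3),
               new_log2 = rnorm(30, ifelse(asym, -0.56, 0), 0.3))
  }))
  sm <- pair_summary(pairs)
  # binomial sd per specimen ~ sqrt(.8*.2/30) = 7.3%; mean of 4 ~ 3.7%
  expect_lt(abs(sm$prop_asymmetric[["mean"]] - 80), 4 * 3.7)
})
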