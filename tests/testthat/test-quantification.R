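simple_roi <- function(values, voxel = 5) {
  n <- length(values)
  v <- voxel_volume(array(values, c(1, 1, n)), voxel)
  m <- label_mask(array(1L, c(1, 1, n)), c("1" = "roi"))
  list(volume = v, mask = m)
}

test_that("roi statistics use the population SD and respect include masks", {
  fx <- simple_roi(c(2, 2, 2, 2))
  st <- roi_stats(fx$volume, fx$mask)
  expect_equal(st$mean, 2); expect_equal(st$sd, 0)
  expect_identical(st$n_voxels, 4L)

  fx <- simple_roi(c(1, 2, 3, 4))
  st <- roi_stats(fx$volume, fx$mask)
  expect_equal(st$mean, 2.5)
  expect_equal(st$sd, sqrt(1.25))  # population SD by hand
  expect_equal(st$min, 1); expect_equal(st$max, 4)

  # include mask restricts the population
  inc <- array(c(TRUE, TRUE, FALSE, FALSE), c(1, 1, 4))
  st2 <- roi_stats(fx$volume, fx$mask, include = inc)
  expect_equal(st2$mean, 1.5)
  expect_error(roi_stats(fx$volume, fx$mask, include = !inc & FALSE),
               "empty ROI")
  # geometry is checked before computing
  bad <- label_mask(array(1L, c(2, 2, 2)), c("1" = "roi"))
  expect_error(roi_stats(fx$volume, bad), "geometry mismatch")
})

test_that("large-sample ROI stats recover generator ground truth", {
  set.seed(123)
  n <- 1e5
  v <- voxel_volume(array(stats::rnorm(n, 100, 8), c(50, 50, 40)), 5)
  m <- label_mask(array(1L, c(50, 50, 40)), c("1" = "tissue"))
  st <- roi_stats(v, m)
  expect_lt(abs(st$mean - 100), 0.1)
  expect_lt(abs(st$sd - 8), 0.1)
  expect_equal(wt_background_threshold(st), c(tissue = st$mean + st$sd))
  expect_lt(abs(wt_background_threshold(st) - 108), 0.2)
})

test_that("background threshold and corrected means follow the mean + 1 SD rule", {
  st <- data.frame(name = "r", mean = 100, sd = 10)
  expect_equal(unname(wt_background_threshold(st)), 110)
  st0 <- data.frame(name = "r", mean = 77, sd = 0)
  expect_equal(unname(wt_background_threshold(st0)), 77)

  lacz <- data.frame(name = c("a", "b", "c"),
                     mean = c(130, 105, 90), sd = c(5, 5, 5))
  wt <- data.frame(name = c("a", "b", "c"),
                   mean = c(100, 100, 100), sd = c(10, 10, 10))
  out <- corrected_region_means(lacz, wt)
  expect_equal(out$corrected, c(20, 0, 0))  # 130-110; clamped below
  raw <- corrected_region_means(lacz, wt, clamp = FALSE)
  expect_equal(raw$corrected, c(20, -5, -20))
  expect_error(corrected_region_means(lacz, wt[1:2, ]), "pairing error")
})

test_that("self-subtraction is exactly null", {
  set.seed(5)
  fx <- simple_roi(stats::rnorm(500, 80, 8))
  st <- roi_stats(fx$volume, fx$mask)
  out <- corrected_region_means(st, st)
  # lacz mean - (mean + sd) < 0 always, clamped to exactly 0
  expect_identical(out$corrected, 0)
  img <- corrected_voxel_image(fx$volume, fx$mask, st)
  expect_true(all(img$data[fx$volume$data <= st$mean + st$sd] == 0))
})

test_that("per-voxel correction matches a brute-force loop over two ROIs", {
  set.seed(6)
  shape <- c(3, 4, 5)
  vol <- voxel_volume(array(stats::runif(prod(shape), 0, 150), shape), 5)
  roi <- array(0L, shape); roi[1, , ] <- 1L; roi[3, , ] <- 2L
  mask <- label_mask(roi, c("1" = "ROIc", "2" = "ROIh"))
  wt <- data.frame(name = c("ROIc", "ROIh"), mean = c(60, 90), sd = c(5, 8))
  img <- corrected_voxel_image(vol, mask, wt)
  for (i in 1:3) for (j in 1:4) for (k in 1:5) {
    expected <- if (roi[i, j, k] == 1L) max(vol$data[i, j, k] - 65, 0)
      else if (roi[i, j, k] == 2L) max(vol$data[i, j, k] - 98, 0)
      else 0
    expect_equal(img$data[i, j, k], expected)
  }
  # uniform ROI arithmetic and all-zero clamp
  u <- simple_roi(rep(120, 8))
  wtu <- data.frame(name = "roi", mean = 100, sd = 10)
  expect_true(all(corrected_voxel_image(u$volume, u$mask, wtu)$data == 10))
  wthi <- data.frame(name = "roi", mean = 150, sd = 10)
  expect_true(all(corrected_voxel_image(u$volume, u$mask, wthi)$data == 0))
  expect_error(corrected_voxel_image(u$volume, u$mask,
                                     data.frame(name = "other", mean = 1,
                                                sd = 1)),
               "pairing error")
})

test_that("grade thresholds sit at mean + 1/2/3 SD", {
  t1 <- grade_thresholds(data.frame(mean = 0, sd = 1))
  expect_equal(c(t1$t1, t1$t2, t1$t3), c(1, 2, 3))
  t2 <- grade_thresholds(data.frame(mean = 50, sd = 5), source = "WT")
  expect_equal(c(t2$t1, t2$t2, t2$t3), c(55, 60, 65))
  expect_identical(t2$source, "WT")
  expect_warning(t0 <- grade_thresholds(data.frame(mean = 7, sd = 0)),
                 "degenerate")
  expect_equal(c(t0$t1, t0$t2, t0$t3), c(7, 7, 7))
})

test_that("grading follows the half-open bin convention and conserves counts", {
  fx <- simple_roi(c(0.5, 1.5, 2.5, 3.5))
  thr <- grade_thresholds(data.frame(mean = 0, sd = 1))
  g <- grade_volume(fx$volume, thr, roi = fx$mask)
  expect_identical(as.vector(g$data[1, 1, ]), c(0L, 1L, 2L, 3L))
  expect_equal(unname(g$counts), c(1, 1, 1, 1))
  expect_equal(sum(g$counts), g$n_graded)
  # boundary values are inclusive at each threshold
  fb <- simple_roi(c(1, 2, 3))
  gb <- grade_volume(fb$volume, thr, roi = fb$mask)
  expect_identical(as.vector(gb$data[1, 1, ]), c(1L, 2L, 3L))
  # degenerate sd: at/above the mean means grade 3
  suppressWarnings(thr0 <- grade_thresholds(data.frame(mean = 2, sd = 0)))
  g0 <- grade_volume(fb$volume, thr0, roi = fb$mask)
  expect_identical(as.vector(g0$data[1, 1, ]), c(0L, 3L, 3L))
})

test_that("raising a voxel's value never lowers its grade", {
  set.seed(11)
  fx <- simple_roi(stats::rnorm(200, 50, 10))
  thr <- grade_thresholds(data.frame(mean = 50, sd = 10))
  g1 <- grade_volume(fx$volume, thr, roi = fx$mask)
  bumped <- fx$volume
  bumped$data <- bumped$data + array(abs(stats::rnorm(200, 5, 5)),
                                     dim(bumped$data))
  g2 <- grade_volume(bumped, thr, roi = fx$mask)
  sel <- g1$data != 255L
  expect_true(all(g2$data[sel] >= g1$data[sel]))
})

test_that("graded fractions on pure noise approach the normal tail masses", {
  set.seed(77)
  n <- 2e5
  v <- voxel_volume(array(stats::rnorm(n, 100, 8), c(50, 50, 80)), 5)
  m <- label_mask(array(1L, dim(v$data)), c("1" = "roi"))
  thr <- grade_thresholds(roi_stats(v, m), source = "SELF")
  g <- grade_volume(v, thr, roi = m)
  expected <- c(stats::pnorm(1),
                stats::pnorm(2) - stats::pnorm(1),
                stats::pnorm(3) - stats::pnorm(2),
                1 - stats::pnorm(3))
  se <- sqrt(expected * (1 - expected) / n)
  # generous 4 SE here (thresholds are themselves estimated); the acceptance
  # suite runs the tighter 3-SE check at n = 1e6
  expect_true(all(abs(g$fractions - expected) < 4 * se + 2e-4))
})

test_that("disjoint ROI grade maps merge with additive counts; overlaps error", {
  shape <- c(1, 1, 3)
  thr <- grade_thresholds(data.frame(mean = 0, sd = 1))
  single <- function(pos, value) {
    v <- const_volume(shape, 0); v$data[1, 1, pos] <- value
    m <- array(0L, shape); m[1, 1, pos] <- 1L
    grade_volume(v, thr, roi = label_mask(m, c("1" = paste0("r", pos))))
  }
  maps <- list(single(1, 1.5), single(2, 2.5), single(3, 3.5))
  merged <- merge_roi_grades(maps)
  expect_equal(unname(merged$fractions[c("low", "intermediate", "high")]),
               rep(1 / 3, 3))
  expect_identical(merged$n_graded, 3)
  expect_named(merged$thresholds, c("r1", "r2", "r3"))
  expect_error(merge_roi_grades(list(single(1, 1), single(1, 2))),
               "overlap error")
})
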