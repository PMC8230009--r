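test_that("identical specs generate bit-identical phantoms", {
  spec <- phantom_spec(seed = 31)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  c <- generate_phantom(phantom_spec(seed = 32))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("a noiseless spec yields a piecewise-constant volume matching its means", {
  spec <- phantom_spec(
    paraffin = c(mean = 20, sd = 0),
    tissue_rois = list(list(name = "cerebrum",
                            geometry = geom_ellipsoid(c(20, 40, 28),
                                                      c(14, 24, 17)),
                            mean = 80, sd = 0)),
    deposits = list(list(roi_name = "cerebrum",
                         geometry = geom_box(c(18, 36, 24), c(22, 44, 32)),
                         activity = 24)),
    calibration = list(
      water = list(mean = 200, sd = 0,
                   geometry = geom_box(c(1, 1, 1), c(40, 6, 80))),
      air = list(mean = 10, sd = 0,
                 geometry = geom_box(c(1, 75, 1), c(40, 80, 80)))),
    seed = 1)
  ph <- generate_phantom(spec)
  m <- ph$mask$data; v <- ph$volume$data; dep <- ph$truth$deposit_mask$data
  expect_setequal(unique(v[m == 1L & dep == 0L]), 20)
  expect_setequal(unique(v[m == 2L]), 200)
  expect_setequal(unique(v[m == 3L]), 10)
  expect_setequal(unique(v[m == 4L & dep == 0L]), 80)
  expect_setequal(unique(v[dep == 1L]), 80 + 24)  # delta = kappa * activity
  # truth table is verifiable against the emitted volume by brute force
  for (r in seq_len(nrow(ph$truth$regions))) {
    row <- ph$truth$regions[r, ]
    expect_identical(sum(m == row$label), as.integer(row$n_voxels))
  }
})

test_that("deposit regions carry the stated density excess under noise", {
  spec <- phantom_spec(seed = 17)  # deposit activity 24 = 3 tissue SDs
  ph <- generate_phantom(spec)
  dep <- ph$truth$deposit_mask$data == 1L
  n <- sum(dep)
  expect_gt(n, 1e3)
  # realized deposit-region mean ~ tissue mean + delta within 3 SE
  expect_lt(abs(mean(ph$volume$data[dep]) - (80 + 24)), 3 * 8 / sqrt(n))
  # deposits must stay inside their ROI
  bad <- phantom_spec(deposits = list(list(
    roi_name = "cerebrum",
    geometry = geom_box(c(1, 1, 1), c(40, 80, 80)), activity = 5)))
  expect_error(generate_phantom(bad), "outside its ROI")
})

test_that("matched pairs share geometry, differ only in deposits", {
  spec <- phantom_spec(seed = 41)
  pair <- generate_pair(spec)
  expect_identical(pair$lacz$mask$data, pair$wt$mask$data)
  expect_identical(nrow(pair$wt$truth$deposits), 0L)
  expect_false(identical(pair$lacz$volume$data, pair$wt$volume$data))
  # with no deposits the two phantoms are statistically exchangeable
  null_spec <- phantom_spec(deposits = list(), seed = 43)
  np <- generate_pair(null_spec)
  for (lab in c(4L, 5L)) {
    sel <- np$lacz$mask$data == lab
    n <- sum(sel)
    d <- mean(np$lacz$volume$data[sel]) - mean(np$wt$volume$data[sel])
    expect_lt(abs(d), 3 * 8 * sqrt(2 / n))
  }
  # with a deposit, the ROI mean excess ~ delta * (deposit volume / ROI volume)
  sel <- pair$lacz$mask$data == 4L
  f <- pair$lacz$truth$deposits$n_voxels / sum(sel)
  excess <- mean(pair$lacz$volume$data[sel]) - mean(pair$wt$volume$data[sel])
  expect_lt(abs(excess - 24 * f), 3 * 9 * sqrt(2 / sum(sel)))
})

test_that("layer phantom: noiseless step plus boundary band peaks at the boundary", {
  spec <- layer_phantom_spec(paraffin = c(mean = 20, sd = 0),
                             molecular = c(mean = 60, sd = 0),
                             granular = c(mean = 90, sd = 0),
                             band = NULL, seed = 1)
  ph <- generate_layer_phantom(spec)
  mid <- ph$volume$data[8, 20, ]
  expect_setequal(unique(mid[7:54]), 60)   # molecular side
  expect_setequal(unique(mid[55:94]), 90)  # granular side
  # closed form of step + Gaussian bump: maximum at the boundary column
  spec2 <- layer_phantom_spec(paraffin = c(mean = 20, sd = 0),
                              molecular = c(mean = 60, sd = 0),
                              granular = c(mean = 90, sd = 0), seed = 1)
  ph2 <- generate_layer_phantom(spec2)
  prof <- ph2$volume$data[8, 20, 7:94]
  expect_identical(which.max(prof) + 6L, 55L)
  # wild-type variant (delta 0) agrees on the granular side far from the band
  far <- 75:94
  expect_equal(ph$volume$data[8, 20, far], ph2$volume$data[8, 20, far],
               tolerance = 1e-4)
})

test_that("student-t noise option keeps the stated mean and SD scale", {
  spec <- phantom_spec(noise = "student_t", seed = 13)
  ph <- generate_phantom(spec)
  sel <- ph$mask$data == 4L & ph$truth$deposit_mask$data == 0L
  expect_lt(abs(mean(ph$volume$data[sel]) - 80), 0.5)
  expect_lt(abs(stats::sd(ph$volume$data[sel]) - 8), 0.5)
})

test_that("phantom volumes and truth flow through the writers", {
  ph <- generate_layer_phantom(layer_phantom_spec(seed = 2))
  dir <- withr::local_tempdir()
  write_volume(ph$volume, file.path(dir, "v.tif"), "f32")
  write_mask(ph$mask, file.path(dir, "m.tif"))
  write_truth_json(ph, file.path(dir, "truth.json"))
  back <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_equal(back$boundary_col, 55)
  expect_identical(read_mask(file.path(dir, "m.tif"),
                             ph$mask$labels)$data, ph$mask$data)
})
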