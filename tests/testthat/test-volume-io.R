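test_that("a directory of equal slices assembles in lexicographic order", {
  dir <- withr::local_tempdir()
  # filenames chosen so lexicographic != numeric order: s1, s10, s2
  for (nm in c("s1", "s2", "s10")) {
    val <- switch(nm, s1 = 7, s2 = 9, s10 = 8)
    write_slice_tiff(matrix(val, 4, 5), file.path(dir, paste0(nm, ".tif")))
  }
  jsonlite::write_json(list(voxel_size_um = 5), file.path(dir, "volume.json"),
                       auto_unbox = TRUE)
  v <- read_volume(dir)
  expect_identical(dim(v$data), c(3L, 4L, 5L))
  expect_equal(v$data[1, , ], matrix(7, 4, 5))
  expect_equal(v$data[2, , ], matrix(8, 4, 5))  # s10 sorts before s2
  expect_equal(v$data[3, , ], matrix(9, 4, 5))
  expect_identical(v$units, "RAW_GRAY")
  # reading the same directory twice is deterministic
  expect_identical(read_volume(dir)$data, v$data)
})

test_that("f32 write/read round trip is bit-exact (independent per-pixel check)", {
  for (seed in c(11, 22, 33)) {
    v <- random_f32_volume(c(4, 4, 4), seed)
    f <- withr::local_tempfile(fileext = ".tif")
    write_volume(v, f, "f32")
    r <- read_volume(f)
    expect_identical(r$units, "RAW_GRAY")
    expect_equal(r$voxel_size_um, 5)
    # exhaustive voxel-by-voxel comparison against the source array
    for (i in 1:4) for (j in 1:4)
      expect_identical(unname(r$data[i, j, ]), unname(v$data[i, j, ]))
  }
})

test_that("multi-page values are preserved exactly in page order", {
  arr <- array(0, c(2, 2, 2))
  arr[1, , ] <- matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE)
  arr[2, , ] <- matrix(c(4, 5, 6, 7), 2, 2, byrow = TRUE)
  v <- voxel_volume(arr, 20)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f, "u16")
  expect_identical(read_volume(f)$data, arr)
})

test_that("integer depths round half to even and enforce their range", {
  v <- voxel_volume(array(c(0.5, 1.5, 2.5, 3.5, 250, 254.5, 100, 0),
                          c(2, 2, 2)), 5)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f, "u8")
  expect_identical(as.vector(read_volume(f)$data),
                   c(0, 2, 2, 4, 250, 254, 100, 0))
  expect_error(write_volume(const_volume(c(2, 2, 2), 70000), f, "u16"),
               "range error")
  expect_error(write_volume(const_volume(c(2, 2, 2), -1), f, "u8"),
               "range error")
  # all-zero u8 identity round trip
  z <- const_volume(c(2, 2, 2), 0)
  write_volume(z, f, "u8")
  expect_identical(read_volume(f)$data, z$data)
})

test_that("malformed stacks are rejected", {
  dir <- withr::local_tempdir()
  write_slice_tiff(matrix(1, 2, 2), file.path(dir, "a.tif"))
  write_slice_tiff(matrix(1, 3, 3), file.path(dir, "b.tif"))
  expect_error(read_volume(dir, voxel_size_um = 5), "mixed shapes")

  empty <- withr::local_tempdir()
  expect_error(read_volume(empty, voxel_size_um = 5), "empty input")

  rgb <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(2, 2, 3)), rgb, bits.per.sample = 8L,
                  compression = "none")
  expect_error(read_volume(rgb, voxel_size_um = 5), "multichannel")
})

test_that("volumes with NaN/Inf or bad geometry are refused at construction", {
  expect_error(voxel_volume(array(c(1, NaN), c(2, 1, 1)), 5), "non-finite")
  expect_error(voxel_volume(array(1, c(2, 2)), 5), "3D")
  expect_error(voxel_volume(array(1, c(2, 2, 2)), 0), "positive")
})

test_that("codec output interoperates with the tiff package, both directions", {
  set.seed(4)
  arr <- array(as.numeric(sample(0:65535, 3 * 4 * 5, TRUE)), c(3, 4, 5))
  v <- voxel_volume(arr, 20)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f, "u16")
  pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
  expect_length(pages, 3L)
  for (i in 1:3) expect_true(all(pages[[i]] == arr[i, , ]))
  # tiff::writeTIFF (uncompressed and LZW) both readable
  f2 <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(c(0, 7, 255, 100) / 255, 2, 2)
  for (comp in c("none", "LZW")) {
    tiff::writeTIFF(m, f2, bits.per.sample = 8L, compression = comp)
    r <- read_volume(f2, voxel_size_um = 5)
    expect_equal(as.vector(r$data[1, , ]), c(0, 7, 255, 100))
  }
})

test_that("masks read with validated label coverage and integer typing", {
  dir <- withr::local_tempfile(fileext = ".tif")
  arr <- array(c(0L, 1L, 2L, 0L, 1L, 2L, 2L, 0L), c(2, 2, 2))
  mk <- label_mask(arr, c("1" = "ROIc", "2" = "ROIh"))
  write_mask(mk, dir)
  m <- read_mask(dir, c("1" = "ROIc", "2" = "ROIh"))
  expect_identical(m$data, arr)
  # voxel counts per label by brute-force scan
  expect_identical(sum(m$data == 1L), 2L)
  expect_identical(sum(m$data == 2L), 3L)
  expect_error(read_mask(dir, c("1" = "ROIc")), "unknown label")
  # all-zero mask with empty labels is valid
  zf <- withr::local_tempfile(fileext = ".tif")
  write_mask(label_mask(array(0L, c(2, 2, 2))), zf)
  expect_identical(sum(read_mask(zf)$data), 0L)
  # non-integer pixels are not a mask
  ff <- withr::local_tempfile(fileext = ".tif")
  write_volume(const_volume(c(2, 2, 2), 0.5), ff, "f32")
  expect_error(read_mask(ff, c("1" = "x")), "non-integer")
})

test_that("sidecar metadata round trips voxel size and units", {
  v <- voxel_volume(array(1:8 / 4, c(2, 2, 2)), 12.5)
  v$units <- "HU"
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f, "f32")
  r <- read_volume(f)
  expect_equal(r$voxel_size_um, 12.5)
  expect_identical(r$units, "HU")
})
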