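test_that("NIfTI volumes round-trip voxels, spacing and origin", {
  ph <- make_tube_phantom(0.3, 2, spacing_mm = 0.05)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, path)
  v2 <- read_volume(path)
  expect_identical(dim(v2$voxels), dim(ph$volume$voxels))
  expect_equal(v2$voxels, ph$volume$voxels, ignore_attr = TRUE)
  expect_equal(v2$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)
  expect_equal(v2$origin_mm, ph$volume$origin_mm, tolerance = 1e-6)
})

test_that("masks round-trip as uint8 NIfTI", {
  ph <- make_tube_phantom(0.3, 2, spacing_mm = 0.05)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(ph$mask, path)
  m2 <- read_volume(path)
  expect_identical(m2$voxels > 0, ph$mask$voxels)
})

test_that("MetaImage volumes round-trip in both .mha and .mhd forms", {
  ph <- make_tube_phantom(0.3, 2, spacing_mm = 0.05)
  for (ext in c(".mha", ".mhd")) {
    path <- file.path(withr::local_tempdir(), paste0("vol", ext))
    write_volume(ph$volume, path)
    v2 <- read_volume(path)
    expect_equal(v2$voxels, ph$volume$voxels, ignore_attr = TRUE)
    expect_equal(v2$spacing_mm, ph$volume$spacing_mm)
    expect_equal(v2$origin_mm, ph$volume$origin_mm)
  }
})

test_that("DICOM series are ordered by spatial position, not filename", {
  ph <- make_tube_phantom(0.3, 1.5, spacing_mm = 0.05)
  sorted_dir <- withr::local_tempdir()
  write_dicom_series(ph$volume, sorted_dir)
  ref <- read_dicom_series(sorted_dir)
  expect_equal(ref$voxels, ph$volume$voxels, ignore_attr = TRUE)
  expect_equal(ref$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)

  # shuffled file names must give the identical volume
  nz <- dim(ph$volume$voxels)[3]
  set.seed(42)
  shuffled <- sprintf("scrambled_%04d.dcm", sample(nz))
  shuf_dir <- withr::local_tempdir()
  write_dicom_series(ph$volume, shuf_dir, file_names = shuffled)
  v2 <- read_dicom_series(shuf_dir)
  expect_identical(v2$voxels, ref$voxels)
})

test_that("a directory mixing DICOM series is rejected", {
  ph <- make_tube_phantom(0.3, 0.5, spacing_mm = 0.05)
  dir <- withr::local_tempdir()
  write_dicom_series(ph$volume, dir, series_uid = "1.2.3.1")
  nz <- dim(ph$volume$voxels)[3]
  write_dicom_series(ph$volume, file.path(dir),
                     series_uid = "1.2.3.2",
                     file_names = sprintf("other_%04d.dcm", seq_len(nz)))
  expect_error(read_dicom_series(dir), "mixes DICOM series")
})

test_that("unknown formats and missing files raise format errors", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "no such file")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a volume", bad)
  expect_error(read_volume(bad), "unrecognised")
})

test_that("intensity inversion is an involution that swaps extremes", {
  ph <- make_tube_phantom(0.3, 1, spacing_mm = 0.05)
  inv <- invert_intensity(ph$volume)
  expect_identical(invert_intensity(inv)$voxels, ph$volume$voxels)
  # lumen was the minimum; after inversion it holds the maximum
  expect_equal(max(inv$voxels), -min(ph$volume$voxels))
  expect_equal(min(inv$voxels), -max(ph$volume$voxels))
  expect_equal(inv$spacing_mm, ph$volume$spacing_mm)
})

test_that("world/index conversion follows the voxel-centre convention", {
  v <- volume3d(array(0, c(4, 4, 4)), spacing_mm = 0.5, origin_mm = c(1, 2, 3))
  expect_equal(index_to_world(v, c(1, 1, 1))[1, ], c(1, 2, 3))
  expect_equal(world_to_index(v, c(1.5, 2.5, 3.5))[1, ], c(2, 2, 2))
  rt <- index_to_world(v, world_to_index(v, c(1.23, 2.34, 3.45)))
  expect_equal(rt[1, ], c(1.23, 2.34, 3.45))
})
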