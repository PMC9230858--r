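test_that("windowing maps HU to display gray with inclusive clamps and half-up rounding", {
  v <- ct_volume(array(c(-2000L, -160L, -159L, 40L, 239L, 240L, 1000L, 0L),
                       c(2, 2, 2)), c(3, 0.798, 0.798))
  w <- apply_window(v, 400, 40)
  expect_equal(as.vector(w$voxels), c(0L, 0L, 1L, 128L, 254L, 255L, 255L, 102L))
  # HU = 40 sits at the window center: 255 * 200/400 = 127.5 rounds half-up
  expect_identical(w$voxels[2, 2, 1], 128L)
  expect_error(apply_window(v, 0, 40), "width")
})

test_that("windowing is monotone non-decreasing in HU", {
  hu <- sort(as.integer(round(runif(200, -1200, 1200))))
  v <- ct_volume(array(hu, c(200, 1, 1)), c(1, 1, 1))
  g <- as.vector(apply_window(v)$voxels)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 255))
})

test_that("volumes round-trip through NIfTI voxel- and spacing-identical", {
  ph <- small_phantom()
  td <- withr::local_tempdir()
  f <- file.path(td, "vol.nii.gz")
  write_ct_volume(ph$volume, f)
  back <- read_ct_volume(f)
  expect_identical(back$voxels, ph$volume$voxels)
  expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-5)

  lab <- small_iip_run()$seq$labels
  fl <- file.path(td, "lab.nii.gz")
  write_label_volume(lab, fl)
  back2 <- read_label_volume(fl)
  expect_identical(back2$voxels, lab$voxels)

  bin <- binary_volume(array(c(0L, 255L), c(4, 4, 2)), c(1, 1, 1))
  fb <- file.path(td, "bin.nii.gz")
  write_binary_volume(bin, fb)
  expect_identical(read_binary_volume(fb)$voxels, bin$voxels)
})

test_that("reading a directory or missing file is a format error", {
  td <- withr::local_tempdir()
  expect_error(read_ct_volume(td), "format error")
  expect_error(read_ct_volume(file.path(td, "nope.nii")), "format error")
  bad <- file.path(td, "bad.nii")
  writeLines("not a nifti", bad)
  expect_error(read_ct_volume(bad), "format error")
})

test_that("in-plane resampling changes dimensions as round(n * s / target) and leaves z alone", {
  v <- ct_volume(array(7L, c(100, 80, 2)), c(3, 0.617, 0.617))
  r <- resample_inplane(v, 0.798)
  expect_equal(dim(r$voxels), c(round(100 * 0.617 / 0.798), round(80 * 0.617 / 0.798), 2))
  expect_true(all(r$voxels == 7L))  # bilinear interpolation of a constant
  expect_equal(unname(r$spacing["z"]), 3)

  v2 <- ct_volume(array(5L, c(10, 10, 1)), c(3, 0.798, 0.798))
  expect_identical(resample_inplane(v2, 0.798), v2)  # no-op at target spacing
  expect_error(resample_inplane(v, -1), "parameter error")
})

test_that("mask resampling is nearest-neighbour and creates no new values", {
  set.seed(9)
  b <- random_binary_volume(c(40, 40, 3), 0.3)
  b$spacing <- c(z = 3, y = 0.617, x = 0.617)
  r <- resample_inplane(b, 0.798)
  expect_true(all(r$voxels %in% c(0L, 255L)))
  lab <- label_volume(array(rep(c(0L, 2L, 1L, 0L), 100), c(20, 20, 1)), c(3, 1.1, 1.1))
  rl <- resample_inplane(lab, 0.798)
  expect_true(all(unique(as.vector(rl$voxels)) %in% unique(as.vector(lab$voxels))))
})

test_that("overlays are one PNG per slice and empty labels draw nothing", {
  run <- small_iip_run()
  td <- withr::local_tempdir()
  paths <- write_overlays(run$win, run$seq$labels, file.path(td, "ov"), run$seq$report)
  expect_length(paths, dim(run$win$voxels)[3])
  expect_true(all(file.exists(paths)))

  empty <- label_volume(array(0L, dim(run$win$voxels)), run$win$spacing)
  p2 <- write_overlays(run$win, empty, file.path(td, "ov0"))
  img <- png::readPNG(p2[1])
  expect_identical(dim(img)[3], 3L)
  # pure grayscale: all channels equal when nothing is annotated
  expect_equal(img[, , 1], img[, , 2])
})

test_that("reports serialize to JSON and read back", {
  run <- small_iip_run()
  td <- withr::local_tempdir()
  f <- file.path(td, "report.json")
  write_report(run$seq$report, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(x$.class, "rib_label_report")
  expect_identical(nrow(x$pairs), run$seq$report$n_pairs)
})
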