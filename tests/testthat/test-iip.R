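test_that("binarization keeps strictly-above-threshold pixels only", {
  mk <- function(val) windowed_volume(array(val, c(4, 4, 1)), c(1, 1, 1), 400, 40)
  expect_true(all(binarize(mk(139L), 140L)$voxels == 0L))
  expect_true(all(binarize(mk(140L), 140L)$voxels == 0L))
  expect_true(all(binarize(mk(141L), 140L)$voxels == 255L))
  expect_error(binarize(mk(10L), 300L), "parameter error")
})

test_that("sad is the exact absolute-difference sum and zero only for identical patches", {
  img <- matrix(c(255L, 0L, 255L, 0L, 255L, 0L, 0L, 0L, 100L), 3, 3)
  expect_identical(sad(img, img), 0L)
  tpl <- matrix(c(0L, 0L, 255L, 0L), 2, 2, byrow = TRUE)
  patch <- matrix(c(255L, 0L, 255L, 0L), 2, 2, byrow = TRUE)
  expect_equal(sad(patch, tpl), 255)
  expect_error(sad(img, matrix(0L, 5, 5)), "overhangs")

  set.seed(5)
  for (i in 1:20) {
    a <- matrix(sample(0:255, 64, TRUE), 8, 8)
    b <- matrix(sample(0:255, 64, TRUE), 8, 8)
    expect_equal(sad(a, b), sum(abs(a - b)))
    expect_gte(sad(a, b), 0)
    if (!identical(a, b)) expect_gt(sad(a, b), 0)
  }
})

test_that("template matching equals brute-force search on both binary and grayscale fixtures", {
  set.seed(11)
  for (rep in 1:10) {
    binary <- rep <= 5
    img <- if (binary) matrix(sample(c(0L, 255L), 32 * 32, TRUE), 32, 32)
    else matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    tpl <- img[5:12, 9:16]  # planted copy guarantees a zero-score optimum
    ts <- template_set(list(tpl))
    det <- match_vertebra(img, ts)
    om <- sad_oracle(img, tpl)
    expect_identical(det$score, as.integer(min(om)))
    hit <- which(om == min(om), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    expect_equal(unname(det$origin), unname(hit))
  }
})

test_that("an exact template copy is found at the planted position with score zero", {
  slice <- matrix(0L, 400, 400)
  tpl <- matrix(0L, 40, 30)
  tpl[10:30, 8:22] <- 255L
  slice[300:339, 250:279] <- tpl
  decoy <- matrix(0L, 10, 10)
  decoy[3, 3] <- 255L; decoy[6, 6] <- 255L  # isolated diagonal pair: never matches exactly
  ts <- template_set(list(decoy, tpl))      # id 2 is the right one
  det <- match_vertebra(slice, ts)
  expect_identical(det$score, 0L)
  expect_equal(unname(det$origin), c(300, 250))
  expect_identical(det$template_id, "tpl02")
  # degenerate tie: all-zero slice with all-zero template matches at (1, 1)
  det0 <- match_vertebra(matrix(0L, 20, 20), template_set(list(matrix(0L, 3, 3))))
  expect_identical(det0$score, 0L)
  expect_equal(unname(det0$origin), c(1, 1))
  expect_error(match_vertebra(matrix(0L, 4, 4), template_set(list(matrix(0L, 9, 9)))),
               "no template fits")
})

test_that("vertebra/sternum erasure removes both boxes and clips at borders", {
  sl <- matrix(0L, 100, 100)
  sl[70:80, 45:55] <- 255L            # "vertebra"
  sl[20:26, 46:54] <- 255L            # "sternum" mirror
  det <- list(box = c(70L, 80L, 45L, 55L))
  er <- erase_vertebra_sternum(sl, det, body_centroid_y = 50)
  expect_true(all(er$slice[70:80, 45:55] == 0L))
  expect_true(all(er$slice[20:26, 46:54] == 0L))
  expect_identical(sum(er$slice), 0L)

  # box at the slice border: clipped, no error
  det2 <- list(box = c(-5L, 10L, 95L, 120L))
  er2 <- erase_vertebra_sternum(sl, det2, body_centroid_y = 50)
  expect_true(all(er2$vertebra_box >= 1 & er2$vertebra_box <= 100))
})

test_that("erasure removes vertebra and sternum from the phantom without touching ribs", {
  run <- small_iip_run()
  ph <- run$ph
  bin <- binarize(run$win)
  vol <- bin$voxels
  for (z in seq_len(dim(vol)[3])) {
    det <- run$mask$detections[[z]]
    er <- erase_vertebra_sternum(vol[, , z], det,
                                 body_centroid_y = (dim(vol)[1]) / 2)
    vol[, , z] <- er$slice
  }
  vcode <- which(ph$truth$structure_names == "vertebra")
  scode <- which(ph$truth$structure_names == "sternum")
  expect_identical(sum(vol[ph$truth$structures == vcode] == 255L), 0L)
  expect_identical(sum(vol[ph$truth$structures == scode] == 255L), 0L)
  expect_identical(sum(vol[ph$truth$rib_labels > 0L] != 255L), 0L)
})

test_that("bed and small-object removal never adds foreground", {
  # isolated pixel below the size floor disappears
  a <- array(0L, c(30, 30, 1)); a[10, 10, 1] <- 255L
  v <- binary_volume(a, c(1, 1, 1))
  expect_identical(sum(remove_bed_and_noise(v, min_size = 5L, opening_radius = 0L)$voxels), 0L)
  # all-zero stays all-zero
  z <- binary_volume(array(0L, c(20, 20, 2)), c(1, 1, 1))
  expect_identical(sum(remove_bed_and_noise(z)$voxels), 0L)
  # phantom: bed voxels removed, rib voxels retained
  run <- small_iip_run()
  ph <- run$ph
  cleaned <- remove_bed_and_noise(binarize(run$win))
  bcode <- which(ph$truth$structure_names == "bed")
  expect_identical(sum(cleaned$voxels[ph$truth$structures == bcode] == 255L), 0L)
  expect_true(all(cleaned$voxels[ph$truth$rib_labels > 0L] == 255L))
  expect_true(all(cleaned$voxels <= binarize(run$win)$voxels))
})

test_that("objects without vertebral contact at first appearance are excluded", {
  run <- small_iip_run()
  ph <- run$ph
  dcode <- which(ph$truth$structure_names == "clavicle")
  # distractor voxels absent from the final mask, rib voxels all present
  expect_identical(sum(run$mask$volume$voxels[ph$truth$structures == dcode] == 255L), 0L)
  expect_true(all(run$mask$volume$voxels[ph$truth$rib_labels > 0L] == 255L))
  expect_gte(length(run$mask$removed$filtered), 1L)

  # a mask containing only vertebra-contacting ribs passes through unchanged
  tm <- truth_mask(ph)
  filtered <- filter_nonrib_objects(tm$volume, run$mask$detections)
  expect_identical(filtered$volume$voxels, tm$volume$voxels)

  # object first appearing on the last slice, touching: kept
  d <- dim(tm$volume$voxels)
  a <- array(0L, d)
  vb <- run$mask$detections[[d[3]]]$box
  a[vb[1] - 1L, vb[3]:(vb[3] + 9L), d[3]] <- 255L
  kept <- filter_nonrib_objects(binary_volume(a, tm$volume$spacing),
                                run$mask$detections)
  expect_identical(sum(kept$volume$voxels == 255L), 10L)

  # no detection available for a first-appearance slice -> processing error
  dets <- vector("list", d[3])
  dets[[5]] <- run$mask$detections[[5]]
  b <- array(0L, d); b[50, 50, 2] <- 255L
  expect_error(filter_nonrib_objects(binary_volume(b, tm$volume$spacing), dets),
               "slice 2")
})

test_that("the IIP pipeline recovers exactly the ground-truth rib voxels", {
  run <- small_iip_run()
  expect_identical(run$mask$volume$voxels == 255L, run$ph$truth$rib_labels > 0L)
  # no stage adds foreground
  sf <- run$mask$removed$stage_foreground
  expect_true(all(diff(sf) <= 0))
})

test_that("cleanup stages are no-ops on a phantom without bed or distractors", {
  ph <- generate_phantom(small_spec(include_bed = FALSE, distractors = character(0)))
  ts <- generate_template_set(ph)
  win <- apply_window(ph$volume)
  full <- build_iip_mask(win, ts)
  ablated <- build_iip_mask(win, ts, iip_config(opening_radius = 0L, min_size = 0L,
                                                bed_band = 0L))
  expect_identical(full$volume$voxels, ablated$volume$voxels)
  expect_identical(full$volume$voxels == 255L, ph$truth$rib_labels > 0L)
})

test_that("an all-air volume yields an empty mask with error or warning per config", {
  air <- ct_volume(array(-1000L, c(160, 160, 4)), c(3, 0.798, 0.798))
  ts <- small_iip_run()$ts
  win <- apply_window(air)
  expect_error(build_iip_mask(win, ts), "processing error")
  expect_warning(m <- build_iip_mask(win, ts, iip_config(missing_vertebra = "warn")),
                 "no reliable vertebra")
  expect_identical(sum(m$volume$voxels), 0L)
})

test_that("config files round-trip through YAML with defaults for missing keys", {
  td <- withr::local_tempdir()
  f <- file.path(td, "cfg.yaml")
  writeLines(c("threshold: 120", "contact_margin: 5"), f)
  cfg <- load_iip_config(f)
  expect_identical(cfg$threshold, 120L)
  expect_identical(cfg$contact_margin, 5L)
  expect_identical(cfg$min_size, iip_config()$min_size)
  writeLines("nonsense: 1", f)
  expect_error(load_iip_config(f), "unknown config keys")
})
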