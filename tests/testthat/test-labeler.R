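test_that("cluster discovery finds 24 ribs on the phantom mask and drops specks", {
  run <- small_iip_run()
  lc <- label_clusters(run$mask)
  expect_length(lc$clusters, 24L)
  expect_identical(lc$labels$label_count, 24L)
  # discovery order: first slice ascending
  fs <- vapply(lc$clusters, `[[`, integer(1), "first_slice")
  expect_true(all(diff(fs) >= 0))

  # empty mask
  empty <- binary_volume(array(0L, c(8, 8, 2)), c(1, 1, 1))
  lce <- label_clusters(empty)
  expect_length(lce$clusters, 0L)
  expect_identical(sum(lce$labels$voxels), 0L)

  # 2-voxel speck below min_cluster_size vanishes
  a <- run$mask$volume$voxels
  a[1, 1, 1] <- 255L; a[2, 1, 1] <- 255L
  withspeck <- binary_volume(a, run$mask$volume$spacing)
  expect_length(label_clusters(withspeck, min_cluster_size = 10L)$clusters, 24L)
  expect_length(label_clusters(withspeck, min_cluster_size = 0L)$clusters, 25L)
})

test_that("side assignment puts patient-left at image right with ties going right", {
  cl <- structure(list(centroid = c(z = 1, y = 50, x = 400)), class = "cluster3d")
  expect_identical(assign_side(cl, 256), "left")
  cl$centroid["x"] <- 100
  expect_identical(assign_side(cl, 256), "right")
  cl$centroid["x"] <- 256
  expect_identical(assign_side(cl, 256), "right")
  # symmetric phantom: exactly half the clusters on each side
  run <- small_iip_run()
  sides <- vapply(run$seq$clusters, `[[`, character(1), "side")
  expect_identical(sum(sides == "left"), 12L)
  expect_identical(sum(sides == "right"), 12L)
})

test_that("pairing joins sides ordinal-by-ordinal and reports asymmetry", {
  run <- small_iip_run()
  rep12 <- run$seq$report
  expect_identical(rep12$n_pairs, 12L)
  expect_identical(rep12$pairs$ordinal, 1:12)
  expect_identical(nrow(rep12$unpaired), 0L)
  # bilateral symmetry: paired clusters first appear on the same slice
  fs <- vapply(run$seq$clusters, `[[`, integer(1), "first_slice")
  expect_true(all(fs[rep12$pairs$left_cluster_id] == fs[rep12$pairs$right_cluster_id]))

  # missing left 12th: 11 pairs plus one unpaired right cluster
  miss <- generate_phantom(small_spec(missing_rib = list(side = "left", ordinal = 12L)))
  sq <- label_sequence(truth_mask(miss))
  expect_identical(sq$report$n_pairs, 11L)
  expect_identical(nrow(sq$report$unpaired), 1L)
  expect_identical(sq$report$unpaired$side, "right")
  expect_match(sq$report$warnings, "asymmetry", all = FALSE)

  # single cluster on one side only: zero pairs, one unpaired
  a <- array(0L, c(20, 20, 3)); a[5:10, 15:18, 1:2] <- 255L
  one <- label_sequence(binary_volume(a, c(1, 1, 1)))
  expect_identical(one$report$n_pairs, 0L)
  expect_identical(nrow(one$report$unpaired), 1L)
})

test_that("re-coded labels are exactly {1..2P} with left ribs 1..P", {
  run <- small_iip_run()
  labs <- run$seq$labels
  expect_identical(sort(unique(labs$voxels[labs$voxels > 0L])), 1:24)
  ph <- run$ph
  for (i in c(1L, 6L, 12L)) {
    sel_left <- ph$truth$rib_labels == i
    expect_true(all(labs$voxels[sel_left] == i))
    sel_right <- ph$truth$rib_labels == 12L + i
    expect_true(all(labs$voxels[sel_right] == 12L + i))
  }
  expect_true(all(labs$voxels[ph$truth$rib_labels == 0L] == 0L))
  expect_identical(nrow(run$seq$report$annotations), 12L)
  expect_identical(run$seq$report$annotations$ordinal, 1:12)
})

test_that("labeling a mask equals labeling the ground-truth rib mask", {
  run <- small_iip_run()
  from_truth <- label_sequence(truth_mask(run$ph))
  expect_identical(run$seq$labels$voxels, from_truth$labels$voxels)
  expect_identical(run$seq$report$pairs, from_truth$report$pairs)
})

test_that("discovery ordinals survive appending empty slices below and padding columns right", {
  run <- small_iip_run()
  v <- run$mask$volume$voxels
  d <- dim(v)
  padded <- array(0L, d + c(0L, 30L, 4L))
  padded[, seq_len(d[2]), seq_len(d[3])] <- v
  sq <- label_sequence(binary_volume(padded, run$mask$volume$spacing))
  base <- label_sequence(binary_volume(v, run$mask$volume$spacing))
  expect_identical(sq$report$n_pairs, base$report$n_pairs)
  expect_identical(sq$labels$voxels[, seq_len(d[2]), seq_len(d[3])], base$labels$voxels)
})

test_that("the pipeline is bit-identical across repeated runs", {
  ph <- small_phantom()
  ts <- generate_template_set(ph)
  win <- apply_window(ph$volume)
  a <- label_sequence(build_iip_mask(win, ts))
  b <- label_sequence(build_iip_mask(win, ts))
  expect_identical(a$labels$voxels, b$labels$voxels)
  expect_identical(a$report$pairs, b$report$pairs)
  expect_identical(a$report$annotations, b$report$annotations)
})

test_that("more than 12 pairs flags the case", {
  run <- small_iip_run()
  v <- run$mask$volume$voxels
  # plant a fake 13th pair below the last rib
  d <- dim(v)
  v[30:40, 120:130, d[3]] <- 255L
  v[30:40, 30:40, d[3]] <- 255L
  sq <- label_sequence(binary_volume(v, run$mask$volume$spacing))
  expect_identical(sq$report$n_pairs, 12L)
  expect_true("too_many_pairs" %in% sq$report$flags)
  expect_identical(nrow(sq$report$unpaired), 2L)
})
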