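test_that("confusion counts equal a brute-force voxel tally", {
  mk <- function(fg, d) binary_volume(array(ifelse(fg, 255L, 0L), d), c(1, 1, 1))
  d <- c(10, 10, 10)
  truth <- array(FALSE, d); truth[1:10, 1:10, 1] <- TRUE  # 100 of 1000
  cc <- confusion_counts(mk(truth, d), mk(truth, d))
  expect_identical(cc$TP, 100L); expect_identical(cc$TN, 900L)
  expect_identical(cc$FP + cc$FN, 0L)
  cc2 <- confusion_counts(mk(array(FALSE, d), d), mk(truth, d))
  expect_identical(cc2$FN, 100L); expect_identical(cc2$TP, 0L)

  set.seed(31)
  for (i in 1:10) {
    p <- array(runif(256) < 0.5, c(8, 8, 4))
    t <- array(runif(256) < 0.5, c(8, 8, 4))
    cc3 <- confusion_counts(mk(p, dim(p)), mk(t, dim(t)))
    tally <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (j in seq_along(p)) {
      k <- if (p[j] && t[j]) "TP" else if (p[j]) "FP" else if (t[j]) "FN" else "TN"
      tally[k] <- tally[k] + 1L
    }
    expect_identical(c(TP = cc3$TP, FP = cc3$FP, TN = cc3$TN, FN = cc3$FN), tally)
  }
  expect_error(confusion_counts(mk(truth, d), mk(array(FALSE, c(5, 5, 5)), c(5, 5, 5))),
               "parameter error")
})

test_that("metric formulas reproduce hand-computed values and degenerate cases", {
  m <- compute_metrics(list(TP = 2, FP = 1, FN = 1, TN = 6))
  expect_equal(m$dsc, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$accuracy, 0.8)

  perfect <- compute_metrics(list(TP = 50, FP = 0, FN = 0, TN = 50))
  expect_true(all(unlist(perfect) == 1))

  degen <- compute_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(degen$dsc, 0)
  expect_true(is.na(degen$precision))
})

test_that("dsc is the harmonic mean of precision and recall and is symmetric", {
  set.seed(77)
  for (i in 1:20) {
    p <- random_binary_volume(c(8, 8, 3), runif(1, 0.2, 0.8))
    t <- random_binary_volume(c(8, 8, 3), runif(1, 0.2, 0.8))
    m <- compute_metrics(confusion_counts(p, t))
    if (!is.na(m$precision) && !is.na(m$recall) && (m$precision + m$recall) > 0)
      expect_equal(m$dsc, 2 * m$precision * m$recall / (m$precision + m$recall))
    m2 <- compute_metrics(confusion_counts(t, p))
    expect_equal(m$dsc, m2$dsc)                 # symmetry of dice
    expect_equal(m$precision, m2$recall)        # precision(p,t) = recall(t,p)
    # invariance to a consistent voxel permutation
    perm <- sample(prod(dim(p$voxels)))
    pp <- binary_volume(array(p$voxels[perm], dim(p$voxels)), p$spacing)
    tp <- binary_volume(array(t$voxels[perm], dim(t$voxels)), t$spacing)
    expect_equal(unlist(compute_metrics(confusion_counts(pp, tp))), unlist(m))
  }
})

test_that("identity masks score all ones", {
  mask <- small_iip_run()$mask$volume
  m <- compute_metrics(confusion_counts(mask, mask))
  expect_true(all(unlist(m) == 1))
})

test_that("k-fold splits are patient-level partitions, deterministic in the seed", {
  ids <- sprintf("case%02d", 1:50)
  folds <- kfold_split(ids, 5, seed = 42L)
  expect_length(folds, 5L)
  expect_true(all(vapply(folds, function(f) length(f$test), integer(1)) == 10L))
  expect_true(all(vapply(folds, function(f) length(f$train), integer(1)) == 40L))
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))), sort(ids))
  for (f in folds) expect_length(intersect(f$train, f$test), 0L)
  expect_identical(kfold_split(ids, 5, seed = 42L), folds)
  expect_false(identical(kfold_split(ids, 5, seed = 43L), folds))
  # leave-one-out
  loo <- kfold_split(letters[1:5], 5, seed = 1L)
  expect_true(all(vapply(loo, function(f) length(f$test), integer(1)) == 1L))
  expect_error(kfold_split(letters[1:3], 5), "parameter error")
})
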