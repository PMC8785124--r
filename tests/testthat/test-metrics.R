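test_that("metric quadruple matches the TP=2 FP=1 FN=1 fixture", {
  pred <- array(c(1L, 1L, 1L, 0L), dim = c(1, 2, 2))
  truth <- array(c(1L, 1L, 0L, 1L), dim = c(1, 2, 2))
  r <- evaluate_segmentation(pred, truth, 2)
  fg <- r$summary[r$summary$class == 1, ]
  expect_equal(fg$dsc, 2 / 3, tolerance = 1e-9)
  expect_equal(fg$iou, 1 / 2, tolerance = 1e-9)
  expect_equal(fg$recall, 2 / 3, tolerance = 1e-9)
  expect_equal(fg$precision, 2 / 3, tolerance = 1e-9)
})

test_that("identity and disjoint predictions hit the metric extremes", {
  set.seed(2)
  lab <- array(sample(0:1, 32, replace = TRUE), dim = c(2, 4, 4))
  r <- evaluate_segmentation(lab, lab, 2)
  expect_true(all(abs(as.matrix(r$summary[, c("dsc", "iou", "recall", "precision")]) - 1) < 1e-12))

  pred <- array(c(1L, 0L), dim = c(1, 2))
  truth <- array(c(0L, 1L), dim = c(1, 2))
  d <- evaluate_segmentation(pred, truth, 2)$summary
  expect_true(all(d[c("dsc", "iou", "recall", "precision")] == 0))
})

test_that("IoU and DSC obey their algebraic identity on random masks", {
  set.seed(33)
  for (i in 1:50) {
    pred <- array(sample(0:1, 64, replace = TRUE), dim = c(1, 8, 8))
    truth <- array(sample(0:1, 64, replace = TRUE), dim = c(1, 8, 8))
    r <- evaluate_segmentation(pred, truth, 2)$per_image
    ok <- !is.na(r$dsc)
    expect_equal(r$iou[ok], r$dsc[ok] / (2 - r$dsc[ok]), tolerance = 1e-9)
    expect_true(all(r$iou[ok] <= r$dsc[ok] + 1e-12))
    eq <- abs(r$iou[ok] - r$dsc[ok]) < 1e-12
    expect_true(all(r$dsc[ok][eq] %in% c(0, 1)))
  }
})

test_that("metrics are invariant under a shared spatial permutation", {
  set.seed(12)
  pred <- array(sample(0:2, 36, replace = TRUE), dim = c(1, 6, 6))
  truth <- array(sample(0:2, 36, replace = TRUE), dim = c(1, 6, 6))
  perm <- sample(36)
  r1 <- evaluate_segmentation(pred, truth, 3)$summary
  r2 <- evaluate_segmentation(array(pred[perm], dim = dim(pred)),
                              array(truth[perm], dim = dim(truth)),
                              3)$summary
  expect_equal(r1, r2)
})

test_that("soft Dice agrees with the hard metric when p is one-hot", {
  set.seed(21)
  pred <- array(sample(0:1, 32, replace = TRUE), dim = c(2, 4, 4))
  truth <- array(sample(0:1, 32, replace = TRUE), dim = c(2, 4, 4))
  hard <- evaluate_segmentation(pred, truth, 2)$per_image
  soft <- soft_dice(one_hot_encode(pred, 2), one_hot_encode(truth, 2),
                    epsilon = 1e-12)
  ok <- !is.na(hard$dsc)
  expect_equal(soft$score[ok], hard$dsc[ok], tolerance = 1e-9)
})

test_that("zero-denominator classes are flagged, warned about and excluded", {
  pred <- array(0L, dim = c(1, 2, 2))   # class 1 never predicted or present
  truth <- array(0L, dim = c(1, 2, 2))
  expect_warning(r <- evaluate_segmentation(pred, truth, 2), "zero denominator")
  fg <- r$per_image[r$per_image$class == 1, ]
  expect_true(is.na(fg$recall) && is.na(fg$precision) && is.na(fg$dsc))
  expect_equal(r$summary$n_images[r$summary$class == 1], 0)
})

test_that("micro averaging pools counts before computing metrics", {
  pred <- array(c(1L, 1L, 0L, 0L,  1L, 0L, 0L, 0L), dim = c(2, 2, 2))
  truth <- array(c(1L, 0L, 0L, 0L,  1L, 1L, 0L, 0L), dim = c(2, 2, 2))
  mi <- evaluate_segmentation(pred, truth, 2, average = "micro")$summary
  # pooled fg: tp = 2, fp = 1, fn = 1
  expect_equal(mi$dsc[mi$class == 1], 2 * 2 / (2 * 2 + 1 + 1), tolerance = 1e-12)
})

test_that("metric reports serialise to CSV and JSON with stable columns", {
  set.seed(3)
  pred <- array(sample(0:1, 32, replace = TRUE), dim = c(2, 4, 4))
  truth <- array(sample(0:1, 32, replace = TRUE), dim = c(2, 4, 4))
  r <- evaluate_segmentation(pred, truth, 2)
  fcsv <- tempfile(fileext = ".csv"); fjson <- tempfile(fileext = ".json")
  write_metric_report(r, fcsv)
  write_metric_report(r, fjson)
  back <- utils::read.csv(fcsv)
  expect_true(all(c("image", "class", "dsc", "iou", "recall", "precision")
                  %in% names(back)))
  expect_equal(back$dsc, r$per_image$dsc, tolerance = 1e-9)
  j <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_equal(j$summary$dsc, r$summary$dsc, tolerance = 1e-9)
  expect_error(write_metric_report(r, tempfile(fileext = ".txt")), "csv")
})

test_that("per-image metrics equal an independent per-mask oracle", {
  set.seed(44)
  for (i in 1:10) {
    pred <- array(sample(0:2, 25, replace = TRUE), dim = c(1, 5, 5))
    truth <- array(sample(0:2, 25, replace = TRUE), dim = c(1, 5, 5))
    r <- evaluate_segmentation(pred, truth, 3)$per_image
    o <- oracle_hard_metrics(as.vector(pred), as.vector(truth), 3)
    expect_equal(r$dsc, o$dsc, tolerance = 1e-12)
    expect_equal(r$iou, o$iou, tolerance = 1e-12)
    expect_equal(r$recall, o$recall, tolerance = 1e-12)
    expect_equal(r$precision, o$precision, tolerance = 1e-12)
  }
})
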