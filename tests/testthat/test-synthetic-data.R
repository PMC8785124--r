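test_that("generation is bit-identical under a fixed seed", {
  a <- generate_task(3, shape = c(32, 32), target_fraction = 0.05, seed = 42)
  b <- generate_task(3, shape = c(32, 32), target_fraction = 0.05, seed = 42)
  expect_identical(a$images, b$images)
  expect_identical(a$masks, b$masks)
  c <- generate_task(3, shape = c(32, 32), target_fraction = 0.05, seed = 43)
  expect_false(identical(a$masks, c$masks))
})

test_that("an extreme 3D imbalance target is realized within tolerance", {
  task <- generate_task(2, shape = c(64, 64, 64), target_fraction = 0.002,
                        seed = 7)
  expect_gte(task$realized_fraction, 0.0015)
  expect_lte(task$realized_fraction, 0.0025)
  expect_true(all(task$masks %in% 0:1))
})

test_that("mean realized prevalence tracks the target across seeds", {
  for (target in c(0.002, 0.01, 0.05, 0.10)) {
    fr <- sapply(1:10, function(s) {
      generate_task(2, shape = c(64, 64), target_fraction = target,
                    seed = s)$realized_fraction
    })
    expect_lt(abs(mean(fr) - target) / target, 0.15)
  }
})

test_that("nested three-class masks keep class 2 inside the foreground", {
  task <- generate_task(3, shape = c(48, 48), target_fraction = 0.1,
                        num_classes = 3, seed = 5)
  expect_true(any(task$masks == 2))
  # class 2 arises only by exceeding the higher field threshold, so it is
  # a subset of the blob support; check it never touches background labels
  expect_true(all(task$masks[task$masks == 2] > 0))
  # nested fraction roughly respected
  frac2 <- sum(task$masks == 2) / sum(task$masks > 0)
  expect_gt(frac2, 0.05); expect_lt(frac2, 0.5)
})

test_that("images carry real signal aligned with the masks", {
  task <- generate_task(4, shape = c(64, 64), target_fraction = 0.05,
                        seed = 2, contrast = 0.5, noise_sd = 0.2)
  inside <- mean(task$images[, , , 1][task$masks > 0])
  outside <- mean(task$images[, , , 1][task$masks == 0])
  expect_gte(inside - outside, 0.5 * 0.5)
  expect_true(all(task$images >= 0 & task$images <= 1))
})

test_that("unreachable prevalence targets raise a constraint error", {
  expect_error(generate_task(1, shape = c(8, 8), target_fraction = 0.001),
               "below one pixel")
  expect_error(generate_task(1, shape = c(16, 16), target_fraction = 0.9),
               "target_fraction")
})

test_that("splitting partitions the batch deterministically", {
  task <- generate_task(100, shape = c(16, 16), target_fraction = 0.1, seed = 3)
  sp <- split_task(task, fractions = c(0.64, 0.16, 0.20), seed = 9)
  sizes <- sapply(sp, function(t) dim(t$masks)[1])
  expect_equal(unname(sizes), c(64, 16, 20))
  # disjoint and exhaustive: realized fractions recombine to the batch mean
  all_fr <- c(sp$train$per_image_fraction, sp$val$per_image_fraction,
              sp$test$per_image_fraction)
  expect_equal(sort(all_fr), sort(task$per_image_fraction))
  sp2 <- split_task(task, fractions = c(0.64, 0.16, 0.20), seed = 9)
  expect_identical(sp$test$masks, sp2$test$masks)
  expect_error(split_task(task, fractions = c(0.5, 0.2, 0.2)), "summing")
})

test_that("2D tasks export to PNG with a manifest and survive a round trip", {
  skip_if_not_installed("png")
  task <- generate_task(2, shape = c(16, 16), target_fraction = 0.1, seed = 4)
  dir <- file.path(tempdir(), "unifocal-export")
  man <- export_task(task, dir, format = "png")
  expect_true(all(file.exists(man$image)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m1 <- png::readPNG(man$mask[1])
  expect_equal(round(m1 * 1), task$masks[1, , ] * 1, tolerance = 1e-3)
  unlink(dir, recursive = TRUE)
})

test_that("3D tasks export to NIfTI volumes", {
  skip_if_not_installed("RNifti")
  task <- generate_task(1, shape = c(12, 12, 12), target_fraction = 0.05,
                        seed = 6)
  dir <- file.path(tempdir(), "unifocal-export3d")
  man <- export_task(task, dir, format = "nifti")
  img <- RNifti::readNifti(man$image[1])
  expect_equal(dim(img), c(12, 12, 12))
  unlink(dir, recursive = TRUE)
})

test_that("imbalance presets cover the benchmark prevalence regimes", {
  pre <- imbalance_presets()
  expect_setequal(round(pre$foreground_pct, 1), c(9.3, 8.7, 4.8, 0.2, 11.0))
  # every preset is generable
  row <- pre[pre$regime == "enhancing_brain_tumour", ]
  task <- generate_task(1, shape = c(64, 64), num_classes = row$num_classes,
                        target_fraction = row$target_fraction, seed = 1)
  expect_lt(abs(task$realized_fraction - 0.002), 0.001)
})
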