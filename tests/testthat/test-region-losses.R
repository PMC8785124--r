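test_that("soft Dice reproduces the imbalanced fixture and its limits", {
  fx <- fixture_16()
  sd <- soft_dice(fx$p, fx$y)
  expect_equal(sd$score[sd$class == 1], 1 / 3, tolerance = 1e-4)

  # identity and disjoint limits
  expect_equal(soft_dice(fx$y, fx$y)$score, c(1, 1), tolerance = 1e-5)
  lab_a <- array(c(1L, 0L), dim = c(1, 2))
  lab_b <- array(c(0L, 1L), dim = c(1, 2))
  dj <- soft_dice(one_hot_encode(lab_a, 2), one_hot_encode(lab_b, 2))
  expect_lt(max(dj$score), 1e-5)
})

test_that("Tversky and modified Tversky indices match plugged-in counts", {
  fx <- fixture_16()
  ti <- tversky_index(fx$p, fx$y, alpha = 0.3, beta = 0.7)
  expect_equal(ti$score[ti$class == 1], 2 / 5.2, tolerance = 1e-4)
  mti <- modified_tversky_index(fx$p, fx$y, delta = 0.6)
  expect_equal(mti$score[mti$class == 1], 0.3125, tolerance = 1e-4)

  # definitional identities
  expect_equal(tversky_index(fx$p, fx$y, 0.5, 0.5)$score,
               soft_dice(fx$p, fx$y)$score, tolerance = 1e-12)
  expect_equal(modified_tversky_index(fx$p, fx$y, 0.7)$score,
               tversky_index(fx$p, fx$y, 0.7, 0.3)$score, tolerance = 1e-12)
  expect_equal(tversky_index(fx$y, fx$y, 0.3, 0.7)$score, c(1, 1),
               tolerance = 1e-5)
})

test_that("Dice loss equals the symmetric Tversky loss and matches its fixture", {
  fx <- fixture_16()
  dl <- loss_dice(fx$p, fx$y, class_set = "foreground")
  expect_equal(dl$value, 1 - 1 / 3, tolerance = 1e-4)
  tl <- loss_tversky(fx$p, fx$y, 0.3, 0.7, class_set = "foreground")
  expect_equal(tl$value, 1 - 2 / 5.2, tolerance = 1e-4)
  for (s in 1:20) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = if (s %% 2) 2 else 3)
    expect_lt(abs(loss_dice(b$p, b$y)$value -
                    loss_tversky(b$p, b$y, 0.5, 0.5)$value), 1e-9)
  }
  expect_lt(loss_dice(fx$y, fx$y)$value, 1e-4)
})

test_that("focal Tversky loss reduces at gamma 1 and uses the 1/gamma exponent", {
  for (s in 1:20) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
    expect_lt(abs(loss_focal_tversky(b$p, b$y, 0.3, 0.7, gamma = 1)$value -
                    loss_tversky(b$p, b$y, 0.3, 0.7)$value), 1e-9)
  }
  # construct a batch whose foreground Tversky index is exactly 0.75:
  # fg fraction 1/2, fg probability q = 21/22 everywhere
  q <- 21 / 22
  lab <- array(rep(c(0L, 1L), each = 8), dim = c(1, 4, 4))
  y <- one_hot_encode(lab, 2)
  p <- array(c(rep(1 - q, 16), rep(q, 16)), dim = c(1, 4, 4, 2))
  ti <- tversky_index(p, y, 0.3, 0.7)
  expect_equal(ti$score[ti$class == 1], 0.75, tolerance = 1e-5)
  v <- loss_focal_tversky(p, y, 0.3, 0.7, gamma = 4 / 3,
                          class_set = "foreground")$value
  expect_equal(v, 0.25^0.75, tolerance = 1e-4)
  expect_equal(0.25^0.75, 0.3536, tolerance = 5e-4)
  expect_lt(loss_focal_tversky(y, y, 0.3, 0.7)$value, 1e-4)
})

test_that("modified focal Tversky loss uses the 1 - gamma enhancement exponent", {
  for (s in 1:10) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
    expect_lt(abs(
      loss_modified_focal_tversky(b$p, b$y, delta = 0.5, gamma = 0)$value -
        loss_dice(b$p, b$y)$value), 1e-9)
  }
  fx <- fixture_16()
  v <- loss_modified_focal_tversky(fx$p, fx$y, delta = 0.6, gamma = 0.5,
                                   class_set = "foreground")$value
  expect_equal(v, 0.6875^0.5, tolerance = 1e-4)
  expect_equal(0.6875^0.5, 0.8292, tolerance = 1e-4)
  # literal compatibility mode
  vl <- loss_modified_focal_tversky(fx$p, fx$y, delta = 0.6, gamma = 0.5,
                                    class_set = "foreground",
                                    literal_exponents = TRUE)$value
  expect_equal(vl, 0.6875^0.5, tolerance = 1e-4)  # 0.5 is self-complementary
  vl3 <- loss_modified_focal_tversky(fx$p, fx$y, delta = 0.6, gamma = 0.3,
                                     class_set = "foreground",
                                     literal_exponents = TRUE)$value
  expect_equal(vl3, 0.6875^0.3, tolerance = 1e-4)
})

test_that("asymmetric focal Tversky enhances only rare classes", {
  fx <- fixture_16()
  # background and rare contributions assembled from measured indices
  mti <- modified_tversky_index(fx$p, fx$y, delta = 0.6)
  bg <- mti$score[mti$class == 0]; fg <- mti$score[mti$class == 1]
  v <- loss_modified_asymmetric_focal_tversky(fx$p, fx$y, delta = 0.6,
                                              gamma = 0.5)$value
  expect_equal(v, (1 - bg) + (1 - fg)^0.5, tolerance = 1e-9)
  expect_equal((1 - 0.9) + (1 - 0.3125)^0.5, 0.9292, tolerance = 1e-4)

  # gamma = 0 collapses to the plain Tversky(delta) loss
  set.seed(3)
  b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
  expect_lt(abs(
    loss_modified_asymmetric_focal_tversky(b$p, b$y, delta = 0.6,
                                           gamma = 0)$value -
      loss_tversky(b$p, b$y, alpha = 0.6, beta = 0.4)$value), 1e-9)

  # enhancement never decreases the rare-class term
  plain <- loss_modified_focal_tversky(b$p, b$y, delta = 0.6, gamma = 0,
                                       class_set = "foreground")$value
  enh <- loss_modified_asymmetric_focal_tversky(b$p, b$y, delta = 0.6,
                                                gamma = 0.5,
                                                class_set = "foreground")$value
  expect_gte(enh, plain - 1e-12)
})

test_that("Tversky-family losses respond to delta in the false-negative direction", {
  # fixture with fn > fp: under-segmented foreground
  lab <- array(0L, dim = c(1, 4, 4)); lab[1, , 1:2] <- 1L   # 8 fg positions
  y <- one_hot_encode(lab, 2)
  p <- array(0, dim = c(1, 4, 4, 2))
  p[, , , 2] <- 0.2; p[, , , 1] <- 0.8                       # fn-heavy
  lo <- loss_tversky(p, y, alpha = 0.3, beta = 0.7, class_set = "foreground")
  hi <- loss_tversky(p, y, alpha = 0.7, beta = 0.3, class_set = "foreground")
  # weighting fn more (beta larger) raises the loss on an fn-heavy fixture
  expect_gt(lo$value, hi$value)
  # mTI puts weight 1 - delta on fn, so raising delta lowers the fn-heavy
  # foreground term
  m3 <- loss_modified_focal_tversky(p, y, delta = 0.3, gamma = 0,
                                    class_set = "foreground")$value
  m7 <- loss_modified_focal_tversky(p, y, delta = 0.7, gamma = 0,
                                    class_set = "foreground")$value
  expect_gt(m3, m7)
  # hand-oracle validation of the direction on the foreground class
  o3 <- oracle_region_family(p, y, 0.3, 0.7, rep(1, 2), 2)
  o7 <- oracle_region_family(p, y, 0.7, 0.3, rep(1, 2), 2)
  expect_equal(m3, mean(o3), tolerance = 1e-9)
  expect_gt(mean(o3), mean(o7))
})

test_that("vectorised region losses equal the per-position loop oracle", {
  for (s in 1:20) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
    o <- oracle_all_losses(b$p, b$y)
    specs <- registry_specs()
    for (nm in c("dice", "tversky", "focal_tversky", "modified_focal_tversky",
                 "modified_asymmetric_focal_tversky")) {
      expect_lt(max(abs(compute_loss(specs[[nm]], b$p, b$y)$per_item - o[[nm]])),
                1e-9)
    }
  }
})

test_that("region scores stay in [0, 1] and errors are raised for bad settings", {
  set.seed(2)
  b <- random_softmax_batch(3, c(4, 4), num_classes = 3)
  sc <- tversky_index(b$p, b$y, 0.3, 0.7)$score
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(tversky_index(b$p, b$y, -0.1, 0.7), "non-negative")
  expect_error(loss_focal_tversky(b$p, b$y, gamma = 0), "gamma")
  expect_error(modified_tversky_index(b$p, b$y, delta = 1.2), "delta")
  expect_error(loss_modified_focal_tversky(b$p, b$y, gamma = 1), "gamma")
})
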