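# single foreground position with p_t = 0.5, as a (1,1,2) batch
point_batch <- function(pt = 0.5) {
  y <- one_hot_encode(array(1L, dim = c(1, 1)), 2)
  p <- array(c(1 - pt, pt), dim = c(1, 1, 2))
  list(p = p, y = y)
}

test_that("cross entropy matches hand-computed values", {
  b <- point_batch(0.5)
  expect_equal(loss_cross_entropy(b$p, b$y)$value, log(2), tolerance = 1e-9)

  # perfect prediction is (clipped) zero
  lab <- array(c(0L, 1L), dim = c(1, 2))
  y <- one_hot_encode(lab, 2)
  expect_lt(loss_cross_entropy(y, y, epsilon = 1e-7)$value, 1e-6)

  # four positions with p_t 0.9, 0.8, 0.7, 0.6: mean of the four -log terms
  pt <- c(0.9, 0.8, 0.7, 0.6)
  y4 <- one_hot_encode(array(1L, dim = c(1, 2, 2)), 2)
  p4 <- array(c(1 - pt, pt), dim = c(1, 2, 2, 2))
  expect_equal(loss_cross_entropy(p4, y4)$value, mean(-log(pt)),
               tolerance = 1e-9)
  expect_equal(mean(-log(pt)), 0.29900, tolerance = 1e-4)
})

test_that("focal loss reduces to cross entropy at gamma 0 and matches its fixture", {
  for (s in 1:20) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = if (s %% 2) 2 else 3)
    expect_lt(abs(loss_focal(b$p, b$y, alpha = NULL, gamma = 0)$value -
                    loss_cross_entropy(b$p, b$y)$value), 1e-9)
    # modulating factor never increases the loss
    expect_lte(loss_focal(b$p, b$y, alpha = NULL, gamma = 2)$value,
               loss_cross_entropy(b$p, b$y)$value)
  }
  b <- point_batch(0.5)
  expect_equal(loss_focal(b$p, b$y, alpha = 0.25, gamma = 2)$value,
               0.25 * 0.25 * log(2), tolerance = 1e-9)
  expect_equal(0.25 * 0.25 * log(2), 0.04332, tolerance = 1e-4)
  bp <- point_batch(1)  # pre-clip perfect prediction
  expect_lt(loss_focal(bp$p, bp$y, alpha = 0.25, gamma = 2)$value, 1e-8)
})

test_that("modified focal loss follows the gamma-as-exponent convention", {
  for (s in 1:10) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
    expect_lt(abs(loss_modified_focal(b$p, b$y, delta = 0.5, gamma = 0)$value -
                    0.5 * loss_cross_entropy(b$p, b$y)$value), 1e-9)
  }
  b <- point_batch(0.5)
  expect_equal(loss_modified_focal(b$p, b$y, delta = 0.6, gamma = 0.5)$value,
               0.6 * sqrt(0.5) * log(2), tolerance = 1e-9)
  expect_equal(0.6 * sqrt(0.5) * log(2), 0.2941, tolerance = 1e-4)

  # delta = 1 removes the background contribution entirely
  lab <- array(c(1L, 0L), dim = c(1, 2))
  y <- one_hot_encode(lab, 2)
  p <- array(0.5, dim = c(1, 2, 2))
  full <- loss_modified_focal(p, y, delta = 1, gamma = 0)$value
  fg_only <- 0.5 * log(2)  # one of two positions, weight 1
  expect_equal(full, fg_only, tolerance = 1e-9)

  # literal compatibility mode uses the 1 - gamma exponent
  expect_equal(
    loss_modified_focal(b$p, b$y, delta = 0.6, gamma = 0.3,
                        literal_exponents = TRUE)$value,
    0.6 * 0.5^0.7 * log(2), tolerance = 1e-9)
})

test_that("asymmetric focal loss exempts rare classes from suppression", {
  lab <- array(c(1L, 0L), dim = c(1, 2))
  y <- one_hot_encode(lab, 2)
  p <- array(0.5, dim = c(1, 2, 2))
  v <- loss_modified_asymmetric_focal(p, y, delta = 0.6, gamma = 0.5)$value
  expect_equal(v, mean(c(0.6 * log(2), 0.4 * sqrt(0.5) * log(2))),
               tolerance = 1e-9)
  expect_equal(v, 0.3059, tolerance = 5e-4)

  # gamma = 0 equals the delta-weighted cross entropy
  for (s in 1:10) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
    expect_lt(abs(
      loss_modified_asymmetric_focal(b$p, b$y, delta = 0.6, gamma = 0)$value -
        loss_modified_focal(b$p, b$y, delta = 0.6, gamma = 0)$value), 1e-9)
  }

  # background term strictly decreasing in gamma at fixed p_t
  ybg <- one_hot_encode(array(0L, dim = c(1, 1)), 2)
  pbg <- array(c(0.5, 0.5), dim = c(1, 1, 2))
  vals <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(g) {
    loss_modified_asymmetric_focal(pbg, ybg, delta = 0.6, gamma = g)$value
  })
  expect_true(all(diff(vals) < 0))
})

test_that("distribution losses are non-negative and zero only at perfection", {
  set.seed(11)
  b <- random_softmax_batch(2, c(4, 4), num_classes = 3)
  specs <- registry_specs()[c("cross_entropy", "focal", "modified_focal",
                              "modified_asymmetric_focal")]
  for (sp in specs) {
    expect_gt(compute_loss(sp, b$p, b$y)$value, 0)
    expect_lt(compute_loss(sp, b$y, b$y)$value, 1e-5)
  }
})

test_that("vectorised distribution losses equal the per-position loop oracle", {
  for (s in 1:20) {
    set.seed(s)
    b <- random_softmax_batch(2, c(4, 4), num_classes = 2)
    o <- oracle_all_losses(b$p, b$y)
    specs <- registry_specs()
    for (nm in c("cross_entropy", "focal", "modified_focal",
                 "modified_asymmetric_focal")) {
      expect_lt(max(abs(compute_loss(specs[[nm]], b$p, b$y)$per_item - o[[nm]])),
                1e-9)
    }
  }
})

test_that("configuration errors are raised for invalid settings", {
  b <- point_batch()
  expect_error(loss_focal(b$p, b$y, gamma = -1), "gamma")
  expect_error(loss_focal(b$p, b$y, alpha = c(0.1, 0.2, 0.3)), "alpha")
  expect_error(loss_modified_focal(b$p, b$y, gamma = 1), "gamma")
  expect_error(loss_modified_asymmetric_focal(b$p, b$y, rare_classes = 0L),
               "background")
  expect_error(loss_modified_asymmetric_focal(b$p, b$y, rare_classes = 5L),
               "subset")
})
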