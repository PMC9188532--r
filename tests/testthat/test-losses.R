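test_that("categorical cross-entropy closed forms", {
  expect_equal(categorical_cross_entropy(c(1, 0), c(1, 0)), 0,
               tolerance = 1e-6)
  expect_equal(categorical_cross_entropy(c(0.5, 0.5), c(1, 0)), log(2),
               tolerance = 1e-12)
  # batch mean equals mean of per-sample losses
  sf <- cbind(c(0.9, 0.1), c(0.3, 0.7), c(0.5, 0.5))
  gt <- cbind(c(1, 0), c(0, 1), c(1, 0))
  per <- vapply(1:3, function(i) categorical_cross_entropy(sf[, i], gt[, i]),
                0)
  expect_equal(categorical_cross_entropy(sf, gt), mean(per),
               tolerance = 1e-12)
})

test_that("weighted cross-entropy matches a scalar-loop oracle and is linear in w", {
  set.seed(30)
  K <- 3
  p <- array(runif(4 * 4 * K), c(4, 4, K))
  for (i in 1:4) for (j in 1:4) p[i, j, ] <- p[i, j, ] / sum(p[i, j, ])
  labels <- matrix(sample(0:(K - 1), 16, TRUE), 4, 4)
  w <- matrix(runif(16, 0.5, 3), 4, 4)
  oracle <- 0
  for (i in 1:4) for (j in 1:4)
    oracle <- oracle - w[i, j] * log(p[i, j, labels[i, j] + 1])
  expect_equal(weighted_cross_entropy(p, labels, w), oracle,
               tolerance = 1e-6)
  # unit weights reduce to the sum of per-pixel cross-entropies
  expect_equal(weighted_cross_entropy(p, labels, w * 0 + 1),
               oracle_unit <- sum(sapply(1:4, function(i) sapply(1:4,
                 function(j) -log(p[i, j, labels[i, j] + 1])))),
               tolerance = 1e-6)
  # linearity: scaling w scales L
  expect_equal(weighted_cross_entropy(p, labels, 2 * w),
               2 * weighted_cross_entropy(p, labels, w), tolerance = 1e-9)
  # perfect one-hot predictions give zero loss
  onehot <- array(0, c(4, 4, K))
  for (i in 1:4) for (j in 1:4) onehot[i, j, labels[i, j] + 1] <- 1
  expect_equal(weighted_cross_entropy(onehot, labels, w), 0,
               tolerance = 1e-5)
  expect_error(weighted_cross_entropy(p, labels[1:3, 1:3], w), "mismatch")
})

test_that("softmax + weighted cross-entropy gradient matches finite differences", {
  set.seed(31)
  logits <- array(rnorm(2 * 2 * 3), c(2, 2, 3, 1))
  labels <- array(sample(0:2, 4, TRUE), c(2, 2, 1))
  w <- array(runif(4, 0.5, 2), c(2, 2, 1))
  loss_of <- function(z) {
    p <- muscleseg:::softmax_pixelwise(z)
    weighted_cross_entropy(p[, , , 1], labels[, , 1], w[, , 1])
  }
  p <- muscleseg:::softmax_pixelwise(logits)
  analytic <- p
  for (i in 1:2) for (j in 1:2) {
    analytic[i, j, labels[i, j, 1] + 1, 1] <-
      analytic[i, j, labels[i, j, 1] + 1, 1] - 1
    analytic[i, j, , 1] <- analytic[i, j, , 1] * w[i, j, 1]
  }
  for (idx in seq_len(length(logits))) {
    zp <- logits; zp[idx] <- zp[idx] + 1e-6
    zm <- logits; zm[idx] <- zm[idx] - 1e-6
    fd <- (loss_of(zp) - loss_of(zm)) / 2e-6
    expect_equal(analytic[idx], fd, tolerance = 1e-4)
  }
})

test_that("Dice closed forms, symmetry and range", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_coefficient(a, a)$mean, 1)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dice_coefficient(a, b)$mean, 0)
  # TP = 2, FP = 1, FN = 1 -> 4/6
  pred <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  truth <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  expect_equal(dice_coefficient(pred, truth, class = 1), 2 / 3,
               tolerance = 1e-12)
  # symmetry and range on random maps
  set.seed(32)
  x <- matrix(sample(0:3, 64, TRUE), 8, 8)
  y <- matrix(sample(0:3, 64, TRUE), 8, 8)
  expect_equal(dice_coefficient(x, y)$mean, dice_coefficient(y, x)$mean)
  expect_true(all(dice_coefficient(x, y)$per_class >= 0 &
                    dice_coefficient(x, y)$per_class <= 1))
  # class absent from both is skipped
  expect_true(is.na(dice_coefficient(x, y, class = 9)))
})

test_that("categorical accuracy counts matches", {
  expect_equal(categorical_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(categorical_accuracy(c(1, 2), c(2, 1)), 0)
  expect_equal(categorical_accuracy(c(1, 2, 3, 4), c(1, 2, 3, 0)), 0.75)
  expect_error(categorical_accuracy(1:3, 1:4), "length")
})
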