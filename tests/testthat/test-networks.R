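test_that("receptive fields reproduce the published progression", {
  rf <- receptive_fields(contracting_block_specs(6, block6_kernel = 4))
  expect_equal(rf[[1]], c(1, 3, 5))
  expect_equal(rf[[2]], c(6, 10, 14))
  expect_equal(rf[[3]], c(16, 24, 32))
  expect_equal(rf[[4]], c(36, 52, 68))
  expect_equal(rf[[5]], c(76, 108, 140))
  expect_equal(rf[[6]], c(188, 284, 380))
  # label-literal kernel-3 variant of the sixth block
  rf3 <- receptive_fields(contracting_block_specs(6, block6_kernel = 3))
  expect_equal(rf3[[6]], c(172, 268, 364))
})

test_that("receptive-field recursion matches the gradient-support oracle", {
  # all-linear stack of the first two blocks' convolutions (positive weights,
  # no normalization or nonlinearity): the footprint of one output unit's
  # input gradient is exactly the computed field.
  set.seed(20)
  convs <- list(muscleseg:::make_conv(1, 1, 1, 1),
                muscleseg:::make_conv(1, 1, 3, 1),
                muscleseg:::make_conv(1, 1, 3, 1),
                muscleseg:::make_conv(1, 1, 2, 2),
                muscleseg:::make_conv(1, 1, 3, 1),
                muscleseg:::make_conv(1, 1, 3, 1))
  for (cv in convs) cv$W <- abs(cv$W) + 0.1
  n <- 40
  x <- array(runif(n * n), c(n, n, 1, 1))
  for (cv in convs) x <- muscleseg:::conv_fw(cv, x)
  dy <- array(0, dim(x))
  ctr <- ceiling(dim(x)[1] / 2)
  dy[ctr, ctr, 1, 1] <- 1
  g <- dy
  for (cv in rev(convs)) g <- muscleseg:::conv_bw(cv, g)
  support <- which(abs(g[, , 1, 1]) > 0, arr.ind = TRUE)
  width_r <- diff(range(support[, 1])) + 1
  rf <- receptive_fields(contracting_block_specs(2))
  expect_identical(as.integer(width_r), as.integer(rf[[2]][3]))
})

test_that("classifier emits a 2-probability vector with the expected level dims", {
  set.seed(21)
  net <- build_classifier(classifier_spec(input_size = 64L,
                                          width_multiplier = 1 / 8))
  x <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  p <- net_forward(net, x)
  expect_identical(dim(p), c(2L, 3L))
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  # per-block spatial halving: 128 -> 128, 64, 32, 16, 8 at reference size
  expect_identical(contracting_shapes(128L, c(1, 2, 2, 2, 2)),
                   c(128L, 64L, 32L, 16L, 8L))
  # forward is deterministic in inference mode
  expect_identical(p, net_forward(net, x))
})

test_that("width multiplier shrinks convolutional parameters quadratically", {
  set.seed(22)
  full <- build_classifier(classifier_spec(64L, 1))
  eighth <- build_classifier(classifier_spec(64L, 1 / 8))
  ratio <- n_parameters(full, conv_only = TRUE) /
    n_parameters(eighth, conv_only = TRUE)
  expect_gt(ratio, 45)
  expect_lt(ratio, 70)
})

test_that("segmenter outputs per-pixel softmax over the district's class count", {
  set.seed(23)
  for (K in c(13L, 7L)) {
    net <- build_segmenter(segmenter_spec(n_classes = K, input_size = 48L,
                                          width_multiplier = 1 / 8))
    p <- net_forward(net, array(runif(48 * 48), c(48, 48, 1, 1)))
    expect_identical(dim(p), c(48L, 48L, K, 1L))
    expect_true(all(p >= 0))
    sums <- apply(p[, , , 1], c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  # contracting spatial dims at reference scale
  expect_identical(contracting_shapes(432L), c(432L, 216L, 108L, 54L, 27L, 9L))
})

test_that("analytic loss gradients match finite differences through the segmenter", {
  set.seed(24)
  sp <- segmenter_spec(n_classes = 3, input_size = 12L,
                       width_multiplier = 1 / 16)
  net <- build_segmenter(sp)
  x <- array(runif(12 * 12 * 2), c(12, 12, 1, 2))
  labels <- array(sample(0:2, 12 * 12 * 2, TRUE), c(12, 12, 2))
  weights <- array(runif(12 * 12 * 2, 0.5, 2), c(12, 12, 2))
  r <- muscleseg:::segmenter_batch(net, x, labels, weights, training = TRUE)
  muscleseg:::segmenter_backward(net, r$dlogits)
  params <- muscleseg:::all_params(net)
  loss_at <- function() muscleseg:::segmenter_batch(net, x, labels, weights,
                                                    training = TRUE)$loss
  for (pi in sample(seq_along(params), 8)) {
    p <- params[[pi]]
    th <- p$env[[p$f]]
    i <- sample(length(th), 1)
    eps <- 1e-5
    p$env[[p$f]][i] <- th[i] + eps; lp <- loss_at()
    p$env[[p$f]][i] <- th[i] - eps; lm <- loss_at()
    p$env[[p$f]][i] <- th[i]
    fd <- (lp - lm) / (2 * eps)
    expect_equal(p$env[[p$g]][i], fd, tolerance = 1e-4)
  }
})
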