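tiny_classifier_setup <- function(n = 6, size = 32L, seed = 40) {
  slices <- c(
    generate_dataset(phantom_config("thigh", image_size = 64, seed = seed),
                     n / 2, seed = seed),
    generate_dataset(phantom_config("leg", image_size = 64, seed = seed + 1),
                     n / 2, seed = seed + 1))
  data <- as_classifier_data(slices, size)
  net <- build_classifier(classifier_spec(size, width_multiplier = 1 / 16))
  list(net = net, data = data)
}

test_that("a zero learning rate leaves parameters bitwise unchanged", {
  set.seed(41)
  su <- tiny_classifier_setup()
  before <- lapply(muscleseg:::all_params(su$net),
                   function(p) p$env[[p$f]])
  cfg <- train_config(lr = 0, dropout_rate = 0, l2_factor = 0,
                      batch_size = 3L, epochs = 1L, seed = 1L)
  train(su$net, su$data, config = cfg)
  after <- lapply(muscleseg:::all_params(su$net), function(p) p$env[[p$f]])
  for (i in seq_along(before))
    expect_identical(before[[i]], after[[i]])
})

test_that("plateau scheduler halves the rate after four flat epochs", {
  sch <- plateau_scheduler(0.01, factor = 0.5, patience = 4L)
  lrs <- vapply(rep(1.0, 5), sch$update, 0)
  expect_equal(lrs, c(0.01, 0.01, 0.01, 0.01, 0.005))
  # improvement resets the wait counter
  sch2 <- plateau_scheduler(0.01, 0.5, 4L)
  expect_equal(vapply(c(1, 0.9, 0.9, 0.9, 0.8, 0.8, 0.8, 0.8, 0.8),
                      sch2$update, 0)[9], 0.005)
})

test_that("training history is reproducible under a fixed seed", {
  run_once <- function() {
    set.seed(42)
    su <- tiny_classifier_setup()
    cfg <- train_config(lr = 0.003, dropout_rate = 0.1, l2_factor = 1e-4,
                        batch_size = 3L, epochs = 3L, seed = 7L)
    train(su$net, su$data, config = cfg)$history
  }
  h1 <- run_once()
  h2 <- run_once()
  expect_equal(h1$train_loss, h2$train_loss, tolerance = 1e-5)
  expect_identical(names(h1), c("epoch", "lr", "train_loss", "train_metric",
                                "val_loss", "val_metric"))
})

test_that("L2 regularization shrinks the weight-norm trajectory", {
  norms_for <- function(reg) {
    set.seed(43)
    su <- tiny_classifier_setup()
    cfg <- train_config(lr = 0.003, dropout_rate = 0, l2_factor = reg,
                        batch_size = 3L, epochs = 4L, seed = 7L)
    train(su$net, su$data, config = cfg)
    sqrt(sum(vapply(muscleseg:::all_params(su$net), function(p)
      if (p$decay) sum(p$env[[p$f]]^2) else 0, 0)))
  }
  expect_lt(norms_for(0.05), norms_for(0))
})

test_that("training aborts with a diagnostic when the loss turns non-finite", {
  set.seed(44)
  su <- tiny_classifier_setup()
  # poison one kernel: the forward pass produces NaN probabilities
  p1 <- muscleseg:::all_params(su$net)[[1]]
  p1$env[[p1$f]][1] <- NaN
  cfg <- train_config(lr = 0.001, dropout_rate = 0, l2_factor = 0,
                      batch_size = 3L, epochs = 1L, seed = 7L)
  expect_error(suppressWarnings(train(su$net, su$data, config = cfg)),
               "diverged")
})

test_that("hyperband returns the best configuration with a full trial log", {
  set.seed(45)
  slices <- c(
    generate_dataset(phantom_config("thigh", image_size = 64, seed = 50), 4,
                     seed = 50),
    generate_dataset(phantom_config("leg", image_size = 64, seed = 51), 4,
                     seed = 51))
  trn <- as_classifier_data(slices[c(1, 2, 3, 5, 6, 7)], 32L)
  val <- as_classifier_data(slices[c(4, 8)], 32L)
  space <- expand.grid(lr = c(0.001, 0.005), dr = c(0, 0.2), reg = c(0, 0.01))
  res <- hyperband_search(
    function() build_classifier(classifier_spec(32L, 1 / 16)),
    trn, val, space, max_epochs = 3L, batch_size = 3L, seed = 9L)
  expect_true(all(c("lr", "dr", "reg") %in% names(res$config)))
  expect_true(res$score >= stats::median(res$log$score))
  expect_true(all(res$log$epochs <= 3))
  # a single-configuration space is returned unchanged
  one <- space[2, , drop = FALSE]
  res1 <- hyperband_search(
    function() build_classifier(classifier_spec(32L, 1 / 16)),
    trn, val, one, max_epochs = 2L, batch_size = 3L, seed = 9L)
  expect_equal(res1$config$lr, one$lr)
  # determinism of the search under a fixed seed
  res2 <- hyperband_search(
    function() build_classifier(classifier_spec(32L, 1 / 16)),
    trn, val, one, max_epochs = 2L, batch_size = 3L, seed = 9L)
  expect_equal(res1$score, res2$score, tolerance = 1e-6)
  expect_error(hyperband_search(function() NULL, trn, val,
                                space[0, ], seed = 1), "empty")
})
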