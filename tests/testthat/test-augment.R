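test_that("side splitting isolates one limb's classes per mask and mirrors", {
  s <- thigh64()
  sides <- split_sides(s)
  lab_left <- s$labels; lab_left[!sides$left] <- 0L
  lab_right <- s$labels; lab_right[!sides$right] <- 0L
  expect_setequal(setdiff(unique(as.vector(lab_left)), 0L), 1:12)
  expect_setequal(setdiff(unique(as.vector(lab_right)), 0L), 1:12)
  expect_false(any(sides$left & sides$right))
  # mirroring the slice swaps the masks
  sm <- s
  sm$image <- s$image[, ncol(s$image):1]
  sm$labels <- s$labels[, ncol(s$labels):1]
  sw <- split_sides(sm)
  expect_gt(sum(sw$left & sides$right[, ncol(s$image):1]) /
              sum(sides$right), 0.99)
})

test_that("touching limbs raise a side-split error", {
  s <- thigh64()
  # merge: a bright horizontal bar connecting both limbs
  s2 <- s
  s2$image[30:34, ] <- 0.9
  expect_error(split_sides(s2), "side-split")
})

test_that("side translation bounds offsets by the border distance and preserves area", {
  s <- leg64()
  set.seed(1)
  areas <- replicate(50, {
    out <- random_side_translation(s)
    p <- attr(out, "transform_params")
    for (side in p) {
      expect_lte(abs(side["dx"]), side["D"])
      expect_lte(abs(side["dy"]), side["D"])
    }
    sum(out$labels > 0)
  })
  a0 <- sum(s$labels > 0)
  expect_true(all(abs(areas - a0) / a0 <= 0.02))
})

test_that("translation of a border-touching side is the identity", {
  s <- thigh64()
  sides <- split_sides(s)
  # shift the left limb flush against the left border
  bb <- bbox <- muscleseg:::bbox_of(sides$left)
  shift <- bb["cmin"] - 1
  s2 <- s
  s2$image <- cbind(s$image[, -seq_len(shift)],
                    matrix(0.05, nrow(s$image), shift))
  s2$labels <- cbind(s$labels[, -seq_len(shift)],
                     matrix(0L, nrow(s$labels), shift))
  set.seed(2)
  out <- random_side_translation(s2)
  p <- attr(out, "transform_params")
  D <- vapply(p, function(v) v[["D"]], 0)
  expect_true(any(D == 0))
  k0 <- which(D == 0)[1]
  expect_identical(p[[k0]][["dx"]], 0)
  sides2 <- split_sides(s2)
  m <- if (k0 == 1) sides2$left else sides2$right
  expect_identical(out$labels[m], s2$labels[m])
})

test_that("side rotations sample within range and are near-invertible", {
  s <- leg64()
  set.seed(3)
  angs <- unlist(replicate(200, {
    out <- random_side_rotation(s)
    vapply(attr(out, "transform_params"), function(v) v[["angle"]], 0)
  }, simplify = FALSE))
  expect_true(all(angs >= -7 & angs <= 7))
  se <- sd(angs) / sqrt(length(angs))
  expect_lt(abs(mean(angs)), 3 * se + 0.5)

  # rotating +7 then -7 degrees nearly recovers large classes
  set.seed(4)
  r1 <- random_side_rotation(s, rotation_range = c(7, 7))
  r2 <- random_side_rotation(r1, rotation_range = c(-7, -7))
  big <- names(which(table(s$labels[s$labels > 0]) > 80))
  for (cl in as.integer(big)) {
    d <- dice_coefficient(r2$labels, s$labels, class = cl)
    expect_gte(d, 0.95)
  }
  # forcing a zero angle gives the identity
  set.seed(5)
  r0 <- random_side_rotation(s, rotation_range = c(0, 0))
  expect_identical(r0$labels, s$labels)
})

test_that("piecewise-affine displacements follow the scaled normal amplitude", {
  s <- thigh64()
  set.seed(6)
  disp <- unlist(replicate(40, {
    out <- piecewise_affine(s, scale_range = c(1, 1))
    p <- attr(out, "transform_params")
    c(p$disp_r, p$disp_c)
  }, simplify = FALSE))
  sd_expect <- 64 / 100  # 1 percent of the image size
  expect_lt(max(abs(disp)), 5 * sd_expect)
  expect_equal(sd(disp), sd_expect, tolerance = 0.15)
  # labels never gain classes; zero scale is the identity
  set.seed(7)
  out <- piecewise_affine(s)
  expect_true(all(unique(as.vector(out$labels)) %in%
                    unique(as.vector(s$labels))))
  id <- piecewise_affine(s, scale_range = c(1e-9, 1e-9))
  expect_identical(id$labels, s$labels)
})

test_that("elastic fields smooth with larger kernels and keep labels valid", {
  set.seed(8)
  raw_state <- .Random.seed
  f5 <- muscleseg:::elastic_field(64, 64, kernel_sd = 5, strength = 10)
  .Random.seed <<- raw_state
  f10 <- muscleseg:::elastic_field(64, 64, kernel_sd = 10, strength = 10)
  roughness <- function(f) mean(abs(diff(f$r))) + mean(abs(diff(f$c)))
  expect_lt(roughness(f10), roughness(f5))

  s <- leg64()
  set.seed(9)
  out <- elastic(s)
  expect_true(all(out$labels %in% 0:6))
  expect_identical(dim(out$labels), dim(s$labels))
  id <- elastic(s, strength_range = c(0, 0))
  expect_identical(id$labels, s$labels)
})

test_that("the dataset builder emits the configured count, split and log", {
  src <- generate_dataset(phantom_config("leg", image_size = 64, seed = 1),
                          3, seed = 1)
  cfg <- augmentation_config(target_count = 10, seed = 5)
  res <- build_augmented_dataset(src, cfg)
  expect_length(res$train, 9)
  expect_length(res$validation, 1)
  expect_identical(nrow(res$log), 10L)
  # same seed reproduces bit-identically
  res2 <- build_augmented_dataset(src, cfg)
  expect_identical(lapply(res$train, `[[`, "labels"),
                   lapply(res2$train, `[[`, "labels"))
  # every augmented pair keeps valid labels and dimensions
  for (s in res$train) {
    expect_true(all(s$labels %in% 0:6))
    expect_identical(dim(s$image), c(64L, 64L))
  }
  # mixed districts are refused, as is an empty source list
  thigh <- generate_slice(phantom_config("thigh", image_size = 64, seed = 2))
  expect_error(build_augmented_dataset(c(src, list(thigh)), cfg), "mixed")
  expect_error(build_augmented_dataset(list(), cfg), "empty")
})
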