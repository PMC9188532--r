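test_that("class weights are inverse frequencies with background normalized to 1", {
  m <- matrix(0L, 10, 10)
  m[1:5, 1:5] <- 1L  # 25 of 100 pixels
  w <- class_frequency_weights(list(m), 2)
  expect_equal(unname(w["1"] / w["0"]), 3)
  expect_equal(unname(w["0"]), 1)
  # equal-area classes get equal weights
  m2 <- matrix(rep(0:3, each = 25), 10, 10)
  w2 <- class_frequency_weights(list(m2), 4)
  expect_true(all(abs(w2 - w2[1]) < 1e-12))
  # absent classes are reported by name
  expect_error(class_frequency_weights(list(m), 3), "2")
})

test_that("the smallest phantom muscle receives the largest weight", {
  slices <- generate_dataset(phantom_config("thigh", image_size = 64,
                                            seed = 4), 4, seed = 4)
  w <- class_frequency_weights(slices, 13)
  counts <- Reduce(`+`, lapply(slices, function(s)
    tabulate(as.vector(s$labels) + 1L, 13)))
  expect_equal(unname(which.max(w[-1])), unname(which.min(counts[-1])))
  # strict monotonicity: rarer class => larger weight
  ord <- order(counts)
  expect_true(all(diff(w[ord]) <= 0))
})

test_that("border weight is w0 at zero distances and the term vanishes with one muscle", {
  params <- weight_map_params(10, 7)
  expect_identical(border_weight(0, 0, params), 10)
  # exactly-known distances on a toy map
  m2 <- matrix(0L, 8, 8)
  m2[4, 3] <- 1L
  m2[4, 5] <- 2L
  t2 <- separation_border_term(m2, params)
  # background pixel (4,4): d1 = d2 = 1
  expect_equal(t2[4, 4], border_weight(1, 1, params), tolerance = 1e-12)
  # class-1 pixel (4,3): d1 = 0 (own class), d2 = 2
  expect_equal(t2[4, 3], border_weight(0, 2, params), tolerance = 1e-12)
  single <- matrix(0L, 8, 8); single[3:5, 3:5] <- 1L
  expect_true(all(separation_border_term(single) == 0))
})

test_that("distance computation matches the exhaustive oracle exactly", {
  set.seed(10)
  for (rep in 1:2) {
    m <- matrix(0L, 16, 16)
    m[2:5, 2:6] <- 1L
    m[9:14, 8:13] <- 2L
    m[sample(256, 6)] <- 0L  # poke holes
    got <- separation_border_term(m, weight_map_params(10, 7))
    want <- border_term_oracle(m, 10, 7)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("weight map combines class term and border term with the stated structure", {
  s <- thigh64()
  cw <- class_frequency_weights(list(s$labels), 13)
  params <- weight_map_params(10, 7)
  wm <- compute_weight_map(s$labels, cw, params)
  # far from all borders the map reduces to the class weight
  border <- separation_border_term(s$labels, params)
  far <- border < 1e-6
  expect_true(any(far))
  expect_equal(wm[far], cw[as.character(s$labels[far])],
               ignore_attr = TRUE, tolerance = 1e-6)
  # linearity in w0
  wm2 <- compute_weight_map(s$labels, cw, weight_map_params(20, 7))
  cls <- matrix(cw[as.character(s$labels)], 64, 64)
  expect_equal(wm2 - cls, 2 * (wm - cls), tolerance = 1e-9)
  # inter-muscle corridors carry the top percentile of the map
  q99 <- quantile(wm, 0.99)
  top <- wm >= q99
  expect_gt(mean(border[top] > 1), 0.9)
  # everywhere at least the minimum class weight, and finite
  expect_true(all(is.finite(wm)))
  expect_true(all(wm >= min(cw) - 1e-12))
  # missing class weight is an error
  expect_error(compute_weight_map(s$labels, cw[1:5], params), "missing")
})

test_that("mirroring the label map mirrors the weight map", {
  s <- leg64()
  cw <- class_frequency_weights(list(s$labels), 7)
  wm <- compute_weight_map(s$labels, cw, weight_map_params(10, 8))
  wm_m <- compute_weight_map(s$labels[, 64:1], cw, weight_map_params(10, 8))
  expect_equal(wm_m, wm[, 64:1], tolerance = 1e-12)
})
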