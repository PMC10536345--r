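test_that("extract_patch returns the neighborhood with mirror borders", {
  const <- image_volume(matrix(5, 10, 10))
  expect_equal(extract_patch(const, c(5, 5), 3), matrix(5, 3, 3))
  # corner of a 4x4 ramp: compare against direct reflected indexing
  ramp <- matrix(1:16, 4, 4)
  got <- extract_patch(ramp, c(1, 1), 3)
  want <- ramp[reflect_oracle(0:2, 4), reflect_oracle(0:2, 4)]
  expect_equal(got, want)
  got2 <- extract_patch(ramp, c(4, 4), 5)
  want2 <- ramp[reflect_oracle(2:6, 4), reflect_oracle(2:6, 4)]
  expect_equal(got2, want2)
  expect_error(extract_patch(ramp, c(2, 2), 4), "odd")
})

test_that("patch_distance is the Gaussian-weighted squared difference", {
  p <- matrix(runif(9), 3, 3)
  expect_equal(patch_distance(p, p), 0)
  expect_equal(patch_distance(matrix(3, 1, 1), matrix(5, 1, 1)), 4)
  set.seed(21)
  pa <- matrix(runif(9, 0, 255), 3, 3)
  pb <- matrix(runif(9, 0, 255), 3, 3)
  sigma_eta <- 0.75
  # explicit double loop
  acc <- 0
  for (i in 1:3) for (j in 1:3) {
    g <- exp(-((i - 2)^2 + (j - 2)^2) / (2 * sigma_eta^2))
    acc <- acc + g * (pa[i, j] - pb[i, j])^2
  }
  gsum <- sum(exp(-outer((-1:1)^2, (-1:1)^2, `+`) / (2 * sigma_eta^2)))
  expect_equal(patch_distance(pa, pb, sigma_eta), acc / gsum, tolerance = 1e-12)
  expect_error(patch_distance(pa, matrix(0, 2, 2)), "shape")
})

test_that("sigma_eta = Inf recovers the plain (uniform) L2 norm", {
  set.seed(22)
  pa <- matrix(runif(25), 5, 5); pb <- matrix(runif(25), 5, 5)
  expect_equal(patch_distance(pa, pb, Inf), mean((pa - pb)^2))
})

test_that("compute_weight follows the exponential kernel exactly", {
  expect_equal(compute_weight(0, 3), 1)
  expect_equal(compute_weight(1, 1), exp(-1))
  for (h in c(0.5, 3, 17)) expect_equal(compute_weight(h^2, h), exp(-1))
  expect_error(compute_weight(1, 0), "h")
  expect_error(compute_weight(-1, 1), ">= 0")
})

test_that("pixel weights are in [0,1], self-weight maximal, normalized sum 1", {
  set.seed(23)
  img <- matrix(runif(144, 0, 255), 12, 12)
  pw <- pixel_weights(img, c(6, 6), filter_params(h = 10, patch_size = 3, search_size = 5))
  expect_true(all(pw$weights > 0 & pw$weights <= 1))
  expect_equal(max(pw$relative), 1)
  expect_equal(pw$weights[3, 3], max(pw$weights))  # center = self
  expect_equal(sum(pw$normalized), 1, tolerance = 1e-10)
})

test_that("weighted_average equals the quadruple-loop oracle", {
  set.seed(24)
  for (rep in 1:2) {
    x <- rand_img(8)
    p <- filter_params(h = 3, patch_size = 3, search_size = 5)
    expect_equal(weighted_average(x, p), brute_nlm(x, 3, 5, 3, p$sigma_eta),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("filtering a constant image returns it exactly", {
  v <- image_volume(matrix(42, 16, 16))
  out <- weighted_average(v, filter_params(patch_size = 3, search_size = 7))
  expect_equal(out$data, v$data, tolerance = 0)
})

test_that("output is a convex combination of input intensities", {
  set.seed(25)
  x <- rand_img(20)
  out <- weighted_average(x, filter_params(h = 20, patch_size = 3, search_size = 9))
  expect_gte(min(out), min(x))
  expect_lte(max(out), max(x))
})

test_that("filtering commutes with left-right mirroring", {
  set.seed(26)
  x <- rand_img(16)
  p <- filter_params(h = 5, patch_size = 3, search_size = 7)
  mirrored <- x[, ncol(x):1]
  a <- weighted_average(mirrored, p)
  b <- weighted_average(x, p)[, ncol(x):1]
  expect_equal(a, b, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("h limits: identity as h -> 0, window mean as h -> Inf", {
  set.seed(27)
  x <- rand_img(12)
  p_small <- filter_params(h = 1e-4, patch_size = 3, search_size = 5)
  expect_equal(weighted_average(x, p_small), x, tolerance = 1e-6, ignore_attr = TRUE)
  p_big <- filter_params(h = 1e9, patch_size = 3, search_size = 5)
  # all weights -> 1: uniform mean over the mirrored search window
  want <- brute_nlm(x, 3, 5, 1e9, p_big$sigma_eta)
  got <- weighted_average(x, p_big)
  expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
  # and interior pixels equal the plain 5x5 box mean
  i <- 6; j <- 6
  expect_equal(got[i, j], mean(x[(i - 2):(i + 2), (j - 2):(j + 2)]), tolerance = 1e-6)
})

test_that("parameter validation and window/image size guard", {
  expect_error(filter_params(h = 0), "h")
  expect_error(filter_params(patch_size = 4), "odd")
  expect_error(filter_params(patch_size = 9, search_size = 7), "<=")
  expect_error(weighted_average(rand_img(8), filter_params(search_size = 21)),
               "larger than image")
})

test_that("instrumented visit count equals pixels x window x patch area", {
  x <- rand_img(10)
  out <- weighted_average(x, filter_params(patch_size = 3, search_size = 5))
  expect_equal(attr(out, "pixel_visits"), 100 * 25 * 9)
})
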