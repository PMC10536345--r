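test_that("metric constants derive from K1, K2 and the dynamic range", {
  p <- metric_params()
  expect_equal(p$C1, 6.5025)
  expect_equal(p$C2, 58.5225)
  expect_equal(p$max_i, 255)
  expect_error(metric_params(L = 0), "L")
  expect_error(metric_params(ssim_window = 8), "odd")
})

test_that("ssim is 1 on identical images and symmetric", {
  x <- rand_img(32, seed = 51)
  y <- pmin(pmax(x + rnorm(length(x), 0, 10), 0), 255)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_error(ssim(x, rand_img(16)), "shape")
})

test_that("global-mode ssim matches the closed form on constant images", {
  p <- metric_params()
  a <- image_volume(matrix(100, 16, 16))
  b <- image_volume(matrix(150, 16, 16))
  want <- (2 * 100 * 150 + p$C1) / (100^2 + 150^2 + p$C1)  # contrast factor = 1
  expect_equal(ssim(a, b, mode = "global"), want, tolerance = 1e-12)
})

test_that("local ssim matches an explicit windowed-loop reference", {
  set.seed(52)
  for (rep in 1:3) {
    a <- rand_img(24)
    b <- pmin(pmax(a + rnorm(length(a), 0, 15), 0), 255)
    expect_equal(ssim(a, b), ssim_loop(a, b), tolerance = 1e-6)
  }
})

test_that("psnr follows 10*log10(MAX^2/MSE) with an infinity sentinel", {
  x <- rand_img(16, seed = 53)
  expect_equal(psnr(x, x), Inf)
  expect_equal(psnr(x, x + 1), 48.1308, tolerance = 1e-4)
  expect_equal(psnr(x, x + 255), 0)
  y <- pmin(pmax(x + rnorm(length(x), 0, 12), 0), 255)
  expect_equal(psnr(x, y), psnr_ref(x, y), tolerance = 1e-10)
})

test_that("rmse is the root mean squared difference", {
  expect_equal(rmse(matrix(0, 1, 2), matrix(c(3, 4), 1, 2)), sqrt(25 / 2))
  x <- rand_img(16, seed = 54); y <- rand_img(16)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, y), rmse(y, x))
  expect_equal(rmse(x, y)^2, mean((x - y)^2))
})

test_that("gradient magnitude is zero on constants and matches a loop oracle", {
  expect_true(all(gradient_magnitude(matrix(9, 16, 16)) == 0))
  # pure ramp along one axis: the orthogonal response is 0 in the interior,
  # so the magnitude equals the absolute single-axis Scharr response (2 per
  # unit slope with the /16 normalization)
  ramp <- matrix(rep(1:16, times = 16), 16, 16)  # unit slope along rows
  g <- gradient_magnitude(ramp)
  expect_true(all(abs(g[2:15, 2:15] - 2) < 1e-10))
  # random image: interior equals an explicit mask loop (the Scharr masks are
  # 180-degree antisymmetric, so the magnitude is the same for correlation
  # and convolution)
  set.seed(55)
  x <- rand_img(7)
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  manual <- matrix(0, 7, 7)
  for (i in 2:6) for (j in 2:6) {
    hx <- sum(kx * x[i + (-1):1, j + (-1):1])
    vy <- sum(t(kx) * x[i + (-1):1, j + (-1):1])
    manual[i, j] <- sqrt(hx^2 + vy^2)
  }
  got <- gradient_magnitude(x)
  expect_equal(got[2:6, 2:6], manual[2:6, 2:6], tolerance = 1e-10)
})

test_that("phase congruency is brightness invariant and vanishes on constants", {
  img <- matrix(0, 64, 64); img[, 33:64] <- 180
  pc <- phase_congruency(img)
  for (cshift in c(10, 50))
    expect_lt(max(abs(phase_congruency(img + cshift) - pc)), 1e-6)
  expect_equal(max(phase_congruency(matrix(7, 64, 64))), 0)
})

test_that("phase congruency peaks on a step edge", {
  img <- matrix(0, 64, 64); img[, 33:64] <- 200
  pc <- phase_congruency(img)
  edge <- mean(pc[16:48, 32:33])
  flat <- mean(pc[16:48, c(8:12, 52:56)])
  expect_gt(edge, 2 * flat)
  # columnwise profile peaks at the edge
  prof <- colMeans(pc[16:48, 8:56])
  expect_true(which.max(prof) %in% c(25, 26))  # columns 32-33 within the window
  expect_error(phase_congruency(matrix(1, 16, 16)), "filter support")
})

test_that("fsim is 1 on identical or brightness-shifted images", {
  ph <- phantom_slice(seed = 5, size = 64)
  expect_equal(fsim(ph, ph), 1)
  shifted <- get_slice(ph) + 20
  expect_equal(fsim(get_slice(ph), shifted), 1, tolerance = 1e-6)
  expect_error(fsim(get_slice(ph), rand_img(32)), "shape")
})

test_that("fsim decreases as Gaussian noise rises from 3% to 17%", {
  ph <- phantom_slice(seed = 6, size = 64)
  levels <- c(3, 5, 7, 11, 13, 15, 17)
  means <- sapply(levels, function(lv) {
    mean(sapply(1:5, function(s)
      fsim(ph, add_gaussian(ph, noise_spec("gaussian", lv, seed = s)))))
  })
  expect_true(all(diff(means) < 0))
})

test_that("quality_report bundles all metrics with a per-slice breakdown", {
  set.seed(57)
  vol <- image_volume(array(runif(2 * 64 * 64, 0, 255), dim = c(2, 64, 64)))
  noisy <- add_gaussian(vol, noise_spec("gaussian", 5, seed = 1))
  qr <- quality_report(vol, noisy)
  expect_s3_class(qr, "quality_report")
  expect_true(qr$ssim >= -1 && qr$ssim <= 1)
  expect_true(qr$fsim >= 0 && qr$fsim <= 1)
  expect_gte(qr$rmse, 0)
  expect_equal(nrow(qr$per_slice), 2)
  expect_equal(mean(qr$per_slice$ssim), qr$ssim, tolerance = 1e-12)
})
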