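test_that("constant images have all-zero detail coefficients", {
  v <- matrix(11, 32, 32)
  for (b in c("haar", "db2", "db4")) {
    co <- wavelet_decompose(v, b, 2)
    for (l in 1:2) for (band in co$details[[l]])
      expect_lt(max(abs(band)), 1e-10)
  }
})

test_that("2x2 Haar transform equals the hand-computed butterfly", {
  a <- 1; b <- 2; c <- 3; d <- 4
  co <- wavelet_decompose(matrix(c(a, c, b, d), 2, 2), "haar", 1)
  expect_equal(as.vector(co$approx), (a + b + c + d) / 2)
  expect_equal(as.vector(co$details[[1]]$v), (a - b + c - d) / 2)
  expect_equal(as.vector(co$details[[1]]$h), (a + b - c - d) / 2)
  expect_equal(as.vector(co$details[[1]]$d), (a - b - c + d) / 2)
  # inverse butterfly after thresholding with tau = 0.5
  th <- soft_threshold(co, threshold_spec(0.5))
  rec <- wavelet_reconstruct(th)
  # hand inverse: x = A/2 +- H/2 +- V/2 +- D/2 with shrunken details
  A <- (a + b + c + d) / 2
  H <- sign((a + b - c - d) / 2) * max(abs((a + b - c - d) / 2) - 0.5, 0)
  V <- sign((a - b + c - d) / 2) * max(abs((a - b + c - d) / 2) - 0.5, 0)
  D <- sign((a - b - c + d) / 2) * max(abs((a - b - c + d) / 2) - 0.5, 0)
  want <- matrix(c(A + H + V + D, A - H + V - D, A + H - V - D, A - H - V + D) / 2, 2, 2)
  expect_equal(rec, want, tolerance = 1e-12)
})

test_that("decompose/reconstruct is a perfect-reconstruction pair", {
  set.seed(31)
  for (b in c("haar", "db4")) for (lev in 1:2) {
    x <- rand_img(32, 64)
    co <- wavelet_decompose(x, b, lev)
    expect_lt(max(abs(wavelet_reconstruct(co) - x)), 1e-8)
  }
})

test_that("level limit is enforced with an informative maximum", {
  expect_error(wavelet_decompose(rand_img(16), "db4", 5), "at most 2")
  expect_error(wavelet_decompose(rand_img(6), "db4", 1), "at most 0")
  expect_error(wavelet_decompose(rand_img(8), "haar", 0), ">= 1")
})

test_that("compute_tau implements the mean-intensity threshold rule", {
  expect_equal(compute_tau(matrix(0, 8, 8))$tau, 0)
  expect_equal(compute_tau(matrix(100, 8, 8))$tau, 0.5)
  expect_equal(compute_tau(matrix(100, 8, 8), tau_factor = 0.01)$tau, 1)
  expect_equal(compute_tau(matrix(100, 8, 8))$softness, 0)
  expect_error(compute_tau(matrix(numeric(0), 0, 0)), "empty")
  expect_error(compute_tau(matrix(1, 2, 2), tau_factor = 0), "> 0")
})

test_that("soft thresholding follows the shrinkage law exactly", {
  sp <- function(tau) threshold_spec(tau)
  co <- wavelet_decompose(rand_img(16, seed = 32), "haar", 1)
  co$details[[1]]$h[1, 1] <- 0.5
  co$details[[1]]$h[1, 2] <- -3
  th <- soft_threshold(co, sp(1))
  expect_equal(th$details[[1]]$h[1, 1], 0)
  expect_equal(th$details[[1]]$h[1, 2], -2)
  # full-array agreement with the scalar oracle
  set.seed(33)
  w <- matrix(rnorm(400, 0, 2), 20, 20)
  co2 <- wavelet_decompose(rand_img(16), "haar", 1)
  co2$details[[1]]$h <- w
  tau <- 1.3
  out <- soft_threshold(co2, sp(tau))$details[[1]]$h
  expect_identical(as.vector(out), soft_oracle(as.vector(w), tau))
  # approximation band untouched
  expect_identical(soft_threshold(co2, sp(100))$approx, co2$approx)
})

test_that("thresholding contracts energy and is monotone in tau", {
  set.seed(34)
  co <- wavelet_decompose(rand_img(32), "db4", 2)
  nrg <- function(c) sum(unlist(c$details)^2) + sum(c$approx^2)
  prev <- co
  for (tau in c(0, 1, 5, 20)) {
    cur <- soft_threshold(co, threshold_spec(tau))
    expect_lte(nrg(cur), nrg(co))
    expect_true(all(abs(unlist(cur$details)) <= abs(unlist(prev$details)) + 1e-12))
    prev <- cur
  }
})

test_that("tau = 0 makes the wavelet stage an identity", {
  x <- rand_img(32, seed = 35)
  co <- soft_threshold(wavelet_decompose(x, "db4", 2), threshold_spec(0))
  expect_lt(max(abs(wavelet_reconstruct(co) - x)), 1e-8)
})

test_that("zeroing all details reconstructs the pure approximation image", {
  x <- rand_img(32, seed = 36)
  co <- wavelet_decompose(x, "db4", 2)
  z1 <- soft_threshold(co, threshold_spec(1e12))  # tau -> Inf limit
  z2 <- co
  for (l in 1:2) z2$details[[l]] <- lapply(z2$details[[l]], function(m) m * 0)
  expect_equal(wavelet_reconstruct(z1), wavelet_reconstruct(z2), tolerance = 1e-12)
})

test_that("tampered subband shapes are rejected", {
  co <- wavelet_decompose(rand_img(16), "haar", 1)
  co$details[[1]]$h <- co$details[[1]]$h[1:4, 1:4]
  expect_error(wavelet_reconstruct(co), "inconsistent")
})

test_that("thresholding sparsifies noisy detail bands, more so for larger tau", {
  ph <- phantom_slice(seed = 3, size = 64)
  noisy <- add_gaussian(ph, noise_spec("gaussian", 5, seed = 44))
  co <- wavelet_decompose(get_slice(noisy), "db4", 2)
  frac_zero <- function(c) mean(unlist(c$details) == 0)
  f1 <- frac_zero(soft_threshold(co, threshold_spec(0.5)))
  f2 <- frac_zero(soft_threshold(co, threshold_spec(2)))
  f3 <- frac_zero(soft_threshold(co, threshold_spec(8)))
  expect_gt(f1, 0)
  expect_lt(f1, f2)
  expect_lt(f2, f3)
})

test_that("threshold_spec validates its fields", {
  expect_error(threshold_spec(-1), ">= 0")
  expect_error(threshold_spec(1, softness = 2), "softness")
  expect_silent(threshold_spec(0))
})
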