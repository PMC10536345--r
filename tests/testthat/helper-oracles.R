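## Independent oracles used across the suite. These deliberately re-derive
## results with plain loops and closed forms, sharing no code path with the
## package internals they check.

## Symmetric (mirror, edge-inclusive) reflection by direct search
reflect_oracle <- function(i, n) {
  seq_full <- c(seq_len(n), rev(seq_len(n)))
  seq_full[((i - 1) %% (2 * n)) + 1]
}

## Quadruple-loop similarity filter: for every pixel, compare its patch to
## every candidate patch in the search window and average with exponential
## weights. Mirror borders.
brute_nlm <- function(x, patch, search, h, sigma_eta) {
  n <- nrow(x); m <- ncol(x)
  pr <- (patch - 1) / 2; sr <- (search - 1) / 2
  off <- seq(-pr, pr)
  g <- if (is.infinite(sigma_eta)) matrix(1 / patch^2, patch, patch)
       else {
         gg <- exp(-outer(off^2, off^2, `+`) / (2 * sigma_eta^2))
         gg / sum(gg)
       }
  grab <- function(i, j) x[reflect_oracle(i + off, n), reflect_oracle(j + off, m)]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pa <- grab(i, j)
    acc <- 0; Z <- 0
    for (di in -sr:sr) for (dj in -sr:sr) {
      pb <- grab(i + di, j + dj)
      w <- exp(-sum(g * (pa - pb)^2) / h^2)
      acc <- acc + w * x[reflect_oracle(i + di, n), reflect_oracle(j + dj, m)]
      Z <- Z + w
    }
    out[i, j] <- acc / Z
  }
  out
}

## Elementwise scalar soft-threshold rule
soft_oracle <- function(w, tau) {
  vapply(w, function(v) if (abs(v) < tau) 0 else sign(v) * (abs(v) - tau),
         numeric(1))
}

## Windowed SSIM by explicit per-pixel patch loops (replicate borders)
ssim_loop <- function(a, b, p = metric_params()) {
  w <- (p$ssim_window - 1) / 2
  off <- seq(-w, w)
  g <- exp(-outer(off^2, off^2, `+`) / (2 * p$ssim_sigma^2))
  g <- g / sum(g)
  n <- nrow(a); m <- ncol(a)
  clamp <- function(i, k) pmin(pmax(i, 1), k)
  vals <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ri <- clamp(i + off, n); ci <- clamp(j + off, m)
    pa <- a[ri, ci]; pb <- b[ri, ci]
    mx <- sum(g * pa); my <- sum(g * pb)
    vx <- sum(g * pa^2) - mx^2; vy <- sum(g * pb^2) - my^2
    cxy <- sum(g * pa * pb) - mx * my
    vals[i, j] <- ((2 * mx * my + p$C1) * (2 * cxy + p$C2)) /
      ((mx^2 + my^2 + p$C1) * (vx + vy + p$C2))
  }
  mean(vals)
}

## PSNR from its definition, written independently
psnr_ref <- function(a, b, peak = 255) {
  mse <- sum((a - b)^2) / length(a)
  20 * log10(peak) - 10 * log10(mse)
}

## Small random test image on [0, 255]
rand_img <- function(n, m = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * m, 0, 255), n, m)
}

## Total variation (anisotropic) of a 2-D image
total_variation <- function(m) {
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}
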