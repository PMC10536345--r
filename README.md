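# pixsimwave

Denoising of magnitude MR images (NIfTI volumes or 2-D grayscale images) by
**regularized neighborhood pixel similarity** followed by **wavelet soft
thresholding** — with everything needed to evaluate the method without
external data: calibrated Gaussian/Rician noise simulators, full-reference
quality metrics (SSIM, PSNR, RMSE, FSIM), and a seeded synthetic brain
phantom.

## Who this is for

Researchers preprocessing MRI before segmentation/classification, and anyone
studying patch-based denoising: the package exposes each stage (patch
extraction, patch distances, exponential weights, wavelet subbands,
thresholds) as a tested, documented function rather than a black box.

## The algorithm

Each 2-D slice is processed in two passes:

1. **Similarity filtering.** Every pixel y is replaced by a convex
   combination of the pixels x in its search window Ω(y):

       f̂(y) = Σ_{x∈Ω(y)} w(x,y) g(x) / Σ_{x∈Ω(y)} w(x,y),
       w(x,y) = exp( −‖P_a − P_b‖²_{2,η} / h² )

   where ‖·‖²_{2,η} is a Gaussian-weighted (std η) squared difference
   between the patches around y and x. Defaults: h = 3, 7×7 patches,
   21×21 search window, mirror borders.

2. **Wavelet thresholding.** The filtered slice is decomposed with an
   orthonormal 2-D wavelet transform (db4, 2 levels), detail coefficients
   are soft-thresholded,

       Ŵ = sgn(W)·(|W| − τ)  if |W| ≥ τ,  else 0,
       τ  = 0.005 × mean(f̂),

   and the slice is rebuilt by the exact inverse transform (approximation
   band untouched), then clipped to [0, 255].

Noise levels follow the BrainWeb convention: p% noise means
σ = p/100 × 255. Gaussian noise is additive; Rician noise is the magnitude
model √((I+n₁)² + n₂²).

## Worked example

```r
library(pixsimwave)

clean <- phantom_slice(seed = 1)                        # 256 x 256, [0, 255]
noisy <- add_noise(clean, noise_spec("rician", 5, seed = 42))
fit   <- pixsimwave(noisy)                              # default pipeline
print(fit)
#> PixSimWave denoising fit
#>   input:  256 x 256  | slices: 1
#>   filter: h = 3, patch 7, search 21 | wavelet db4 x2 | tau_factor 0.005
#>   threshold tau: 0.6334 .. 0.6334

quality_report(clean, noisy,       with_fsim = FALSE)
#> <quality_report>
#>   SSIM: 0.4268   PSNR: 26.24 dB   RMSE: 12.4329   FSIM: -
quality_report(clean, fitted(fit), with_fsim = FALSE)
#> <quality_report>
#>   SSIM: 0.4457   PSNR: 26.52 dB   RMSE: 12.0399   FSIM: -
```

The threshold τ ≈ 0.63 is 0.005 times the mean filtered intensity. Denoising
raises SSIM and PSNR and lowers RMSE against the clean reference; with the
reference parameters (h = 3) the pipeline is deliberately conservative —
gains are largest at low noise and always positive across 3–17% for both
noise models (this is asserted by the acceptance tests). See the methods
vignette (`vignettes/pixsimwave-methods.Rmd`) for why, and for the knobs
(`h`, `tau_factor`) that trade smoothing strength for feature preservation.

A full noise sweep reproducing a comparison-table layout:

```r
res <- run_experiment(clean, models = c("gaussian", "rician"),
                      levels = c(3, 5, 7, 11, 13, 15, 17), seeds = 1:10)
aggregate(cbind(ssim, psnr) ~ model + level, res, mean)
```

## Command line

```sh
Rscript inst/cli/pixsimwave.R phantom --shape 8,256,256 --seed 1 phantom.nii.gz
Rscript inst/cli/pixsimwave.R noisegen --model gaussian --level 5 --seed 42 phantom.nii.gz noisy.nii.gz
Rscript inst/cli/pixsimwave.R denoise noisy.nii.gz denoised.nii.gz
Rscript inst/cli/pixsimwave.R metrics --reference phantom.nii.gz --test denoised.nii.gz --report report.json
```

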