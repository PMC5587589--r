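# pwlsfr

Statistical iterative reconstruction for sparse-view and limited-angle
fan-beam CT, with a feature-refinement step that restores the fine detail
total-variation regularization tends to erase.

## The problem and the method

Reducing CT dose by acquiring fewer projection views, or a restricted
angular arc, leaves filtered back-projection (FBP) with severe streak
artifacts. Iterative reconstruction with a total-variation (TV) penalty
suppresses the streaks but, because TV assumes piecewise-constant images,
it also flattens small low-contrast structure into "patchy" artifacts.

`pwlsfr` implements **PWLS-TV-FR**: penalized weighted least squares with
TV regularization, refined after every iteration by a structure
descriptor. Given log-transformed line integrals `y`, the system operator
`G` (exact-transpose Siddon projector pair), and per-ray variance
estimates on the diagonal of `Σ`, each iteration performs the
steepest-descent update

    μ⁽ⁿ⁺¹⁾ = μⁿ − τⁿ H − β_step ∇TV(μⁿ),     H = Gᵀ(Σ⁻¹(Gμⁿ − y))

with the exact line-search step `τⁿ = HᵀH / (GH)ᵀΣ⁻¹(GH)`, and then a
feature-refinement (FR) blend

    μ_new = P[ μ⁽ⁿ⁺¹⁾ + f_t ⊗ (μⁿ − μ⁽ⁿ⁺¹⁾) ]

where `P` clamps negatives to zero and `f_t ∈ [0,1]` is an SSIM-style
per-pixel structure map, `f_t = 1 − |(2σ_qp + C)/(σ_p² + σ_q² + C)|`,
computed from 3×3 patch statistics of the fresh iterate and its
Gaussian-blurred copy. Flat regions get `f_t ≈ 0` (keep the TV-smoothed
value); detail that blurring destroys gets `f_t → 1` (restore it from the
residual). FBP provides the initial image and the comparison baseline.

The package also ships the surrounding machinery: fan-beam scan-geometry
presets (curved equiangular and flat detectors), an ellipse-phantom
simulator with closed-form sinograms, a Poisson transmission noise model
producing the variance map `Σ` needs, equiangular/flat fan-beam FBP,
RMSE/PSNR evaluation, plain-text sinogram and TIFF image I/O, and a
command-line interface.

## Worked example

A low-dose sparse-view scan of the built-in head phantom — 120 views over
360°, 672 detector bins, Poisson noise at 10⁵ incident photons per ray —
reconstructed on a 128×128 grid:

```r
library(pwlsfr)
geom    <- makeGeometry("xcat_sparse")        # 120 views / 360 deg, 672 bins
grid    <- defaultGrid(geom, 128)             # FOV inscribes the fan
phantom <- makeHeadPhantom(grid, "head")
clean   <- analyticSinogram(phantom$phantom, geom)
noisy   <- addTransmissionNoise(clean, noiseModel(I0 = 1e5, seed = 7))

fit <- reconstruct(noisy$sinogram, noisy$weights,
                   reconConfig(method = "pwls-tv-fr", grid = grid,
                               maxIterations = 50),
                   muTrue = phantom$image)
fit$image
#> AttenuationImage: 128 x 128, range [0, 0.02116] mm^-1
cat(sprintf("iterations: %d  RMSE: %.3e mm^-1  PSNR: %.2f dB\n",
            fit$iterations, fit$rmse, fit$psnr))
#> iterations: 50  RMSE: 4.675e-04 mm^-1  PSNR: 32.18 dB

baseline <- reconstruct(noisy$sinogram, NULL,
                        reconConfig(method = "fbp", grid = grid),
                        muTrue = phantom$image)
cat(sprintf("FBP baseline RMSE: %.3e mm^-1  PSNR: %.2f dB\n",
            baseline$rmse, baseline$psnr))
#> FBP baseline RMSE: 1.888e-03 mm^-1  PSNR: 20.05 dB
```

The feature-refined reconstruction cuts the FBP baseline's RMSE by a
factor of four on this scan (4.7e-4 vs 1.9e-3 mm⁻¹, +12 dB PSNR); running
the same configuration with `method = "pwls-tv"` lands in between, which
is the point of the FR step. `fit$history` holds the per-iteration step
size, weighted data cost, TV value and metrics:

```r
tail(fit$history[, c("n", "tau", "wlsCost", "rmse", "psnr")], 3)
#>     n          tau wlsCost         rmse     psnr
#> 48 48 8.138560e-11 1264185 0.0004683379 32.16362
#> 49 49 8.202223e-11 1259682 0.0004678805 32.17211
#> 50 50 8.267377e-11 1255348 0.0004674859 32.17944
```

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/scripts/pwlsfr`): `simulate`, `reconstruct` and `evaluate`
subcommands; see `?runCli`.

See the vignette (`vignettes/pwls-tv-fr-methods.Rmd`) for the model,
parameter meanings and defaults, the simulator's assumptions, and the
numerical design choices.

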