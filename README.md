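# t2relax

Estimation of mono-exponential decay parameters from multi-echo magnitude
image series — the processing step behind quantitative T2 mapping and
related relaxometry/diffusion measurements — with a focus on behaviour at
low signal-to-noise ratio, where magnitude (Rician) noise makes standard
least-squares fitting overestimate the time constant.

The package is aimed at quantitative-MRI researchers who want to compare
conventional pixelwise curve fitting with neural-network estimators trained
on physics-based synthetic data, on equal footing and with known ground
truth.

## What it implements

The signal model is `S(eta) = S0 * exp(-eta / T)`, with the sampling
dimension normalized by the longest echo time (`eta = TE / TE_max`,
`T = T2 / TE_max`). Around it:

* **Synthetic data generation** (`build_synthetic_dataset`): 128×128 maps
  with `S0 ∈ [0, 1]`, `T ∈ [0.045, 4]`, per-series complex-Gaussian noise
  `sigma ~ U[0.001, 0.1]` followed by a magnitude operation (Rician noise),
  on the ten-echo grid `eta = k/11, k = 2..11`. Ground-truth maps come
  either from a corpus of grayscale images (naturalistic spatial
  correlation; a procedural corpus generator is included so nothing needs
  downloading) or from i.i.d. uniform pixels (`urand`), which removes
  spatial correlation and isolates the contribution of learned spatial
  priors.
* **Four curve fitters**: log-linear OLS (`fit_loglin`), unbounded
  Levenberg–Marquardt (`fit_nlls`), bounded LM with `S0 ∈ [0, 1000]`,
  `1/T ∈ [0.25, 22]` (`fit_nlls_bound`), and a three-parameter fit against
  the *expectation of the Rice distribution*
  `E[M] = sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / 2 sigma^2)`
  (`fit_nlls_rice`), all vectorized across pixels.
* **Two neural estimators**: a per-pixel dense network (17,474 parameters)
  and a residual U-Net (widths [128, 128, 256, 512]; 6,950,457 parameters,
  i.e. the reported 6.9 M), trained supervised with MSE loss and AdamW on
  the synthetic data (`build_nn1d`, `build_cnn`, `train_model`,
  `predict_map`). The whole stack, including the convolution kernels, is
  implemented in the package (R + compiled code) and gradient-checked.
* **Evaluation harness**: per-slice bias / precision / accuracy (median
  signed error, IQR, median absolute error), SSIM, 100-bin SNR- and
  T-resolved error surfaces (`summarize_errors`, `ssim_score`,
  `bin_errors`), and a noise-addition robustness experiment
  (`noise_addition_experiment`) for data without ground truth.
* **I/O and CLI**: NIfTI series/maps with JSON echo-time sidecars,
  dataset containers with manifests, physical-unit conversion
  (`physical_t_bounds`: the default training range corresponds to
  6.6–580.8 ms for an 11-echo 13.2–145.2 ms acquisition), and a thin
  command-line front end (`inst/cli/t2relax.R`) with
  `synth | fit | train | predict | eval | noise-exp` subcommands.

## Worked example

```r
library(t2relax)

corpus <- procedural_corpus(8, size = 64, seed = 1)
ds <- build_synthetic_dataset(
  synth_config(4, size = 64, mode = "corpus", seed = 2), corpus)
rec <- ds$records[[1]]

round(rec$sigma, 4)
#> [1] 0.0193

fits <- list(FIT_LOGLIN     = fit_loglin(rec$series),
             FIT_NLLS       = fit_nlls(rec$series),
             FIT_NLLS_BOUND = fit_nlls_bound(rec$series),
             FIT_NLLS_RICE  = fit_nlls_rice(rec$series))
for (nm in names(fits)) {
  s <- summarize_errors(fits[[nm]]$map, rec$truth)
  cat(sprintf("%-15s bias % .4f  precision %.4f  accuracy %.4f  ssim %.3f\n",
              nm, s$bias, s$precision, s$accuracy, s$ssim))
}
#> FIT_LOGLIN      bias -0.0015  precision 0.4503  accuracy 0.2249  ssim 0.322
#> FIT_NLLS        bias  0.0029  precision 0.4307  accuracy 0.2125  ssim 0.332
#> FIT_NLLS_BOUND  bias  0.0039  precision 0.4328  accuracy 0.2124  ssim 0.371
#> FIT_NLLS_RICE   bias -0.3140  precision 1.0141  accuracy 0.4779  ssim 0.126
```

The numbers are in normalized time units (multiply by `TE_max` for
milliseconds). Bias is the median signed `T` error over the slice,
precision its interquartile range, accuracy the median absolute error, and
SSIM the structural similarity between the estimated and true `T` maps.
This series has moderate noise (`sigma ≈ 0.02`); bounding the fit improves
the map structure (SSIM), while the three-parameter Rician-expectation fit
trades accuracy and precision for reduced noise-floor bias — its advantage
appears at low SNR, which the test suite probes directly.

To train and use the neural estimators (scaled-down preset shown):

```r
train <- build_synthetic_dataset(
  synth_config(250, size = 32, mode = "corpus", seed = 101),
  procedural_corpus(500, size = 32, seed = 100))
cnn <- build_cnn(channels = c(16, 16, 32, 64), seed = 7)
cnn <- train_model(cnn, train, train_config(epochs = 60, batch = 25, seed = 8))
pm <- predict_map(cnn, rec_32$series)   # maps on the training schedule
```

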