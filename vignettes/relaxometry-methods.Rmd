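---
title: "Estimating mono-exponential decay parameters: models, fitters and neural estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mono-exponential decay parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2relax)
```

## The estimation problem

Quantitative T2 mapping acquires a series of magnitude images at increasing
echo times and estimates, per pixel, the amplitude and decay constant of a
mono-exponential signal

$$S(\eta) = S_0 \exp(-\eta / T),$$

where the sampling dimension is normalized by the longest echo time,
$\eta = \mathrm{TE}/\mathrm{TE_{max}}$, so that $T = T_2/\mathrm{TE_{max}}$
is dimensionless and the same machinery applies to any mono-exponential
process (diffusion, other relaxation times). An `echo_schedule()` carries
$\eta$ and, when known, the physical echo times; the package default is the
ten-echo grid $\eta = k/11$, $k = 2\ldots11$ — an eleven-echo, equally
spaced acquisition with the first echo discarded (the first echo is the one
most contaminated by stimulated echoes, and `preprocess_series()` implements
exactly that convention for measured data).

Magnitude images have **Rician** noise: complex Gaussian noise of
per-channel standard deviation $\sigma$ followed by the magnitude operation.
At long echo times the measured signal does not decay to zero but plateaus
near $\sigma\sqrt{\pi/2}$, which is why least-squares fitting — unbiased
under Gaussian noise — systematically *overestimates* $T$ at low SNR. The
per-pixel SNR is defined over the whole echo series,

$$\mathrm{SNR_{dB}} = 20\log_{10}\!\left(\frac{\lVert S(\eta)\rVert_2}{\sigma\sqrt{N}}\right),$$

and equals $-\infty$ where $S_0 = 0$; the sentinel propagates into the
binned error analysis, where such pixels fall below every finite bin edge
and are excluded.

## Synthetic data with known ground truth

`build_synthetic_dataset()` simulates acquisitions under broad, known
conditions: $128\times128$ maps, $S_0 \in [0,1]$, $T \in [0.045, 4]$, and a
per-series noise level $\sigma \sim U[0.001, 0.1]$ (so the SNR spans
$-\infty$ to about 59 dB). Two modes differ only in where the ground-truth
maps come from:

* **corpus mode** — each record takes two distinct grayscale images as
  $S_0$ and $T$ surrogates, center-cropped and min-max scaled per image to
  the full parameter range. Natural images supply realistic spatial
  correlation and texture. The scaling is deliberately per-image (the
  alternative, corpus-global scaling, is not fixed by the reference
  description): it guarantees that every record covers the complete
  parameter range, which is what makes range-confinement arguments about
  supervised training meaningful.
* **urand mode** — every pixel of both maps is i.i.d. uniform. Spatially
  adjacent pixels share no information, so any estimator advantage that
  depends on spatial context must vanish here. The contrast between the two
  modes is the instrument that isolates the contribution of learned spatial
  priors.

Because the canonical photographic corpus is an external download, the
package ships `procedural_corpus()`: Gaussian random fields at two length
scales overlaid with piecewise-constant ellipses and rectangles, scaled to
$[0,1]$. Its images have lag-1 spatial autocorrelation above 0.5 (tested),
versus $\approx 0$ for urand maps — the property that matters for the
spatial-prior experiments. What the procedural corpus does *not* emulate is
the semantic diversity of photographs; conclusions about absolute
performance on naturalistic anatomy should not be read off these tests,
only the *orderings* between estimators, which are driven by noise handling
and spatial correlation.

Synthetic series are not re-normalized after noise addition: the global-max
normalization convention belongs to measured data (`normalize_series()`),
while synthetic records are already on the unit scale by construction.

## The four curve fitters

All fitters work per pixel on the rate parameterization $R = 1/T$ (avoiding
division by zero) and are initialized from the log-linear fit:

| method | algorithm | parameters | bounds |
|---|---|---|---|
| `fit_loglin` | OLS on $\log S$ | $S_0, R$ | none |
| `fit_nlls` | Levenberg–Marquardt | $S_0, R$ | none |
| `fit_nlls_bound` | projected LM | $S_0, R$ | $S_0\in[0,1000]$, $R\in[0.25,22]$ |
| `fit_nlls_rice` | projected LM | $S_0, R, \sigma_{Rice}$ | as above; $\sigma_{Rice}\in[0,10]$ |

Implementation notes, in order of consequence:

* The LM solver is **vectorized across pixels**: damped normal equations are
  solved in closed form ($2\times2$, or $3\times3$ by cofactors) for all
  pixels simultaneously, with per-pixel damping. A per-pixel call into a
  scalar optimizer would be hundreds of times slower at map scale; the
  vectorized solver is cross-checked in the tests against an independent
  per-curve LM implementation (`minpack.lm`) on noisy fixtures.
* Log-linear fitting clamps nonpositive samples to a machine-epsilon floor
  before the log, keeping the fit total and vectorizable; no weighting is
  applied, so the log transform's implicit up-weighting of high-signal
  points is retained, as is conventional.
* `fit_nlls_rice` minimizes the residual against the **expectation value**
  of the Rice distribution rather than a full maximum-likelihood criterion
  (per-pixel three-parameter ML on magnitude data is numerically fragile).
  `rician_mean()` uses the closed form
  $E[M] = \sigma\sqrt{\pi/2}\,L_{1/2}(-\nu^2/2\sigma^2)$ with exponentially
  scaled Bessel functions and switches to the expansion
  $\nu + \sigma^2/2\nu$ above $\nu/\sigma = 40$; the two branches agree to
  better than $10^{-7}$ at the switch. $\sigma_{Rice}$ is initialized from
  the log-linear residual RMS — the natural scale estimate available before
  any Rician fit. Its Jacobian is taken by forward differences.
* Convergence: relative step below $10^{-8}$ or 100 iterations. A pixel
  that fails to converge keeps its log-linear estimate and is flagged in
  `converged` — log-linear and unbounded NLLS behave similarly, so the
  fallback degrades gracefully rather than inventing sentinels. At an
  active bound the projected step shrinks to zero, which counts as
  converged. $t = 1/R$ is reported even at active bounds, keeping map
  semantics uniform.
* `estimate_sigma_map()` estimates $\sigma$ as the degrees-of-freedom
  corrected RMS residual of a fit ($\sqrt{SS/(n-2)}$), reproducing the
  residual-based SNR protocol used when the true noise level is unknown.

## The two neural estimators

Both networks regress $(S_0, T)$ directly and are trained supervised with
MSE loss against ground truth, AdamW (lr 0.002), and an 80/20
train/validation split; the best-validation-epoch weights are restored
after training (final weights are kept alongside).

* `build_nn1d()`: a per-pixel dense network, $10 \to 64 \to 64 \to 64 \to
  64 \to 64 \to 2$ with ReLU between weight layers and a linear head —
  17,474 trainable parameters exactly. The published description ("6 hidden
  layers with 64 weights each") is ambiguous; the printed parameter count
  pins this stack ($704 + 4\times4160 + 130$), and the count wins.
* `build_cnn()`: a residual U-Net with four resolution levels of widths
  $[128, 128, 256, 512]$, stride-2 downsampling at three stages, $3\times3$
  convolutions everywhere, two-subunit residual blocks (kernel-size
  projection shortcuts when strided, $1\times1$ when only channels change),
  batch normalization, PReLU, channel-concatenating skips, and
  transposed-convolution upsampling. The exact count at the reference spec
  is **6,950,457** (reported in the source as 6.9 M): encoder
  171,394 + 443,266 + 1,181,442, bottleneck 3,673,602, decoder
  1,032,962 + 443,138 + 4,653. No output activation is applied on either
  network — the targets are unbounded regression values, and range
  confinement is learned, not imposed.

Inputs receive no normalization beyond the series-level unit-max
convention: per-curve renormalization would destroy the $S_0$ target.
Both architectures are tied to the $\eta$ grid they were trained on;
`predict_map()` refuses a mismatched schedule rather than interpolating.

The whole stack — convolutions via im2col/GEMM in compiled code, batch
norm, PReLU, residual and skip blocks, AdamW — is implemented in the
package and verified against central finite differences through the full
U-Net graph (relative gradient error $\sim 10^{-9}$).

### Problem sizes used by the test suite

Training the reference CNN recipe is a GPU-day-scale computation. The
package therefore treats scaled-down presets as first-class study
conditions for CPU experiments, and the test suite uses: widths
$[16, 16, 32, 64]$ (112,633 parameters), 250 corpus-driven $32\times32$
training series, 60 epochs at batch 25 for the CNN; 5 epochs at batch
10,000 curves for the 1D network; 50-series held-out corpus and urand test
sets. Noise and parameter ranges are *never* scaled — they are the study
conditions. At this scale all the qualitative claims the tests assert
(orderings between estimators, bias signs, robustness trends) reproduce
with wide margins, but absolute error magnitudes are not comparable to a
fully trained reference model.

## Evaluation harness

`summarize_errors()` decomposes the per-slice signed error of a $T$ map
into **bias** (median signed error), **precision** (IQR of the signed
error) and **accuracy** (median absolute error) — medians, not means,
because unbounded fits produce heavy-tailed errors. Note that accuracy is
*not* bounded below by |bias|; medians do not nest that way.
`ssim_score()` is single-scale SSIM with a Gaussian $11\times11$ window
($\sigma = 1.5$), stability constants $(0.01L)^2, (0.03L)^2$, averaged over
positions where the window fits fully inside the map; $L$ defaults to the
$T$-range span $3.955$ so scores are comparable across slices. The
implementation reproduces a reference implementation to $10^{-6}$ on
fixtures frozen in the tests.

`bin_errors()` resolves the signed error over per-pixel SNR and true $T$:
100 equal-width bins per axis spanning the observed finite range
(half-open bins, last bin closed; the edge convention and the equal-width
choice are ours — quantile edges would be the alternative), median and IQR
per marginal bin and per joint cell, empty bins `NA`.

`noise_addition_experiment()` measures robustness on measured-style data
where no ground truth exists: each method's map on the original normalized
series is its own reference, Rician noise of $\sigma = 0.02$–$0.08$
(0.01 steps; the 0.02/0.03/0.04 subset is a natural preset) is added, and
the change $T_{\text{added noise}} - T_{\text{original}}$ is summarized
per slice. Added noise compounds in quadrature with the noise already in
the series, which the tests verify via residual-based $\sigma$ estimates.

## Degenerate inputs and numerical conventions

* All-zero series: `normalize_series()` errors; fitters return the
  flat-curve solution ($R \to 0$, i.e. $t \to \infty$ unbounded, $t = 4$ at
  the bound) without crashing.
* Constant corpus image: zero dynamic range, mapped to the range midpoint
  with a warning.
* Center cropping with odd excess takes the `floor` offset on each axis.
* Normalization is applied before cropping for measured series, so the
  post-crop maximum may fall just below 1; the `normalized` flag survives
  only if the maximum is still exactly 1.
* Seeds: every stochastic stage (corpus, dataset, noise draws, splits,
  shuffling, initialization) derives child seeds below $2^{31}$ from a
  single user seed; RNG state is always restored, so library calls never
  perturb a caller's stream.

## Known limitations

* Mono-exponential decay only; no stimulated-echo/Bloch corrections, no
  multi-exponential models, no complex- or real-valued fitting.
* The fitters' bounded variants use projection rather than a
  trust-region-reflective interior scheme; at active bounds the two agree
  on the solution but may differ in iteration path.
* Dataset containers are R-native (RDS + JSON manifest) with NIfTI
  interchange for individual series and maps.
* Models are schedule-locked by design; transferring to a different echo
  grid requires regenerating data and retraining.
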