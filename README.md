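# tomoprox

Multichannel variational image reconstruction by proximal splitting, in R.

Dynamic and spectral computed tomography, and vector-valued image
restoration generally, share one mathematical skeleton: reconstruct a
multichannel image `u` (time frames, energy bins or colour planes) from
measurements `b` by solving

```
u* = argmin_u  f(K u) + g(u)
```

with `K` a linear forward map (projector, gradient, mask, or a block of
them), `f` a data-fidelity / regularization functional and `g` a
constraint or second regularizer.  tomoprox provides that skeleton as
composable pieces for people prototyping reconstruction methods on
sparse-view, dynamic and hyperspectral problems:

* **geometries and containers** — declarative `image_geometry` /
  `acquisition_geometry`, channel-first `mc_image` / `mc_sinogram`
  arrays, `block()` product-space tuples, angle undersampling
  (`slice_angles`), Lambert–Beer conversion (`negative_log`), TIFF +
  plain-text serialization;
* **linear operators** under one direct/adjoint contract — forward
  finite-difference gradients with spatial or spatio-channel correlation,
  symmetrized gradient, masks, channelwise lifting, block composition,
  and a sparse ray-driven (Siddon) projector for parallel and fan beam,
  with power-method norms;
* **convex functions** with proximal maps — `||.-b||_1`, `0.5||.-b||^2`,
  mixed `l2,1`, Kullback–Leibler, box indicators, scaling/block
  composition, conjugate proxes via the Moreau identity, and TV /
  vectorial TV / directional TV (dTV) proxes solved by fast gradient
  projection (FGP) with warm-started duals;
* **solvers** — FISTA, PDHG (explicit and implicit), stochastic PDHG with
  uniform/balanced subset sampling and epoch accounting, SIRT (plain and
  warm-started channelwise), CGLS, and filtered back-projection with a
  Ram–Lak filter;
* **case studies** — synthetic phantom generators plus end-to-end
  pipelines for colour denoising (vectorial TV) and TGV inpainting,
  sparse-view dynamic CT (FBP / Tikhonov / TV / dTV comparison), and
  hyperspectral K-edge CT (SPDHG with coupled or split spatio-spectral
  TV), with PSNR/SSIM scoring and regularization-weight grid search.

## A worked example

Sparse-view dynamic CT on the built-in contrast-uptake phantom: 17 time
frames of a 64×64 gel disc with five cavities filling over time, scanned
at 360 angles with Gaussian noise, then undersampled 20× to 18
projections.  Each method's weight is grid-searched for mean PSNR against
the dense-angle FBP reference:

```r
library(tomoprox)
ph  <- make_dynamic_gel_phantom()          # ground truth + cavity ROIs
rep <- run_dynamic_comparison(ph, step = 20, seed = 1)
rep$mean_table
#>     method     psnr      ssim
#> 1      dtv 26.48482 0.7673841
#> 2      fbp 14.70514 0.3539415
#> 3 tikhonov 21.39790 0.5751554
#> 4       tv 25.67949 0.7373091
```

At 18 of 360 projections, channelwise FBP is dominated by streak
artefacts (14.7 dB); Tikhonov smoothing recovers 6–7 dB; spatio-temporal
TV adds edge preservation (25.7 dB); and directional TV, which imports
edge structure from pre/post-scan reference images, is best (26.5 dB) —
the qualitative ordering such comparisons report on real gel-phantom
data.  `rep$tac` holds the centre-of-cavity time-activity curves; the TV
and dTV curves track the monotone uptake while the sparse-view FBP curve
oscillates.

The hyperspectral counterpart:

```r
ph  <- make_hyperspectral_phantom()        # 80 bins, 75.15-93.37 keV
rep <- run_hyperspectral(ph, coupling = "split", alpha = 0.05, beta = 0.05,
                         S = 10, epochs = 25, noise_sigma = 0.1, seed = 1)
rep$detected_edges$spdhg
#> edge1 edge2
#>    26    57
```

Channels 26 and 57 are exactly the bins containing the gold
(80.725 keV) and lead (88.005 keV) absorption edges used to build the
phantom: the split spatio-spectral TV reconstruction preserves the
K-edge jumps through 500 balanced-sampling SPDHG iterations (25 epochs
with 10 data subsets).

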