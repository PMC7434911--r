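# mrdenoise

Compressed-sensing acceleration makes high-resolution proton-density
vessel-wall MRI clinically practical, but high acceleration factors leave
noise-like reconstruction artefacts, and the clean reference scan acquired
minutes later is never aligned pixel-by-pixel with the accelerated one — so
ordinary supervised denoising has no target to regress on. `mrdenoise`
implements, end-to-end and on synthetic vessel-wall phantoms, the two
training strategies that work without aligned pairs, plus the complete
no-reference evaluation suite needed to compare them:

* **Self-supervised U-Net** — corrupt clean images with zero-mean Gaussian
  noise `g(mu, sigma)`, with `sigma` drawn per image from 25–35% of the
  image mean (the artificial-pair construction
  `x̂ = y + g(mu, sigma)`), and minimise `sum_i L(f_theta(x̂_i), y_i)` with
  MSE over aligned patches.
* **Unsupervised CycleGAN** — two U-Net generators `G_AB`, `G_BA` and two
  convolutional discriminators trained with least-squares adversarial
  losses and an L1 cycle-consistency penalty,
  `L = L_GAN(G_AB, D_B) + L_GAN(G_BA, D_A) + lambda * L_cyclic`.
* **Evaluation** — vessel-wall SNR (peak wall signal over lumen standard
  deviation), CSF/parenchyma SNR (ROI mean over ROI sd), 5×5 blockwise
  noise maps, BRISQUE natural-scene statistics with a self-contained
  fallback scorer, 465 radiomic features (18 first-order, 75 texture over
  GLCM/GLRLM/GLSZM/NGTDM/GLDM, and the same set on four Haar wavelet
  sub-bands), and per-feature reproducibility via Lin's concordance
  correlation coefficient (CCC > 0.8 = reproducible), with paired-t and
  Kolmogorov–Smirnov statistics throughout.

The convolutional-network engine (im2col convolutions, pooling, transposed
convolutions, batch/instance normalisation, Adam, exact backpropagation) is
implemented in the package itself on RcppArmadillo; the gradient of every
layer is verified against finite differences in the test suite.

Because the clinical images this design targets are not publicly available,
the package is organised around a seeded synthetic study: a phantom
generator (`generate_phantom()`) draws brain-like slices with bright vessel
walls, dark lumina, CSF pockets, textured parenchyma and an air corner, and
every pipeline claim is computed on those phantoms. See the methods
vignette (`vignettes/methods.Rmd`) for the models, their assumptions, and
what the synthetic study does and does not establish.

## A worked example

```r
library(mrdenoise)

# a 64x64 desk-scale phantom and its regions of interest
spec <- phantom_spec(size = 64, n_vessels = 2, vessel_radii = c(4, 7),
                     n_csf = 1, csf_radii = c(4, 6), seed = 7)
ph <- generate_phantom(spec)
noisy <- add_noise(ph$image, noise_spec(seed = 1))

attr(noisy, "sigma")   # the sigma actually drawn: 27.7% of the image mean
#> [1] 16.39482

# noise calibration in the air corner, with a normality screen
est <- estimate_air_noise(noisy, ph$roi$air)
est$sigma
#> [1] 18.03157
est$normality
#> D'Agostino-Pearson: statistic = 6.841, p = 0.0327 (n = 64, alpha = 0.01) -> normal
```

The drawn corruption sigma was 16.39 (27.7% of the image mean); the
air-corner estimate of 18.0 recovers it within the sampling error of a
64-pixel box, and the normality verdict (p > 0.01) is what licenses the
Gaussian corruption model in the first place.

The full comparison study — both denoisers, all quality metrics, the
radiomic CCC analysis and the paired tests — is one call:

```r
summary <- run_experiment(experiment_config(seed = 1))
summary
#> <study_summary>
#>   input    parenchyma noise 19.111 +/- 1.778, SNR   5.26, BRISQUE  98.7
#>   selfsup  parenchyma noise  7.634 +/- 0.841, SNR  13.22, BRISQUE  96.5
#>   target   parenchyma noise  8.382 +/- 1.029, SNR  12.06, BRISQUE  51.9
#>   unsup    parenchyma noise  9.568 +/- 0.929, SNR  12.31, BRISQUE  97.9
compare_conditions(summary)
#>                                     check  pass
#> 1   denoisers beat input on noise and SNR  TRUE
#> 2            selfsup noise <= unsup noise  TRUE
#> 3 unsup improves texture and wavelet CCC FALSE
#> 4           outputs beat input on BRISQUE  TRUE
```

Reading the summary: both trained denoisers reduce parenchyma noise (by 60%
and 50%) and more than double the parenchyma SNR relative to the noisy
input, with the self-supervised output the cleaner of the two — here even
cleaner than the clean target, the signature of Noise2Noise-style training
with noisy-in-expectation targets — and both outputs improve (lower) the
BRISQUE score. Check 3 is reported failing on the phantoms: the
pixel-aligned MSE U-Net recovers the texture field per-image and therefore
beats the CycleGAN on radiomic concordance at this scale (the methods
vignette discusses why this clinical-scale finding does not transfer).
`summary$ccc` holds the full radiomic reproducibility triplet
(input/self-supervised/unsupervised, each against the clean target).

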