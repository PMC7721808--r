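# pics — phase imaging with computational specificity

Quantitative phase imaging (QPI) measures the optical path-length delay of
light through a transparent cell, which is directly proportional to its
dry-mass density — but a phase map has no chemical specificity: it cannot
say which pixels are nucleus and which are cytoplasm. `pics` closes that
gap computationally. It reconstructs quantitative phase from gradient
light interference microscopy (GLIM) acquisitions, trains a compact
residual U-Net to predict fluorescence channels (a DAPI-like nuclear stain
and a DiI-like cell-body stain) from the phase image alone, and uses the
predicted "digital stains" to gate the phase map so that nuclear and
cytoplasmic dry mass, confluence, nuclear-cytoplasmic ratio and growth
curves can be followed in live, never-stained cultures.

The package is aimed at microscopists and image-analysis developers who
want a fully inspectable, dependency-light reference implementation of
this pipeline. Everything runs on synthetic-but-physical simulations with
known ground truth, so every stage is testable without any external data.

## The models at the core

**Phase retrieval.** GLIM records four interferograms at modulator phases
$n\pi/2$:

$$I_n = I_1 + I_2 + 2\sqrt{I_1 I_2}\cos(\Delta\phi + n\pi/2),
\qquad \Delta\phi(x) = \phi(x) - \phi(x - s),$$

with $s$ the DIC shear vector. The four-step estimator
$\Delta\phi = \operatorname{atan2}(I_{3\pi/2} - I_{\pi/2}, I_0 - I_\pi)$
demodulates the shear gradient, and a regularised Fourier deconvolution of
the shear-difference transfer function $H(k) = 1 - e^{-ik\cdot s}$
integrates it back to $\phi$.

**Virtual staining.** A U-Net with batch normalisation before every
activation, feature widths at a quarter of the original schedule
(16…256), and a residual addition of the input to the final convolutional
block — about 1.9 million trainable parameters versus over 30 million for
the original widths — is trained per fluorophore with ADAM against an MSE
loss on co-registered (phase, fluorescence) pairs, and applied with a
32-pixel mirror pad to suppress border artifacts. The network and its
backpropagation are implemented in pure R on BLAS matrix products; no
deep-learning framework is required.

**Quantification.** Thresholding the predicted channels gives nucleus /
cell / cytoplasm masks; dry mass under a mask follows
$m = \frac{\lambda}{2\pi\gamma}\sum_{\text{mask}}\phi\,A_{\text{pixel}}$
(defaults $\lambda = 0.55$ µm, $\gamma = 0.2$ ml/g, giving picograms);
growth curves are normalised to the mean of the first six hours and
doubling times fitted on $\log_2$ mass.

## Worked example

```r
library(pics)

print(unet_spec())
#> <unet_spec> depth 5, widths 16-32-64-128-256, batch norm, residual

p  <- scene_params(field_size_px = c(128, 128), n_cells = 6, seed = 3,
                   noise_model = list(gaussian_sd = 0, poisson_scale = 0))
sc <- generate_scene(p)                       # ground-truth monolayer scene
fs <- simulate_glim_frames(sc, p, noiseless = TRUE)
g  <- reconstruct_gradient(fs)                # 4-frame demodulation
max(abs(g$dphi - fs$dphi_truth))
#> 4.440892e-16                               # demodulation is exact

pm <- rebase_phase(integrate_gradient(g))     # shear integration + re-zero
cor(as.vector(pm$phi), as.vector(sc$phase_truth))
#> 0.9999988                                  # faithful phase reconstruction

masks <- segment(pmin(sc$fluor_dapi, 1), pmin(sc$fluor_dil, 1))
cfg   <- dry_mass_config(pixel_size_um = p$pixel_size_um)
mass_record(pm, masks, cfg, time_h = 0, fov_id = 1)
#>   nuclear_mass_pg cyto_mass_pg total_mass_pg confluence ncr
#> 1         177.851      161.647       339.498      0.434 1.1
```

The scene covers 43% of the field with six cells; the reconstructed phase
correlates with the ground truth to five nines, and the compartment masks
split the ~339 pg of cellular dry mass into nucleus and cytoplasm (NCR
1.1 — nuclei are simulated 1.5× denser than cytoplasm).

`run_end_to_end(run_config(...))` chains the whole protocol — simulate a
growing time-lapse, train on the final stained timepoint, infer backwards,
quantify — and writes mass records, growth curves and a JSON manifest;
see the methods vignette (`vignettes/pics-methods.Rmd`) for the model
details and design decisions.

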