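---
title: "Methods: phase imaging with computational specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase imaging with computational specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pics)
```

This vignette documents the models implemented in `pics`, the assumptions
behind them, the tunable parameters, and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The imaging model

GLIM (gradient light interference microscopy) turns a DIC microscope into a
quantitative phase imager. The two orthogonally polarised beams of the
Nomarski optics are laterally displaced by a shear vector $s$ (magnitude
`shear_px` pixels, direction `shear_angle_rad` from the $+x$ axis), and a
variable retarder adds a controlled offset $n\pi/2$, $n = 0,1,2,3$, between
them. The camera records four interferograms

$$I_n(x) = I_1 + I_2 + 2\sqrt{I_1 I_2}\,
\cos\!\big(\Delta\phi(x) + n\pi/2\big),$$

where $\Delta\phi(x) = \phi(x) - \phi(x - s)$ is the *finite* shear
difference of the specimen phase $\phi$ — not the infinitesimal directional
gradient, which is only its small-shear limit. `simulate_glim_frames()`
implements exactly this model (the shear difference is applied as a Fourier
phase ramp, i.e. with periodic boundary), so the demodulator and integrator
can be validated against it in closed form.

**Demodulation.** `reconstruct_gradient()` uses the classical four-step
estimator
$$\Delta\phi = \operatorname{atan2}(I_{3\pi/2} - I_{\pi/2},\, I_0 - I_\pi),$$
the unique unbiased four-frame solution for equal $\pi/2$ steps. It is
exactly invariant to any common additive background. Pixels where all four
frames coincide carry no modulation; they are set to 0 and flagged in a
validity mask rather than propagating `atan2(0, 0)`.

**Integration.** The shear-difference operator has transfer function
$H(k) = 1 - e^{-i k \cdot s}$. `integrate_gradient()` inverts it by
regularised Fourier deconvolution,
$$\hat\phi = \mathcal{F}^{-1}\!\left[\frac{\bar H\, G}{|H|^2 +
\varepsilon^2}\right],$$
with $\varepsilon = 10^{-3}$ by default. $\varepsilon$ trades noise
amplification near the nulls of $H$ against attenuation of genuine
low-frequency content; at the default, frequencies with $|H| \gg
\varepsilon$ pass essentially unchanged (the round-trip attenuation is
$|H|^2/(|H|^2+\varepsilon^2)$). $\varepsilon \le 0$ is rejected because the
DC pole would be exposed.

Two physical facts shape the conventions here:

* The DC component is unobservable — a constant phase offset cancels in
  $\phi(x) - \phi(x-s)$ — so the returned phase is zero-mean. Absolute
  dry-mass work needs a physical zero instead; `rebase_phase()` subtracts
  the field median, which estimates the empty-substrate level whenever the
  field is sub-confluent (cells cover less than half the pixels).
* Structure that is invariant along the shear direction is equally
  unobservable: $H$ vanishes on the whole lattice line $k \cdot s \equiv 0
  \pmod{2\pi}$ whenever the shear components have a rational ratio (for
  example, a shear exactly along $x$ annihilates every purely vertical
  frequency). Real prisms are not aligned with the camera lattice, so the
  generator's default shear direction is oblique (0.5 rad); then the null
  set reduces to the DC point and the noiseless simulate–demodulate–
  integrate chain reproduces the true phase essentially exactly, which is
  what the oracle tests assert.

**Scattering display.** For thick, turbid specimens the phase dynamic
range defeats linear display; `scattering_display()` shows
$\log(|\phi| + \mathrm{floor})$, monotone in $|\phi|$ and sign-invariant,
with `floor = 1` making zero phase map to zero.

## The synthetic scene generator

No real acquisitions ship with the package, so every stage is validated on
simulated monolayers with known ground truth. `generate_scene()` places
random ellipses (mean radius 6 µm, sd 1 µm, axis ratio 0.6–1, area
preserved) with concentric nuclei at half the cell radius, rejecting any
candidate that would overlap already-placed cells by more than 50% of its
area — enough to reach the crowded-but-monolayer regime without a
biophysical contact model. Phase is a sum of unit-height paraboloid caps
scaled to 2 rad at the cell centre, plus a nuclear excess with
multiplier 1.5 (nuclei are denser than cytoplasm in QPI data), blurred by a
1-pixel Gaussian. These amplitudes are configurable defaults, not claims
about any particular cell line. Fluorescence channels are the masks, with
optional blur, Poisson shot noise (`poisson_scale` photons per intensity
unit) and Gaussian read noise — a DAPI-like channel supported on nuclei and
a DiI-like channel on cell bodies. `generate_timelapse()` keeps the
geometry of each field fixed and scales the phase by $2^{t/T_d}$, the
idealised exponential-growth regime against which the quantification stage
is checked.

What the generator does *not* emulate: optical diffraction beyond Gaussian
blur, halo artifacts, cell motility, division, debris, uneven
illumination, or 3-D scattering. Tests passing on these scenes therefore
demonstrate the correctness of the pipeline's computations, not its
performance on real acquisitions, whose correlations depend on data that
is not distributed.

## Preprocessing

**Normalization.** Images enter the network as
$$I' = \operatorname{med}\!\left(0,\ \frac{I - \rho_{\min}}
{\rho_{\max} - \rho_{\min}},\ 1\right),$$
where $\rho_{\min}, \rho_{\max}$ are the global extremes over the training
set and the pixel-wise median of $\{0, v, 1\}$ is exactly the clamp of $v$
to $[0,1]$ — which is how `normalize_image()` implements it. Ranges are
computed per modality (phase and each fluorophore separately), since their
physical units differ. A constant training set is rejected as degenerate.

**Focus scoring.** `focus_score()` takes one level of the 2-D Haar
transform and returns the detail-band energy (horizontal + vertical +
diagonal) divided by the image's AC energy. The normalisation makes the
score 0 for constants, invariant to additive offsets, and comparable
across exposure levels. The scorer is a plain function argument of
`select_in_focus()`, so other sharpness statistics can be plugged in.
Selection returns the $k = 3$ best slices (the standard training
augmentation depth); ties break toward the stack centre, where best focus
is expected a priori.

**Best-focus surface.** Multiwell plates sit slightly tilted, so the
in-focus plane varies across mosaic tiles. `interpolate_focus_surface()`
triangulates the user's focus points (Bowyer–Watson, implemented in the
package since no installed dependency provides Delaunay triangulation) and
interpolates barycentrically: exact at the focus points and exact for any
affine surface, which is the case that matters for a flat glass bottom.
Tiles outside the convex hull — routine at mosaic corners — are
extrapolated with the plane of the nearest simplex and flagged with a
warning. Collinear focus points are rejected.

## The network

The virtual-staining network is a U-Net with three modifications: batch
normalisation before every activation, feature widths at a quarter of the
original schedule (16–256 instead of 64–1024), and a residual addition of
the input to the output of the final convolutional block, so the network
learns the *difference* between phase and fluorescence. At the default
`unet_spec()` (depth 5, base width 16, one channel in and out) the model
has 1,943,761 trainable parameters, against 31,030,593 for the
original-width baseline (depth 5, widths 64–1024, no batch norm, no
residual) — counts that `count_parameters()` derives from the instantiated
weights, including batch-norm scale and shift, excluding running
statistics.

No deep-learning framework is involved: convolutions, batch norm, pooling,
up-convolutions, their backward passes, and the ADAM optimiser are
implemented in R directly on BLAS matrix products (features live in
`(N·H·W) × C` matrices; all spatial wiring is precomputed integer
indexing). The analytic gradients are verified against central finite
differences in the test suite. Training is seed-deterministic: the seed
fixes initialisation and shuffling, and two runs with the same seed
produce identical loss histories.

Design choices worth recording:

* **One network per fluorophore** (`out_channels = 1`), trained
  independently; the residual addition is only well-posed
  channel-to-channel, and multiplexing is achieved by running several
  networks on the same phase image.
* **Zero-initialised final convolution** when the residual path is on:
  the untrained model is then exactly the identity map, the natural
  starting point under the residual-learning hypothesis. (The identity is
  also reachable at zero weights of the final block, which the tests use
  as a wiring probe.)
* **Inference padding.** `infer()` mirror-pads by 32 pixels (plus
  whatever makes the size divisible by the network stride), runs the
  model, and crops back, suppressing border artifacts; padded and
  unpadded inference agree in the field interior.
* **Optimisation defaults** (`train_config()`): ADAM with learning rate
  $10^{-3}$, $\beta = (0.9, 0.999)$, batch size 4, MSE loss. These are
  conventional values recorded in the configuration object, not
  hard-coded; the best-validation checkpoint is returned when a
  validation split is requested.

**Desk-scale benchmark.** The package's virtual-staining benchmark trains
on 20 simulated 128 × 128 phase/DAPI pairs (4 held out) for 12 epochs with
a depth-3, base-width-8 spec — a few CPU-minutes — and requires a pooled
held-out Pearson correlation of at least 0.8, strictly above the
residual-identity starting point. The reduced depth/width is a deliberate
desk-scale choice: the benchmark fixes the data regime (about 20 pairs
suffice for a usable stain), not the production architecture, whose
defining property — the parameter count — is checked separately.

## Quantification

Thresholding the predicted DAPI and DiI channels (Otsu per image by
default, fixed thresholds optional), removing objects below
`min_object_px` (default 9 px), clipping the nucleus mask to the cell mask
and taking the set difference yields the nucleus / cell / cytoplasm
semantic segmentation (`segment()`); `cytoplasm == cell & !nucleus` is an
enforced invariant. Dry mass under a mask follows the standard QPI
relation
$$m = \frac{\lambda}{2\pi\gamma} \sum_{\mathrm{mask}} \phi\, A_{\rm pixel},$$
with literature defaults $\lambda = 0.55$ µm (white-light centre) and
$\gamma = 0.2$ ml/g (protein refractive increment); with these units the
result is in picograms. The relation is linear in $\phi$ and additive over
disjoint masks, so nuclear + cytoplasmic mass equals cellular mass
exactly. Confluence is the occupied-area fraction of the cell mask;
`count_cells()` counts connected components, with the documented failure
mode that touching nuclei merge.

`growth_curves()` normalises each field's series by its mean over the
first 6 hours, reports the pointwise median across fields, and estimates
doubling time by least squares on $\log_2(\text{mass})$ over time
(optionally windowed). Fitted slopes below $10^{-9}$ doublings/hour are
reported as an infinite doubling time; fields with non-positive baseline
are dropped with a warning. On the synthetic exponential time-lapse, the
end-to-end pipeline with an oracle predictor recovers the programmed
doubling time within 5% and the nuclear-cytoplasmic ratio within 10%,
which the test suite asserts.

The nuclear mass is the phase integral under the (binary) nucleus mask,
matching the mask-based construction used for the predicted-vs-chemical
comparison (`mask_mass_discrepancy()`), rather than a channel-weighted
integral.

## The end-to-end protocol

`run_end_to_end()` mirrors the two-step experimental protocol in silico:
the time-lapse is recorded label-free; the stain exists only at the final
timepoint (fixation and staining end the experiment); networks are trained
on those final-timepoint pairs; inference then runs backwards over the
whole sequence. An `"oracle"` predictor mode substitutes the ground-truth
fluorescence for the network output, isolating the quantification stage.
Runs are pure functions of (configuration, seed): re-running a
configuration reproduces its CSV outputs byte for byte.

## Problem sizes and limitations

The test suite exercises 64–256 px fields, up to 24 simulated pairs, and
2-FOV, 6-timepoint pipelines; these sizes were chosen so the full suite
runs in minutes on one CPU core while still leaving every numerical claim
non-trivial (the staining benchmark is the dominant cost). Known
limitations: the pure-R network is CPU-bound and desk-scale — it is not a
route to real-time inference; the shear model is periodic, so fields whose
content touches the border inherit a wrap-around assumption; the
background-median rebase fails above ~50% confluence, where the median
pixel is no longer substrate; and the synthetic scenes are deliberately
simple, so measured correlations do not transfer to real acquisitions.
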