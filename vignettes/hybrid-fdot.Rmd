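---
title: "Hybrid model-based and learned fDOT: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid model-based and learned fDOT: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fdot` reconstructs the spatial distribution of a fluorophore inside a
cylindrical vessel — the setting is a bench-top bioreactor whose engineered
cells report their state through fluorescence — from boundary measurements of
excitation and emission light. The method is two-step: a classic
normalized-Born inversion with Tikhonov regularization produces a fast,
artifact-prone volume, and a 3D residual encoder–decoder network trained on
simulated phantoms maps that volume to a cleaned-up estimate. This vignette
records the models, their assumptions, and the places where the design was
genuinely open and a choice had to be made.

## The light-transport model

Continuous-wave light in a highly scattering medium is modeled by coupled
diffusion equations: the excitation fluence $\Phi_x$ satisfies
$-\nabla\cdot\kappa_x\nabla\Phi_x + \mu_{ax}\Phi_x = q_0$, and the emission
fluence $\Phi_m$ satisfies the same equation at the emission wavelength with
the volumetric source $\Phi_x(\mathbf r)\,\gamma(\mathbf r)$, where
$\gamma = \eta\,\mu_{af}$ lumps the fluorophore's quantum efficiency and
absorption — the quantity the tomography reconstructs. The diffusion
coefficient is $\kappa = 1/\bigl(3(\mu_a + \mu_s')\bigr)$ and the boundary
condition is of Robin type, $\Phi + 2A\kappa\,\partial\Phi/\partial\hat\nu = 0$,
with $A$ computed from the refractive index ($n = 1.33$ by default, an aqueous
medium) through the standard internal-reflection fit
$R_\text{eff} = -1.440/n^2 + 0.710/n + 0.668 + 0.0636\,n$,
$A = (1+R_\text{eff})/(1-R_\text{eff})$. The vessel is a cylinder of 13 cm
diameter and 15 cm height.

**Discretization.** The package discretizes the cylinder directly on the
regular reconstruction grid with a voxel finite-volume scheme: 7-point flux
stencil with conductance $\kappa\,\text{area}/h$ on interior faces, the Robin
admittance $\text{area}/(2A + h/2\kappa)$ on exposed faces (half-cell
resistance in series with the boundary), and $\mu_a\,\delta V$ on the
diagonal. The operator is symmetric positive definite by construction.
Tetrahedral finite elements would be the conventional alternative; the voxel
scheme was chosen because the method's end products — Jacobian, reconstruction,
network input — all live on the regular grid anyway, and its accuracy is
certified directly against the closed-form infinite-medium Green's function
$\exp(-\mu_\text{eff} r)/(4\pi\kappa r)$: on a $\varnothing$200 mm domain the
maximum relative error for $r \in [10, 30]$ mm is below 5% at a ~2 mm voxel
pitch and decreases under refinement (both are asserted in the test suite).
A finite-element backend could be added behind `assemble_system()` without
touching anything downstream.

**Optodes.** Sources and detectors sit on the lateral surface and are
represented inside the medium at one transport mean free path $1/\mu_s'$ along
the inward normal. A point source is deposited with mask-renormalized
trilinear weights over the surrounding voxel centers, and *the same weights*
are used to read fields out at optodes and to place adjoint (detector)
sources. This shared convention makes modeled measurements exactly reciprocal
and makes the Born-linearized prediction $J\gamma$ agree with a full emission
solve to solver precision for a point-like inclusion — both are tested.

**Solvers.** Repeated solves (all sources, all detectors, every simulated
case) share one sparse Cholesky factorization; one-off large solves use
Jacobi-preconditioned conjugate gradients at a relative residual of
$10^{-10}$.

## The inverse problem

Each channel pairs one source and one detector. The Born ratio
$y_i = \hat\Phi_m(s_i, d_i)/\hat\Phi_x(s_i, d_i)$ cancels channel-wise
multiplicative systematics (coupling, gain, mirror losses). The sensitivity
of channel $i$ to voxel $j$ is
$J_{ij} = \bar\Phi_x(s_i, r_j)\, G_m(d_i, r_j)\,\delta V_j / \bar\Phi_x(s_i, d_i)$,
with the adjoint Green's function $G_m$ computed per detector. The
reconstruction solves the ridge problem
$\hat\gamma = (J^\top J + \alpha I)^{-1} J^\top y$. Because channels number
far fewer than voxels, the package solves the equivalent dual system
$J^\top(JJ^\top + \alpha I)^{-1} y$ by Cholesky (falling back to an SVD
filter-factor construction if conditioning demands it) and verifies the
normal-equations residual below $10^{-8}$; the test suite checks agreement
with an independent SVD oracle to $10^{-8}$ on random instances.

$\alpha$ is a per-regime constant, not automated: 100 for the dense simulated
layout and 1 for the sparse camera layout, matching the study design this
package reproduces. Channel selection supports three policies: none (dense
simulated regime), both amplitudes above $0.8\times$ the standard deviation of
their wavelength's amplitudes (sparse regime), and percent-of-reference-max
(18% emission / 1% excitation). "Expected max" is under-determined for
synthetic data, so the reference maximum defaults to the dataset maximum per
wavelength, with an explicit argument for a camera full-scale value. Invalid
channels are dropped (rows removed), not zero-filled.

## Synthetic phantom cases

Two generation regimes mirror the study's tables:

* **Dense simulated regime** (`sim_config_table1()`): background
  $\mu_a = 0.0089 \pm 10\%$, $\mu_s' = 1.314 \pm 10\%$ mm$^{-1}$ (equal at
  both wavelengths), 1–2 non-overlapping spheres with radii 7–15 mm, yield
  $\gamma \in [4\times10^{-4}, 4\times10^{-2}]$ mm$^{-1}$, and Gaussian noise
  added to the Born ratios with a per-case standard deviation drawn uniformly
  from 0–2% of the maximum ratio. Inversion always uses the fixed, deliberately
  mismatched properties $\mu_{ax} = 0.0089$, $\mu_{am} = 0.0062$,
  $\mu_{sx}' = 1.314$, $\mu_{sm}' = 1.274$ mm$^{-1}$ with $\alpha = 100$.
* **Sparse camera regime** (`sim_config_table2()`): $\mu_a = 0.0005 \pm 30\%$,
  $\mu_s' = 0.1 \pm 30\%$ mm$^{-1}$, 1–3 z-aligned cylinders (radii 5–10 mm,
  heights 10–30 mm), the same $\gamma$ range, and independent 0–1% noise on
  each wavelength's amplitudes, with ratios recomputed afterwards;
  $\alpha = 1$ and the 0.8-sd channel selection.

All draws are uniform. The "0–2%" noise wording is read as: one level per
case, drawn uniformly from the interval, then applied as the standard
deviation of i.i.d. Gaussian noise scaled by the maximum amplitude; the
manifest records the realized level. Whether the noise level should instead
vary per channel is not decidable from the description; per-case is assumed.
Inclusion centers are drawn uniformly over the cylinder with rejection until
full containment (one reconstruction-voxel margin, 3 mm) and pairwise
non-overlap hold; 1000 rejections abort. Each inclusion draws its own yield.
Reproducibility uses one master seed with per-case seeds derived by a counter
scheme, so any case can be regenerated in isolation.

The generator emulates the optical physics of inclusion phantoms in a
homogeneous background. It does **not** emulate continuum fluorophore
distributions, background fluorescence, camera quantization, or the manual
exclusion of distorted surface regions — so passing tests certify the
algorithmic chain, not performance on real bioreactor data.

## The denoising network

The enhancer is a 3D residual encoder–decoder (U-Net family). Per resolution
level: two 3×3×3 convolution + ReLU blocks; 2× average pooling downward;
nearest-neighbor upsampling followed by a 1×1×1 channel-mixing projection
upward; skip concatenation at matching resolutions; the deepest level gets
two extra convolutions, which widens the receptive field at 1/8th of the
fine-level cost. The final convolution is zero-initialized and a global
input→output skip makes the fresh network exactly the identity: the network
learns a *correction* to the classic reconstruction. The published figure
does not state per-level channel counts; the full preset uses 4 levels with
(16, 32, 64, 128) channels and a desk-scale preset uses 2 levels with (8, 16).
Odd extents are zero-padded symmetrically to the nearest valid size and
cropped on output.

Both inputs and targets are divided by their standard deviation over the
in-cylinder voxels (population form; no centering), which is why the
downstream IoU threshold of 1 means "one standard deviation". The loss is the
plain sum of squared differences over in-cylinder voxels only. Training uses
Adam at $10^{-3}$ (unstated in the source material; the conventional
choice), batch 16, at most 200 epochs, and early stopping when the
validation loss has not decreased for 5 consecutive epochs, restoring the
best-validation weights.

The implementation is self-contained: volumes are flattened with a one-voxel
zero pad so a 3×3×3 convolution becomes 27 constant row shifts, each a dense
BLAS `gemm` on a contiguous row range (row-blocked for cache residency,
single-precision arithmetic as is conventional for network training, no
im2col materialization). Backpropagation is hand-derived and verified two
ways: the forward pass against an independent dense double-precision
reference implementation, and analytic gradients against finite differences
of that reference.

## Time-resolved optical-property fitting

Background $\mu_a$ and $\mu_s'$ are estimated from time-resolved traces at
four source–detector distances (13.8, 18.4, 23.0, 27.6 mm). The instrument
response is conditioned by a 0.5 ns moving average, subtraction of the
pre-pulse baseline (first 10% of samples by default), and peak normalization.
The model is the analytical semi-infinite-medium reflectance with an
isotropic source at depth $z_0 = 1/\mu_s'$ and an extrapolated-boundary image
source at $-(z_0 + 2z_b)$, $z_b = 2AD$ (a zero-boundary variant is
switchable). Two features are compared after convolving the model with the
IRF: the peak amplitude (mean of the five largest samples) and the mean time
of flight $\sum_j t_j I_{t_j} / \sum_j I_{t_j}$. The fit minimizes, over the
grid $\mu_a \in [10^{-5}, 10^{-3}]$ step $10^{-5}$ and
$\mu_s' \in [0.02, 0.2]$ step $0.001$ mm$^{-1}$, the weighted sum of squared
mismatches of *relative* flight times and *relative* log peak ratios with
respect to the first distance, the time term carrying weight 100. Ties break
to the smallest $\mu_a$, then $\mu_s'$.

Numerical choices: the diffusion coefficient in this module is
$D = 1/(3\mu_s')$, the standard time-domain convention, under which
absorption enters the model *exactly* as $e^{-\mu_a v t}$ — an identity the
tests check to machine precision. (The tomography modules keep
$\kappa = 1/\bigl(3(\mu_a+\mu_s')\bigr)$; at the fitted regime's
$\mu_a \sim 10^{-4}$ mm$^{-1}$ the two differ negligibly.) The default time
grid is 0–10 ns at 10 ps. The expensive part — the feature table over the full
parameter grid — is computed once per IRF with FFT-batched convolutions and
reused across fits.

A caution on precision, measured with this implementation: with noiseless
on-grid features recovery is exact, but the estimator's variance under trace
noise is substantial because only relative features carry information —
at 0.1% trace-amplitude noise the median $|\mu_s'|$ error is about 5% and
$\mu_a$ is identified only to the scale of its grid. The test suite asserts
exactly these measured precisions and their monotone degradation with noise,
rather than any sharper claim.

## Camera preprocessing

The cylindrical surface is imaged in three sections (direct view and two
mirrors). Calibration control points — a printed 1 cm lattice wrapped on the
vessel — anchor least-squares 2D polynomial transforms (default total degree
3) in both directions; round-trip residuals are reported and must stay below
half a pixel. Unwrapping builds a dense rectilinear grid and samples the
camera image at inverse-transformed locations bilinearly; sections are
stitched side by side with provenance retained. Saturated spots (vessel
autofluorescence, spurious reflections) are thresholded, dilated by a 5 px
disk, and filled harmonically (Laplace interpolation from the boundary —
smooth and parameter-free); images are then smoothed by a 7×7 median filter
with reflective padding; measurement amplitudes are medians of the 3×3 block
around each mapped pixel, truncated at borders. A deterministic synthetic
fixture (`synth_camera_fixture()`) with known warps, spots and ground-truth
panorama exercises the whole chain.

## Evaluation metrics

* **IoU** (the primary metric): $|\{\text{recon} > 1\} \cap \{\text{truth} > 0\}|
  / |\{\text{recon} > 1\} \cup \{\text{truth} > 0\}|$ over the cylinder mask.
  Classic reconstructions are divided by their masked standard deviation
  first, so the threshold of 1 means one standard deviation; the network's
  output is produced directly in those normalized units (its training targets
  were std-normalized truths) and is thresholded at 1 as-is. A half-cylinder
  split along the y–z plane scores two inclusions separately.
* **Center-of-mass bias**: distance from the intensity-weighted centroid of
  the thresholded reconstruction to the true center.
* **FWHM**: 3D FWHM is not well-defined by a printed table; the package uses
  the equivalent-spherical diameter $2(3V/4\pi)^{1/3}$ of the above-half-peak
  set — deterministic and shape-independent — with an axis-aligned-extent
  alternative behind a flag.
* **SSIM**: single-window form with $K_1 = 0.01$, $K_2 = 0.03$, dynamic range
  1 after max-normalization, computed over the union of 3 cm balls around the
  true centers (background voxels would otherwise inflate the score).

## The desk-scale study and what it shows

Full-scale training (48×48×56 grid, 2500 cases, 64+56 optodes) is GPU-class
work. The package's reference study — run by `scripts/acceptance.R` and
asserted by the acceptance tests — is a desk-scale version chosen once:
24×24×28 grid, 16 sources + 16 detectors in 4×4 rings (channels under 70 mm,
as in the dense regime), 320 cases split 256/32/32, the 2-level network
preset, batch 16, patience 5, and at most 40 epochs (early stopping fires
well before this in practice). Under these conditions the held-out IoU after
denoising must at least double the classic IoU with paired significance
below 0.01. The full-scale figures reported for this method (mean IoU
0.054 → 0.44, an ~8-fold improvement) are not reproducible at this scale and
are not asserted; the desk-scale doubling is the verifiable surrogate.

## Known limitations

* The forward model is continuous-wave and Born-linear in $\gamma$ (the
  emission source term uses the unperturbed excitation field); whether the
  original data generation allowed the fluorophore to perturb the excitation
  field is not stated anywhere, and the linear model is adopted.
* Homogeneous background optical properties per case (heterogeneous maps are
  structurally possible but not exercised).
* Inclusion-type fluorophore distributions only; continuum distributions and
  background fluorescence are out of scope.
* The optode arrangement behind the printed channel count of the full-scale
  layout is not recoverable from the description; ring patterns are
  configuration, and the printed counts are not asserted.
* The TPSF fitter's precision is feature-limited (see above); it was chosen
  for faithfulness to the two-feature grid search, not as the best possible
  estimator.
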