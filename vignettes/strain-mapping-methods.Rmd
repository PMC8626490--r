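---
title: "Methods: simulated tagging MRI and pixelwise principal strain mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated tagging MRI and pixelwise principal strain mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tagging MRI (1-1 SPAMM) imprints sinusoidal magnetization stripes into soft
tissue; the stripes deform with the tissue, so a pair of images with
perpendicular tag lines encodes the full 2D motion at every pixel. The
quantity of clinical interest is the Eulerian strain tensor
$e = \tfrac{1}{2}(I - B^{-1})$ with $B = F F^\top$ the left Cauchy–Green
tensor of the deformation gradient $F = \partial x / \partial X$. Its
eigenvalues $\varepsilon_{p1} \ge \varepsilon_{p2}$ (maximum stretching and
maximum contraction) with perpendicular eigenvectors $n_1, n_2$ form the
principal strain maps this package estimates.

`tagstrain` contains the four ingredients of a complete, self-contained
study of this estimation problem:

1. a Monte-Carlo **phantom simulator** producing tagged cines with analytic
   pixelwise ground truth,
2. the **HARP** harmonic-phase bandpass baseline,
3. a conditional-GAN **pixel-to-pixel strain mapper** (U-net generator,
   patch discriminator, four loss-weighting schemes), and
4. an **evaluation kit** (pooled pixel correlations, 0.05-bin
   absolute-error histograms, patch sampling for artifact review).

## Phantom simulator

### Geometry and motion

The left ventricle is a full annulus and the liver an annulus sector; every
geometric, functional and imaging parameter is drawn uniformly from a
(min, max) pool, so each cine is an independent Monte-Carlo draw
(`simulator_profile()` lists the pools). No closed-form motion model is
prescribed by the physiology, so the package adopts the simplest model
consistent with an annulus phantom and exact ground truth: an
**incompressible, radially symmetric contraction** about the organ centre.
With the inner radius contracted from $r_{0i}$ to $r_i(t)$ and
$\Delta(t) = r_{0i}^2 - r_i(t)^2$, a material point at radius $R$ moves to
$r = \sqrt{R^2 - \Delta(t)}$ (plus an optional rigid rotation); annulus
area is preserved exactly, both map directions are closed-form, and in
polar coordinates $F = \mathrm{diag}(\partial r/\partial R,\; r/R)$, giving
analytic principal strains

$$\varepsilon_{p1} = \tfrac12\!\left(1 - (\rho/R)^2\right) \quad
  \text{(radial)}, \qquad
  \varepsilon_{p2} = \tfrac12\!\left(1 - (R/\rho)^2\right) \quad
  \text{(circumferential)}$$

at spatial radius $\rho$. The systolic time course is a raised cosine from
rest to peak contraction (frame 4 of 7 by default) and back.

A consequence worth stating explicitly: **in-plane incompressibility caps
the radial strain.** Since $\varepsilon_{p1} = \tfrac12(1-\lambda_c^2)$ and
$\varepsilon_{p2} = \tfrac12(1-1/\lambda_c^2)$ share one stretch
$\lambda_c$, requiring $\varepsilon_{p2} \ge -0.5$ forces
$\varepsilon_{p1} \le 0.25$. Real myocardium thickens more than this
(through-plane motion makes in-plane area grow), so the simulated radial
channel spans [0, ~0.24] while the circumferential channel spans
[~-0.46, 0] under the default contraction pool [0.08, 0.28]. Evaluations
that depend on radial strains near 0.5 are therefore outside what this
motion model can produce.

### Image formation

Tags are **material-advected**: the intensity at spatial pixel $x$ is
determined by its reference coordinate $X(x,t)$ obtained from the
closed-form inverse map,
$I_d(x,t) = I_{do}(x,t) + I_{To}(x,t)\cos(\omega_d X(x,t)\cdot n_d)$,
with the tag spacing 8 mm and pixel spacing 1.1 mm of the training grid
(tag carrier 7.27 px/period). Tag preparation fully modulates the
longitudinal magnetization, so at the first frame the image is the signed
pattern $I_o \cos(\omega_d X \cdot n_d)$ — negative lobes present — and
longitudinal relaxation then fades the tag term as
$A_T(t) = e^{-t/\tau}$ while the anatomical term recovers as
$A_d(t) = 1 - A_T(t)$ ($\tau$ drawn from [10, 20] frames, the ~850 ms
$T_1$ at 3 T against ~50 ms frame spacing). Fading is part of image
formation (`render_tagged_pair()`); `degrade()` then applies the
stochastic corruptions: a smoothed log-normal speckle field of mean one,
white Gaussian noise at an SNR drawn from [8, 30], and a low-order
polynomial inhomogeneity phase $\varphi_e$ carried for complex/rectified
output. The blood pool is rendered untagged (through-plane flow washes the
stripes out).

The background stands in for the anatomical image behind the moving
organs. It is a synthetic texture: smooth low-frequency shading, five to
ten elliptical regions with distinct intensities and sharp (1 px)
boundaries, and fine speckle-scale texture. The sharp edges matter — they
spread broadband energy across k-space, which is the mechanism behind
harmonic-peak interference artifacts in bandpass methods; an edge-free
background would flatter the baseline. A user-supplied background image can
be passed to `render_tagged_pair()` instead. What the texture does *not*
emulate: coherent anatomy (ribs, lungs, chambers), receive-coil shading,
or motion of structures other than the two phantom organs, so passing
tests here do not certify performance on real acquisitions.

### Ground truth and self-consistency

`analytic_ground_truth()` is exact (no discretization); the test suite
additionally differentiates the dense inverse map numerically and checks
the 99th-percentile agreement inside organs is below 0.01. Organ-boundary
pixels are excluded from that comparison (2-px erosion): the displacement
field is discontinuous across the boundary, so a finite-difference stencil
straddling it measures the discontinuity, not the strain.

## HARP baseline

The harmonic-phase pipeline: FFT, isotropic Gaussian bandpass centred on
the positive harmonic peak ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$, FWHM
given in k-space pixels of the 256-cell reference grid; the classic sweep
is 8–28 px), inverse FFT, wrapped phase. Because harmonic phase is a
material property, $\nabla \varphi_d = \omega_d \cdot (\text{row } d$ of
$F^{-1})$, two perpendicular tag directions assemble $G = F^{-1}$ and
$e = \tfrac12(I - G^\top G)$ follows without any phase unwrapping —
differences are taken modulo $2\pi$, which is exact up to $\pi$ rad/px.
The filter shape is a design choice (only "bandpass" and the FWHM are
standard); a Gaussian is used because it is smooth, standard HARP
practice, and uniquely parameterized by the FWHM. Strain is computed
frame-by-frame from phase gradients (Eulerian), with no temporal tracking,
and maps keep native resolution.

## The strain mapper

The generator is a U-net (eight stride-2, 4×4-kernel encoder stages with
64, 128, 256, 512×5 feature maps down to a 1×1 bottleneck; mirrored
transposed-convolution decoder with skip concatenation) followed by three
stride-1 head convolutions (16, 8, 2 maps). The output activation is
$0.5\tanh$, matching the physical strain range (−0.5, 0.5). The
discriminator scores 32×32 patches of the 4-channel (tags + strain)
input. Normalization is per-sample (instance) normalization — the batch
size is 1, the pix2pix regime — and the 1×1 bottleneck stage carries no
normalization, since a per-sample statistic of a single spatial element is
degenerate.

Training minimizes $\alpha_1 L_G + \alpha_2 L_D$ where
$L_G = \mathbb{E}[K \lVert E_p - G(\tau) \rVert_1]$ with the per-pixel
weight $K = \kappa \lVert E_p \rVert_1 + 1$ ($\kappa = 10$) computed from
the ground truth, and $L_D = \mathbb{E}[1 - \log D(\tau, G(\tau))]$
averaged over the patch-score map. $K$ is per-pixel (not per-image)
because its purpose is to counteract the rarity of high-strain *pixels*.
The named schemes are D-Only (0, 1), G-Only (1, 0), D-G1 ($10^4$, 1) and
D-G2 ($10^3$, 1); optimization is Adam at learning rate 2e-4 with momenta
(0.5, 0.9). Scores are clipped to $[10^{-7}, 1-10^{-7}]$ before
logarithms. With $\alpha_2 = 0$ the discriminator is never built; D-Only
is flagged experimental (it trains the generator on the adversarial term
alone and is not expected to converge to accurate maps).

```{r}
library(tagstrain)
prof <- simulator_profile("desk")
con <- generate_dataset(tempfile(), n_cines = 40,
                        split = c(train = 30, test = 10), prof = prof,
                        seed = 1)
fit <- train_strain_mapper(tagstrain:::container_samples(con, "train"),
                           training_scheme("g-only"), epochs = 30,
                           width_scale = 1 / 8, seed = 1)
autoplot(fit)   # Fig-9-style train/validation loss curves
```

### Desk-scale study conditions

Full-scale training (600 cines at 256×256, thousands of epochs-worth of
updates on a GPU) is out of reach for a CPU package check, so the packaged
study conditions use the `"desk"` profile: 64×64 images at 2.2 mm/pixel
with all geometry pools halved (strain is dimensionless and the motion
model scale-invariant, so the strain distributions are identical), feature
maps scaled by 1/8, 30 cines (210 frames) for training, 10 cines held out,
30 epochs. Under these conditions the G-Only mapper reaches pooled
held-out correlations above 0.8 for both channels — the scaled-down analog
of full-scale performance — and matched 120-frame runs trained to their
loss plateau (20 epochs; the plateau level is the mean validation loss of
the last five epochs) compare the schemes. The comparison at this scale is
a statistical tie for the G-Only/D-G1 pair, whose generator objectives
differ only by a $10^{-4}$-weighted adversarial nudge; the robust,
reproducible feature is that D-G2 (ten-fold stronger adversarial weight)
converges to the highest validation loss.

## Evaluation protocol

`pixel_correlation()` pools pixels across frames (one R per method and
channel, not per-frame averages) over an evaluation mask; the default mask
is the union of the moving organs, and an all-pixels mode exists. The two
modes answer different questions and can rank methods differently: organ
masking measures fidelity where strain lives; all-pixels pooling dilutes
the radial channel (whose within-organ variance is small) with background
artifact noise far more than the circumferential one. The histogram tool
bins pixels by *reference* strain into left-closed 0.05 bins over [0, 0.5]
and [−0.5, 0] and reports median/IQR absolute error per bin; empty bins
are absent, not zero. `sample_patches()` reproduces the blinded
artifact-review protocol (100 patches of ceil(5 mm / pixel spacing) px,
half from early systole — the first third of frames up to peak — and half
from late systole); the artifact grading itself was a human rating and is
deliberately not automated.

## Numerical choices

* Gradients: central differences in the interior, one-sided at borders —
  second-order accurate, no pre-smoothing that would bias strain
  magnitudes. Wrapped-phase differences are wrapped into $(-\pi, \pi]$
  before dividing by the spacing.
* Pixels with numerically non-positive $\det F$ are masked invalid, not
  clipped, so downstream error statistics stay honest.
* Eigenvector sign is fixed by "first nonzero component ≥ 0"; 2×2
  eigenpairs come from the closed-form quadratic.
* Image resampling is bicubic (Catmull–Rom) for images — tag-carrier
  fidelity — and nearest-neighbour for masks; pairs are normalized to
  [−1, 1] jointly and the scale recorded for inversion.
* De-rectification detrends the inhomogeneity phase with a least-squares
  degree-2 polynomial fit on the doubled-angle phase (blind to the
  rectification $\pi$ jumps), then flips the sign where the residual
  wrapped phase exceeds $\pi/2$.
* All randomness flows through R's RNG; every dataset container records
  its seed, profile and pools, and every experiment artifact carries the
  hash of the configuration that produced it.

## Known limitations

* 2D only; no through-plane motion, no Bloch-equation physics, no k-space
  acquisition model beyond the image-domain tagging equation.
* The incompressibility cap on radial strain discussed above: joint
  radial/circumferential ranges of (0.5, −0.5) magnitude are unreachable,
  which also keeps bandpass baselines more correlated with radial truth
  than they are on data with larger, artifact-dominated radial strains.
* The synthetic background approximates the *statistics*, not the
  anatomy, of real images; in-vivo DICOM ingestion is out of scope here.
* HARP is implemented in its frame-independent form (no CINE tracking or
  refinement).
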