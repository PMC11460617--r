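---
title: "Physics-aware plug-and-play reconstruction for lensless inline holography: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-aware plug-and-play reconstruction for lensless inline holography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holopnp)
```

## The imaging model

A lensless digital inline holographic microscope illuminates a thin,
weakly absorbing sample with a quasi-monochromatic, partially coherent
source and records, on a bare sensor a millimetre or so behind the
sample, the interference of the wave scattered by the object with the
unscattered background wave. Under unit-magnification geometry the
recorded intensity after normalization by a no-sample reference is

$$ I = \lvert P_{z_2}(u_o)\rvert^2, $$

where $u_o(\xi,\eta) = a(\xi,\eta)\, e^{i\phi(\xi,\eta)}$ is the complex
object transmission (the unscattered reference is the unit-amplitude part
of $u_o$) and $P_z$ is scalar free-space propagation over the
sample-to-sensor distance $z_2$. Propagation is implemented with the
angular spectrum method: multiply the field's FFT by
$\exp\!\big(i\,2\pi \tfrac{z}{\lambda}\sqrt{1-(\lambda f_x)^2-(\lambda f_y)^2}\big)$
and zero the evanescent band where the square-root argument is negative.
The discrete frequency grid uses the standard FFT convention with spacing
$1/(N\,\mathrm{pitch})$; the sign of $z$ selects the direction, so
$P_z$ and $P_{-z}$ are exact mutual inverses on the propagating band
(verified to $10^{-6}$ max-abs in the tests, and against direct
quadrature of the Rayleigh–Sommerfeld diffraction integral to better than
$10^{-3}$ relative on $64^2$ grids). Lengths are micrometres internally;
wavelengths enter in nanometres and axial distances in millimetres.

Two coherence calculators bound the achievable resolution: the temporal
coherence length $\Delta L_c = (2\ln 2/\pi)\,\lambda^2/(n\,\Delta\lambda)$
and the spatial coherence diameter $D_{coh} = \lambda z_1 / D$, with the
interference half-angles they permit and the conservative resolution
estimate $\Delta x = \lambda / (2\sin\theta_{\min})$. The two limits are
reported side by side rather than combined, since no single combining
rule is canonical; for the default configuration (627 nm, 20 nm width,
$z_2 \approx 1$ mm) $\Delta x$ lands near the 1.67 um pixel pitch, i.e.
the sensor, not the source, is the binding constraint.

## Classic reconstruction and autofocus

Single-shot backpropagation applies the conjugate kernel to the
normalized intensity itself (not its square root; both conventions exist
in the literature, and the intensity form is what the linearized forward
model inverts). The result necessarily carries the twin image: the
conjugate wavefront focused at $-z$ is superposed, defocused, on the
object term.

Autofocus sweeps a coarse grid of candidate distances and refines the
best one by golden-section search. The default criterion is the L1/L2
ratio (a sparsity measure, minimized at focus) of the modulus of the
backprojected DC-removed hologram: at the true distance the scattered
component collapses onto the compact object while the twin only spreads.
Amplitude-sharpness criteria (mean gradient, Tamura coefficient of the
gradient) are selectable, but in z-sweeps on simulated phantoms they were
monotone in $z$ for extended smooth phase objects and never localized the
focus under the intensity-backprojection convention, so the sparsity
criterion is the default. A physical caveat found in the same sweeps:
*smooth, band-limited* phase blobs at these Fresnel numbers barely change
their diffraction pattern over a millimetre of defocus, so no criterion
can focus them reliably; autofocus accuracy is therefore specified (and
tested, to 0.02 mm over 0.8–1.3 mm) on sharp-featured bead fields.

Phase maps are unwrapped either by quality-guided region growing
(default; quality = inverse local variance of the wrapped gradients,
implemented as a banded threshold flood so it stays vectorized) or by a
DCT least-squares Poisson solve (fast, exact on residue-free maps). The
constant phase offset left over is fixed by zeroing the modal value of a
10-pixel border frame, assumed to be undisturbed background.

## The plug-and-play objective

Reconstruction minimizes, over the object estimate $u_o$ and the
parameters $\theta$ of an untrained generator network $R_\theta$,

$$ \tfrac12\,\lVert H(R_\theta) - I_\tau\rVert_2^2
 \;+\; \tfrac{\alpha}{2}\,\mathrm{Re}\langle u_o,\, u_o - u_\tau\rangle
 \;+\; \tfrac{\beta}{2}\,\lVert u_o - R_\theta - t\rVert_2^2 , $$

with $H$ the forward hologram operator at the focused distance, $I_\tau$
the (optionally upsampled) measurement, $u_\tau$ a *prior object* built
from an externally supplied high-resolution phase $\phi_\tau$ combined
with a constant amplitude, and $t$ the Lagrange multiplier of the
splitting $u_o = R_\theta$. The three updates run sequentially each
epoch: Adam steps on $\theta$ (fidelity + proximity), an explicit
steepest-descent step on $u_o$ (prior + proximity gradients,
$\alpha(u_o - u_\tau) + \beta(u_o - R_\theta - t)$), and the multiplier
ascent $t \leftarrow t - (u_o - R_\theta)$. The prior inner product is
taken as the real part of the Hermitian product so the loss is real; its
update gradient is the plain pull $\alpha (u_o - u_\tau)$.

Prior modes: `file` (a phase map produced elsewhere — the role a
pre-trained super-resolution generator plays in the full system),
`tv` (total-variation denoised backpropagated phase; the
regularization-by-denoising surrogate), `bicubic` (interpolated
backpropagated phase), `none` (prior pull disabled; the plain
deep-image-prior objective). In every mode $I_\tau$ is the bicubic
upsampling of the measurement; upsampling factors 1, 2 and 4 are
supported, and the whole loop then runs on the fine grid.

### Stability choices

Two design points were settled by experiment, because the naive choices
diverge:

* **Generator input.** Feeding the generator the *current* estimate
  $u_o^k$ makes the splitting constraint $u_o = R_\theta(u_o)$ nearly
  degenerate (a freshly initialized residual network is close to the
  identity), so the multiplier integrates the residual without an anchor
  and the whole loop runs away — on a noiseless $128^2$ phantom the
  fidelity grew without bound regardless of step sizes. The default
  (`net_input = "initial"`) therefore feeds the *fixed* initial
  backprojection $u_o^0$ every epoch, the standard deep-image-prior
  anchoring, with the evolving-input variant retained as a config switch.
* **Object step size.** The object sub-problem is an exact quadratic, so
  the default step `c_step = 1/(alpha + beta)` is its closed-form
  minimizer; with it the multiplier recursion is contractive (spectral
  factor $\alpha/(\alpha+\beta) < 1$) and at the fixed point
  $u_o = R_\theta$ exactly. Small fixed steps (e.g. 0.05) left the
  multiplier unstable.

The multiplier update is implemented with the constraint residual
$u_o - R_\theta$; the variant with a plus sign inside the parenthesis is
available behind `multiplier_sign = "sum"` for literal replication of the
printed recursion, but only the residual form vanishes at the fixed
point.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.5 | — | prior pull; 0 disables (plain deep prior) |
| `beta` | 0.5 | — | splitting proximity weight |
| `c_step` | $1/(\alpha+\beta)$ | — | object step; default = exact minimizer |
| `theta_lr` | 0.01 | — | Adam rate for the generator |
| `inner_theta_steps` | 1 | — | network steps per epoch |
| `tol` | 1e-3 | — | stagnation tolerance; 0 = run the epoch budget |
| `max_epochs` | 700 | — | simulation budget (1000 for noisy data) |

`alpha`, `beta` and `theta_lr` were fixed once by a small grid search on
a single validation phantom (peak recovery and stability) and are not
data-dependent.

### Stopping

Each epoch yields three sub-objective values (theta step, object step,
multiplier step). The run stops early when
$\max(\epsilon_1,\epsilon_2,\epsilon_3) \le \mathrm{tol}/3$ with
$\epsilon_i = |L_i^{k} - L_i^{k-1}|/n$ ($n$ = number of object pixels),
required for five consecutive epochs because single-epoch Adam jitter
produces spurious dips. Which quantity each $\epsilon_i$ tracks is an
interpretation choice; the change in each update's own objective value is
used here. For *noiseless simulated* data the stagnation rule typically
fires while quantitative phase is still improving (it exists to stop
overfitting of interference noise on experimental holograms), so the
simulation protocol runs the fixed 700-epoch budget (`tol = 0`) and the
stagnation rule is the default for measured data.

## The generator

The untrained network is an encoder–decoder with skip connections
operating on the (real, imaginary) channel pair of the complex field:
per level two 3x3 convolutions, each followed by instance normalization
and LeakyReLU(0.1); 2x2 mean pooling down, bilinear upsampling back, 1x1
skip projections, and a near-zero-initialized 1x1 output projection plus
a residual connection from the input, so a fresh generator is
approximately the identity. Amplitude/phase channelization was rejected
because phase wrapping breaks the smoothness prior. The default size
(depth 3, 8 base channels, 4 skip channels, ~21k parameters) is chosen so
several hundred epochs on a $128^2$ grid run in minutes on one CPU core;
instance normalization is what makes the fit stable at `lr = 0.01` (the
same network without it needed 10x smaller rates and still diverged
occasionally). Convolutions are im2col gathers plus BLAS matrix
multiplies with the gather/scatter inner loops in C++; the backward pass
is hand-written and verified against central differences to $10^{-3}$
relative on every layer type. All initialization is a pure function of
the seed.

## What the synthetic data emulates — and what it does not

`make_cell_phantom` generates smooth, band-limited cytoplasm-plus-nuclei
phase blobs rescaled to an exact peak phase (4 rad by default);
`make_bead_phantom` places spherical-cap beads with
$\phi = 2\pi h (n_1-n_2)/\lambda$; `build_dataset` reproduces the
simulation protocol (z drawn per record from {0.8, ..., 1.3} mm, 627 nm,
paired hologram/phase folders, 1800/148/100-of-2048 split proportions
with floor/floor/remainder rounding). Objects are pure phase by default
(the amplitude model of simulated cells is not pinned down anywhere
authoritative; weak absorption can be added through the amplitude map).
The phantoms deliberately lack: experimental partial-coherence blur,
sensor fixed-pattern artifacts, out-of-plane cell structure, and the
morphological richness of real smears. Passing the test battery
therefore demonstrates the *inverse-problem machinery* — not performance
on clinical data.

Sizes used in the shipped tests and acceptance runs: $64^2$ for the
method-comparison battery, $128^2$ for single-phantom end-to-end runs,
$256^2$ for autofocus; epoch budgets 100–700. These are desk-scale
choices; the algorithms are size-agnostic.

## Known limitations

* **Wrap ambiguity of steep objects.** A 4 um bead at
  $\Delta n = 0.35$ has 14.03 rad of peak phase crossing its rim in
  roughly one 1.67 um pixel. The hologram only encodes
  $e^{i\phi}$, and for an ideal spherical cap the per-sample phase step
  at the rim exceeds $\pi$ at any practical pitch (it would require
  ~0.05 um sampling), so *no* unwrapping algorithm can recover the true
  wrap count from a single hologram; the recovered peak is the wrapped
  residue (~1.4 rad, i.e. ~0.4 um apparent thickness). Quantitative
  bead thickness at this index contrast fundamentally needs either a
  known-shape model fit or a calibrated phase-to-thickness scaling; the
  package reports what the data support.
* **Ab-initio twin suppression is prior-limited.** With only the
  interpolation or TV prior, the untrained network fits the hologram
  well (2% residual intensity) but phase fidelity plateaus
  (correlation ~0.2 with truth on 4-rad phantoms, and the conjugate
  solution is sometimes selected): without amplitude or positivity
  constraints the single-shot inverse problem stays massively
  ambiguous. The method's quantitative accuracy comes from the
  *trained* prior it is designed to plug in; with a faithful
  high-resolution prior phase the pipeline recovers the 4-rad peak
  within 10% and SSIM > 0.95.
* **p-SNR full-frame convention.** `psnr_phase` uses the standard
  deviation of the scored region (a scalar self-covariance is a
  variance; the standard deviation keeps the log argument a
  dimensionless amplitude ratio). Full frame is the default; with it
  the plain deep-prior mode does not consistently beat classic
  backpropagation (its noisier background and occasional conjugate
  selection cost more than its sharper object gains), although the
  structural-similarity ordering classic < deep prior < denoiser prior
  < trained prior holds on every battery phantom. An ROI argument is
  provided for background-referenced scoring.
* **Autofocus needs spatial bandwidth** (see above); smooth extended
  blobs do not focus.
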