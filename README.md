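# holopnp

Simulation and reconstruction toolkit for **lensless digital inline
holographic microscopy** (LDIHM) — the lens-free imaging geometry in
which a partially coherent source illuminates a thin sample sitting a
millimetre or two above a bare sensor, and quantitative phase is
recovered computationally from a single recorded interference pattern.

The package provides, in one coherent R workflow:

* a scalar-diffraction **forward model** (angular-spectrum propagation
  with evanescent cutoff, hologram formation and normalization,
  coherence-limited resolution and field-of-view calculators);
* seeded **synthetic phantoms** — spherical-cap microbeads and
  cell-like smooth phase objects — plus paired hologram/phase datasets
  with train/val/test manifests;
* **classic reconstruction**: backpropagation of the hologram,
  sharpness-based autofocus over the propagation distance, and 2-D
  phase unwrapping (quality-guided or least-squares);
* a **physics-aware plug-and-play ADMM** reconstruction that couples a
  data-fidelity term through the forward model with a pluggable prior
  (file-supplied high-resolution phase, total-variation denoiser, or
  interpolation) and an untrained encoder–decoder generator (deep image
  prior) with hand-written backpropagation, to recover
  twin-image-suppressed, optionally 2x/4x-upsampled phase;
* **evaluation**: phase-SNR `10*log10((max(P) - mu)/sigma)`, SSIM, MSE,
  phase-to-thickness conversion
  `h = p * lambda / (2 * pi * (n1 - n2))`, and z/wavelength robustness
  sweeps;
* a config-driven **command-line interface**
  (`inst/cli/holopnp.R`: `simulate | reconstruct | evaluate | sweep`).

## Worked example

Simulate a cell-like phase object (peak 4 rad) at 627 nm, 1.67 um pixel
pitch and z = 1 mm, then reconstruct it three ways:

```r
library(holopnp)

obj  <- make_cell_phantom(128, peak_phase_rad = 4, seed = 7)
holo <- forward_hologram(object_field(obj),
                         optical_config(z2_mm = 1,
                                        sensor_shape = c(128, 128)))

## classic single-shot backpropagation (twin image included)
classic <- reconstruct_classic(holo, z_mm = 1)
max(classic$phase)            # 1.02  -- twin-biased peak, far from 4

## plug-and-play with a high-resolution prior phase (the role played by
## a pre-trained super-resolution network on in-distribution data)
pnp <- reconstruct_pnp(holo, "hdphysnet",
                       admm_config(tol = 0, max_epochs = 400, seed = 0),
                       generator_spec(), prior_phase = obj$phase,
                       z_mm = 1)
max(pnp$phase)                # 3.72  -- peak phase within 10% of truth
ssim(pnp$phase, obj$phase)    # 0.977
pnp$diagnostics$stop_reason   # "max_epochs" (budget-governed run)
```

The classic reconstruction recovers the object's support but its peak
phase is heavily biased by the superposed conjugate wavefront; the
plug-and-play loop, anchored by the physics fidelity term and pulled by
the prior, restores the quantitative peak. Autofocus, when the distance
is unknown, recovers z to ~0.003 mm on sharp-featured samples:

```r
beads <- make_bead_phantom(8, 10, 1.345, 1.33, size = 256, seed = 4)
bh    <- forward_hologram(object_field(beads),
                          optical_config(z2_mm = 1.1,
                                         sensor_shape = c(256, 256)))
autofocus(bh, 0.5, 2)$z_star_mm   # 1.0984
```

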