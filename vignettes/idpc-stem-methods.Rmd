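---
title: "Simulating and reconstructing iDPC-STEM images of cryo specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing iDPC-STEM images of cryo specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpcstem)
```

## The imaging model

In scanning transmission electron microscopy (STEM) a focused electron
probe is rastered across the specimen and, for every probe position, the
far-field diffraction pattern (CBED) is recorded behind the specimen. The
probe is characterized by its convergence semi-angle (CSA) $\alpha$: the
diffraction-limited resolution is $\lambda/(2\alpha)$, the Nyquist scan
step $\lambda/(4\alpha)$, and the depth of focus $2\lambda/\alpha^2$. At
300 kV ($\lambda = 1.969$ pm) a 2.0 mrad beam resolves 4.9 Å with a
985 nm depth of focus; a 4.5 mrad beam resolves 2.2 Å but focuses over
only 194 nm. Because plunge-frozen specimens are 10–60 nm thick, every
integer CSA up to 8 mrad still projects the full ice thickness; 9 mrad is
the first that does not (`min_csa_below_thickness(300, 60)`).

A thin specimen shifts the centre of mass (COM) of the CBED pattern in
proportion to the transverse gradient of its projected electrostatic
potential. A segmented detector with four quadrants A–D (counterclockwise
from the detector +x axis, central hole of one sixth the outer radius,
camera length set so the bright-field disk radius is four times the hole
radius) approximates the COM by opposite-quadrant differences:

$$D_x = (A + D) - (B + C), \qquad D_y = (A + B) - (C + D),$$

rotated by $-\rho$ when the scan frame is rotated by $\rho$ relative to
the detector. The integrated DPC (iDPC) image is the Fourier-space
integration of this vector field,

$$I(\mathbf k) = \frac{k_x D_x(\mathbf k) + k_y D_y(\mathbf k)}
                      {2\pi i\,(|\mathbf k|^2 + \epsilon)},$$

with the $k = 0$ term nulled (images are mean-zero) and $\epsilon = 0$ by
default; a Tikhonov $\epsilon$ is available for noisy data. For a weak
phase object the result is proportional to the projected potential —
protein renders white — filtered by a contrast transfer function (CTF)
that is positive everywhere, decays towards the cutoff $2\alpha/\lambda$,
and vanishes beyond it. Quadrant detection adds a fourfold azimuthal
modulation at low frequency which ideal COM detection lacks; the package
quantifies it as the $4\theta$ Fourier coefficient of the azimuthal CTF
profile (`ctf_fourfold()`). No 2D correction of that pattern is applied by
default; the CTF returned by `compute_ctf()` can be used for optional
deconvolution.

## Simulator design

`scan_image()` is a full forward model: the aperture-limited probe
(aberration phase $\chi(\theta) = (2\pi/\lambda)(-\Delta f\,\theta^2/2 +
C_s\theta^4/4)$; positive defocus moves the waist upstream) is shifted to
each raster position by Fourier phase ramps (sub-pixel exact), propagated
through the sliced specimen potential by the multislice method
(phase gratings $e^{i\sigma V_s}$ alternating with Fresnel propagators,
both unitary, flux conserved to $10^{-6}$), transformed to the far field,
and integrated over area-weighted quadrant masks (3×3 supersampled edge
pixels; the masks for hole, quadrants and the remainder partition the
pattern exactly). Shot noise enters at the quadrant level as independent
Poisson draws of the expected electron counts per dwell
($\mathrm{TED} \times \mathrm{PS}^2$), reproducible under a single named
seed. All spectral operations use periodic boundary conditions; phantoms
are built so their content tiles the grid (helical rods span an integer
number of repeats).

`compute_ctf()` measures the transfer of the *entire* chain numerically: a
weak random phase object with unit-magnitude spectrum is scanned through
the simulator and the CTF is the per-frequency ratio of output to input
amplitude. This grating-response route is cross-checked in the tests
against an independent semi-analytic path (aperture-overlap/sideband
construction via the shift theorem) and against the linear surrogate
`wpo_image()`, which must agree with the full pipeline on thin weak
specimens at normalized cross-correlation above 0.98.

## Synthetic specimens and what they do (not) show

The generators produce sliced potentials in V·Å per slice:

* `helical_phantom()` — Gaussian blobs on a helical lattice. The defaults
  emulate TMV: 90 Å outer radius, 23 Å pitch, 49 subunits per 3 turns
  (rise 1.41 Å, twist 22.04°), so layer lines appear at $n/23$ Å$^{-1}$
  with low Bessel orders. The pitch is a free parameter because the
  layer-line calibration constant (22.03 Å) and the nominal repeat
  (23 Å) differ in practice. Subunit blobs are 2.5 Å wide: blob width
  damps the axial harmonics as $e^{-2\pi^2\sigma^2 k^2}$, and 2.5 Å keeps
  the second-order (11.5 Å) line at a realistic fraction of the first.
  The blob amplitude (100 V·Å) makes a rod's peak projected potential a
  few hundred V·Å — protein-against-ice contrast, peak phase ≈ 0.15 rad
  at 300 kV, safely weak-phase.
* `gold_lattice_phantom()` — a 2.35 Å cosine lattice on an amorphous
  background, the resolution standard: its spectral peak transfers only
  when $2\alpha/\lambda$ exceeds $1/2.35$ Å$^{-1}$ (true at 4.5 mrad,
  false at 2.0 mrad).
* `atoms_to_potential()` — isotropic Gaussians with strength $\propto
  Z^{0.8}$, a simple monotone proxy for scattering power; the full
  tabulated parameterization of atomic potentials is deliberately out of
  scope since no result here depends on absolute potential scale.
* `ice_layer()` — vitreous ice as a mean potential (3.5 V × slice
  thickness) plus band-limited Gaussian fluctuations (correlation length
  3 Å, RMS 0.2 V per Å of thickness). This reproduces the statistical
  texture of ice, not its molecular structure.

These phantoms exercise every quantitative property of the imaging chain
(transfer cutoffs, layer-line geometry, dose scaling, aliasing), but they
are not protein structures: passing tests demonstrate the correctness of
the physics and the estimators, not attainable resolutions on real
EMPIAR-scale data, which additionally involve classification and 3D
refinement outside this package's scope.

## Analysis conventions

* Layer-line profiles: segment power spectra are summed, then collapsed
  orthogonally to the helical axis over $|k_x| \le 1/50$ Å$^{-1}$
  (configurable). Peaks are located in ±15% windows around the expected
  comb $n/\text{spacing}$ (widened to the three nearest samples on coarse
  grids), with quadratic interpolation of the maximum and a local linear
  background between the window edges. A peak counts as detected only if
  it rises two off-peak standard deviations above that background and
  carries non-negligible power — the printed II/I ratios in real data
  depend on conventions the source material does not specify, so only
  ordering properties (ratio grows with CSA, damping lowers it) are
  asserted on synthetic data.
* Pixel-size calibration fits a single scale factor mapping detected
  peaks onto the $\{n/22.03\ \text{Å}\}$ comb by least squares.
* Guinier fits regress $\ln F$ on $k^2$ (B = −4 × slope); the
  particle-number B factor regresses $\ln N$ on $1/d^2$ (B = 2 × slope).
  Fit ranges are explicit parameters and recorded in the outputs.
* FSC uses shells one frequency sample wide, no masking, and reports the
  first 0.143 crossing with linear interpolation.

## Numerical choices and problem sizes

The experiment this emulates records 4096² pixels over ~1 µm fields. The
package's own tests and the acceptance script run the same chain at
reduced raster sizes — 96² scans over a 138 Å field for the helical rod
(two full 69 Å crystallographic repeats, so the periodic wrap is
seamless and the layer lines fall on exact frequency samples), 96² for
the gold standard, 64²–96² for SNR and aliasing studies — chosen so the
whole suite completes in minutes on one CPU while every frequency of
interest stays well inside the sampled band. Simulation grids are chosen
from sizes with small prime factors (60, 64, 96) where the FFT is
fastest. The quadrant-mask quantization is bounded by requiring the
bright-field disk to span at least ~16 grid samples at these sizes.

Known limitations: no chromatic aberration, source size or partial
coherence; no inelastic scattering or detector MTF beyond Poisson
statistics; ideal descan; stage drift and beam-induced motion are not
modelled (they are uncorrected in the imaging mode this package
describes). The noise model implies one further caveat: because
quadrant-level Poisson noise enters the DPC components as independent
white fields, the *noise* power spectrum of a reconstruction is
isotropic; the fourfold star pattern is a property of the deterministic
signal transfer, which is where the package tests it.

## A worked example

```{r example, eval = FALSE}
# plan: 300 kV, 4.5 mrad, 35 e-/A^2 at 0.75 A pixels
beam <- beam_parameters(300, 4.5, current_pa = 4)
plan_acquisition(beam, scan_geometry(0.75, 4096), 35)
#> <scan_plan> dwell 0.7886 us, frame 13.23 s, dose 35 e-/A^2 (19.7 e-/dwell)

# simulate a TMV-like rod and recover its layer lines
rod <- helical_phantom(helix_spec(outer_radius_A = 60), length_A = 138,
                       voxel_xy_A = 1.4375, slice_dz_A = 30, n_xy = 96)
b3 <- beam_parameters(300, 3.0, current_pa = 4)
sc <- scan_geometry(1.4375, 96)
q <- scan_image(rod, b3, sc, plan = plan_acquisition(b3, sc, 35))
img <- reconstruct_idpc(add_shot_noise(q, 1))
locate_layerlines(layerline_profile(img), 23, orders = 1:2)$peaks
```
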