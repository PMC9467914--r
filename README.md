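# idpcstem

Integrated differential phase contrast STEM (iDPC-STEM) imaging of
frozen-hydrated biological specimens, as an R toolkit: acquisition
planning from beam and dose physics, full forward simulation of the
scanning probe through synthetic specimens with a segmented four-quadrant
detector, reconstruction of iDPC images by Fourier integration of the DPC
vector field, and the micrograph analyses used in helical cryo-EM
(layer lines, pixel-size calibration, B factors, FSC).

It is written for microscopists and methods developers who want a
quantitative, testable model of the iDPC imaging chain: what a given
convergence semi-angle (CSA), dose and pixel size buy you, what the
contrast transfer function of quadrant detection looks like, and how
shot noise at the detector propagates into the reconstructed image.

## The model in brief

* **Probe optics.** Electron wavelength
  `lambda = h / sqrt(2 m0 e V (1 + eV / 2 m0 c^2))` (1.969 pm at 300 kV);
  diffraction-limited resolution `lambda/(2 alpha)`; Nyquist pixel
  `lambda/(4 alpha)`; depth of focus `2 lambda/alpha^2`; dose
  `TED = I t_dwell / PS^2`.
* **Forward simulation.** Aperture-limited probe with aberration phase
  `chi = (2 pi / lambda)(-df theta^2/2 + Cs theta^4/4)`, multislice
  propagation through sliced specimen potentials, far-field CBED,
  area-weighted quadrant integration (hole radius = outer/6, bright-field
  disk = 4x hole), Poisson noise per quadrant per dwell.
* **Reconstruction.** DPC vector from opposite-quadrant differences
  `Dx = (A+D)-(B+C)`, `Dy = (A+B)-(C+D)`, rotated by the scan rotation;
  iDPC image `I(k) = (kx Dx + ky Dy) / (2 pi i |k|^2)` with the DC term
  nulled; optional 251 A FWHM Gaussian high-pass preprocessing.
* **Analysis.** Collapsed helical layer-line profiles and II/I peak
  ratios, least-squares pixel-size calibration against the
  `n / 22.03 A` comb, Guinier (`B = -4 slope` of `ln F` vs `k^2`) and
  particle-number (`B = 2 slope` of `ln N` vs `1/d^2`) B factors, FSC
  with the 0.143 criterion.

## Worked example

Plan a dose-limited acquisition, simulate a TMV-like helical rod, and
recover its layer lines:

```r
library(idpcstem)

beam <- beam_parameters(300, 4.5, current_pa = 4)
plan_acquisition(beam, scan_geometry(0.75, 4096), 35)
#> <scan_plan> dwell 0.7886 us, frame 13.23 s, dose 35 e-/A^2 (19.7 e-/dwell)

stem_parameter_table(300, c(2, 3, 3.5, 4, 4.5))
#>   csa_mrad resolution_A pixel_size_A depth_of_focus_nm
#> 1      2.0          4.9          2.5               985
#> 2      3.0          3.3          1.6               438
#> 3      3.5          2.8          1.4               321
#> 4      4.0          2.5          1.2               246
#> 5      4.5          2.2          1.1               194

rod <- helical_phantom(helix_spec(outer_radius_A = 60), length_A = 138,
                       voxel_xy_A = 1.4375, slice_dz_A = 30, n_xy = 96)
b3 <- beam_parameters(300, 3.0, current_pa = 4)
sc <- scan_geometry(1.4375, 96)
q  <- scan_image(rod, b3, sc, plan = plan_acquisition(b3, sc, 35))
img <- reconstruct_idpc(add_shot_noise(q, 1))
locate_layerlines(layerline_profile(img), 23, orders = 1:2)$peaks
#>   order  frequency   height raw_height background detected
#> 1     1 0.04405022 75810237  103052240   27242003     TRUE
#> 2     2 0.08790357  7227918   16337791    9109872     TRUE
```

The two detected peaks sit at 1/23 and 1/11.5 per Angstrom - the helical
pitch and its second order - and `1/0.0879 = 11.4 A` recovers the
second-order spacing to within one frequency sample. The frame time of
13.2 s is what 4 pA and 35 e-/A^2 imply at 0.75 A pixels for a 4096^2
raster; the parameter table reproduces the standard planning numbers for
300 kV imaging.

A thin command-line interface over the same functions is installed at
`inst/cli/idpcstem` (subcommands `plan`, `fixture`, `simulate`,
`reconstruct`, `analyze`), reading and writing MRC2014 images with JSON
sidecars.

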