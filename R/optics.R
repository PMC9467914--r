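#' Beam parameters
#'
#' Bundles the electron-optical state of the instrument: accelerating
#' voltage, convergence semi-angle (CSA) of the focused probe, lens
#' aberrations and beam current. The wavelength is derived from the voltage
#' and stored in pm.
#'
#' @param voltage_kv Accelerating voltage, kV.
#' @param csa_mrad Convergence semi-angle \eqn{\alpha} of the probe, mrad.
#' @param defocus_nm Defocus \eqn{\Delta f}, nm. Positive values are
#'   underfocus: with the aberration phase used here
#'   (\eqn{\chi = (2\pi/\lambda)(-\Delta f\,\theta^2/2 + C_s\theta^4/4)}),
#'   a positive defocus moves the beam waist upstream of the nominal plane
#'   (towards the source), i.e. the nominal plane sits below focus.
#' @param cs_mm Spherical aberration coefficient \eqn{C_s}, mm
#'   (non-negative; 2.7 mm for a wide-gap pole piece).
#' @param current_pa Beam current, pA.
#' @return An object of class `beam_parameters`.
#' @examples
#' beam_parameters(300, 2.0)
#' @export
beam_parameters <- function(voltage_kv, csa_mrad, defocus_nm = 0,
                            cs_mm = 0, current_pa = 4) {
  stopifnot(voltage_kv > 0, csa_mrad > 0, cs_mm >= 0, current_pa >= 0)
  structure(
    list(
      voltage_kv = voltage_kv,
      wavelength_pm = electron_wavelength(voltage_kv),
      csa_mrad = csa_mrad,
      defocus_nm = defocus_nm,
      cs_mm = cs_mm,
      current_pa = current_pa
    ),
    class = "beam_parameters"
  )
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf(
    "<beam_parameters> %g kV (lambda %.4g pm), CSA %g mrad, defocus %g nm, Cs %g mm, %g pA\n",
    x$voltage_kv, x$wavelength_pm, x$csa_mrad, x$defocus_nm, x$cs_mm, x$current_pa))
  invisible(x)
}

# wavelength in Angstrom for internal geometry (1 pm = 0.01 A)
.lambda_A <- function(beam) beam$wavelength_pm * 1e-2
.alpha_rad <- function(beam) beam$csa_mrad * 1e-3

#' Diffraction-limited STEM resolution
#'
#' The maximum theoretical STEM resolution \eqn{\lambda/(2\alpha)} set by the
#' convergence semi-angle: information beyond spatial frequency
#' \eqn{2\alpha/\lambda} is not transferred. This is also the "effective
#' probe diameter" quoted for a given CSA (4.9 A at 300 kV, 2.0 mrad); the
#' numerically measured Airy FWHM of the probe intensity
#' (about \eqn{0.51\lambda/\alpha}) is a different, smaller quantity and is
#' available from [probe_fwhm()].
#'
#' @param beam A [beam_parameters()] object.
#' @return Resolution in Angstrom.
#' @export
max_resolution <- function(beam) .lambda_A(beam) / (2 * .alpha_rad(beam))

#' Depth of focus of the probe
#'
#' \eqn{2\lambda/\alpha^2}: the axial extent over which the focused probe
#' stays narrow. Specimens thicker than this are depth-sectioned rather than
#' projected. 194 nm at 300 kV and 4.5 mrad.
#'
#' @inheritParams max_resolution
#' @return Depth of focus in nm.
#' @export
depth_of_focus <- function(beam) {
  2 * (beam$wavelength_pm * 1e-3) / .alpha_rad(beam)^2
}

#' Pixel size required for maximum STEM resolution
#'
#' Nyquist sampling of the \eqn{\lambda/(2\alpha)} cutoff requires a scan
#' step of at most \eqn{\lambda/(4\alpha)}; coarser scanning aliases
#' transferred frequencies back below Nyquist.
#'
#' @inheritParams max_resolution
#' @return Required pixel size in Angstrom (exact value, not rounded;
#'   [stem_parameter_table()] applies the 2-significant-figure display
#'   rounding used in planner tables).
#' @export
required_pixel_size <- function(beam) max_resolution(beam) / 2

#' Planner table of critical STEM imaging parameters
#'
#' Tabulates, per convergence semi-angle, the diffraction-limited
#' resolution \eqn{\lambda/(2\alpha)}, the required (Nyquist) pixel size
#' \eqn{\lambda/(4\alpha)} and the depth of focus \eqn{2\lambda/\alpha^2}.
#' Following the convention of printed parameter tables, the wavelength is
#' rounded to 4 significant figures in pm before the derived columns are
#' formed, and each column is rounded half-up to its display precision
#' (2 significant figures for the lengths, whole nm for depth of focus).
#'
#' @param voltage_kv Accelerating voltage, kV.
#' @param csa_mrad Vector of convergence semi-angles, mrad.
#' @param rounded Apply display rounding (default `TRUE`); `FALSE` returns
#'   the raw values.
#' @return A data.frame with columns `csa_mrad`, `resolution_A`,
#'   `pixel_size_A`, `depth_of_focus_nm`, and attribute `wavelength_pm`.
#' @examples
#' stem_parameter_table(300, c(2, 3, 3.5, 4, 4.5))
#' @export
stem_parameter_table <- function(voltage_kv, csa_mrad = c(2, 3, 3.5, 4, 4.5),
                                 rounded = TRUE) {
  lam_pm <- signif(electron_wavelength(voltage_kv), 4)
  a <- csa_mrad * 1e-3
  res <- (lam_pm * 1e-2) / (2 * a)
  pix <- res / 2
  dof <- 2 * (lam_pm * 1e-3) / a^2
  if (rounded) {
    res <- .round_half_up_signif(res, 2)
    pix <- .round_half_up_signif(pix, 2)
    dof <- .round_half_up(dof, 0)
  }
  out <- data.frame(
    csa_mrad = csa_mrad,
    resolution_A = res,
    pixel_size_A = pix,
    depth_of_focus_nm = dof
  )
  attr(out, "wavelength_pm") <- lam_pm
  out
}

# round-half-up (away from the IEC half-even default) used for planner tables
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
.round_half_up_signif <- function(x, digits = 2) {
  mag <- floor(log10(abs(x)))
  .round_half_up(x, digits - 1 - mag)
}

#' Scan geometry
#'
#' The raster geometry of an acquisition: pixel size, image side length and
#' scan rotation (the angle of the scan frame measured in the detector
#' frame). The field of view is `n_pixels * pixel_size`.
#'
#' @param pixel_size_A Scan step / micrograph pixel size, Angstrom.
#' @param n_pixels Pixels per image side (square raster), at least 2.
#' @param scan_rotation_deg Scan rotation, degrees.
#' @return An object of class `scan_geometry` with derived field `fov_A`.
#' @export
scan_geometry <- function(pixel_size_A, n_pixels, scan_rotation_deg = 0) {
  stopifnot(pixel_size_A > 0, n_pixels >= 2)
  n_pixels <- as.integer(n_pixels)
  structure(
    list(
      pixel_size_A = pixel_size_A,
      n_pixels = n_pixels,
      fov_A = n_pixels * pixel_size_A,
      scan_rotation_deg = scan_rotation_deg
    ),
    class = "scan_geometry"
  )
}

#' Plan a dose-limited acquisition
#'
#' From the total electron dose (TED) relation
#' \deqn{TED = I\,t_{dwell} / PS^2 = I\,t_{frame} / FOV^2}
#' computes the dwell time that delivers `total_dose` at the given beam
#' current and pixel size, the resulting frame time
#' \eqn{t_{frame} = N^2 t_{dwell}}, the expected electrons per dwell, and
#' whether the scan is aliased (pixel size exceeds \eqn{\lambda/(4\alpha)}).
#'
#' @param beam A [beam_parameters()] object (current must be positive).
#' @param scan A [scan_geometry()] object.
#' @param total_dose Electron dose, e-/A^2.
#' @param flyback_us Per-line overhead added to the frame time, microseconds
#'   per scan line (default 0: pure scan time).
#' @return An object of class `scan_plan` with fields `dwell_time_us`,
#'   `frame_time_s`, `total_dose`, `electrons_per_dwell`, `aliased`.
#' @examples
#' b <- beam_parameters(300, 4.5, current_pa = 4)
#' plan_acquisition(b, scan_geometry(0.75, 4096), 35)
#' @export
plan_acquisition <- function(beam, scan, total_dose, flyback_us = 0) {
  stopifnot(inherits(beam, "beam_parameters"), inherits(scan, "scan_geometry"))
  if (total_dose <= 0) stop("`total_dose` must be positive", call. = FALSE)
  if (beam$current_pa <= 0) stop("cannot plan with zero beam current", call. = FALSE)
  eps <- .electrons_per_second(beam$current_pa)
  dwell_s <- total_dose * scan$pixel_size_A^2 / eps
  frame_s <- scan$n_pixels^2 * dwell_s + scan$n_pixels * flyback_us * 1e-6
  structure(
    list(
      dwell_time_us = dwell_s * 1e6,
      frame_time_s = frame_s,
      total_dose = total_dose,
      electrons_per_dwell = total_dose * scan$pixel_size_A^2,
      aliased = scan$pixel_size_A > required_pixel_size(beam),
      beam = beam,
      scan = scan
    ),
    class = "scan_plan"
  )
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(
    "<scan_plan> dwell %.4g us, frame %.4g s, dose %g e-/A^2 (%.3g e-/dwell)%s\n",
    x$dwell_time_us, x$frame_time_s, x$total_dose, x$electrons_per_dwell,
    if (x$aliased) " [ALIASED]" else ""))
  invisible(x)
}

#' Total electron dose delivered by a plan
#'
#' Inverts [plan_acquisition()]: recomputes the TED from current, dwell time
#' and pixel size. Round-trips to the planned dose to 1e-9 relative.
#'
#' @param beam A [beam_parameters()] object.
#' @param dwell_time_us Dwell time, microseconds.
#' @param pixel_size_A Pixel size, Angstrom.
#' @return Dose in e-/A^2.
#' @export
total_electron_dose <- function(beam, dwell_time_us, pixel_size_A) {
  .electrons_per_second(beam$current_pa) * dwell_time_us * 1e-6 / pixel_size_A^2
}

#' Smallest convergence semi-angle whose depth of focus drops below a thickness
#'
#' Scans integer CSAs upward and returns the first whose depth of focus
#' \eqn{2\lambda/\alpha^2} is smaller than the given specimen thickness -
#' i.e. the first CSA that no longer yields complete projections of a
#' specimen that thick. 9 mrad for 60 nm ice at 300 kV.
#'
#' @param voltage_kv Accelerating voltage, kV.
#' @param thickness_nm Specimen (ice) thickness, nm.
#' @param max_csa_mrad Upper bound of the integer scan.
#' @return CSA in mrad (integer).
#' @export
min_csa_below_thickness <- function(voltage_kv, thickness_nm, max_csa_mrad = 100) {
  stopifnot(thickness_nm > 0)
  for (a in seq_len(max_csa_mrad)) {
    if (depth_of_focus(beam_parameters(voltage_kv, a)) < thickness_nm) return(a)
  }
  stop("no CSA up to ", max_csa_mrad, " mrad has depth of focus below ",
       thickness_nm, " nm", call. = FALSE)
}

#' Construct the focused probe wave field
#'
#' Inverse Fourier transform of a top-hat aperture of semi-angle
#' \eqn{\alpha} carrying the aberration phase
#' \eqn{\chi(\theta) = (2\pi/\lambda)(-\Delta f\,\theta^2/2 + C_s\theta^4/4)},
#' normalized to unit total intensity. The grid must sample the aperture:
#' `grid_spacing <= lambda/(4 alpha)`.
#'
#' @param beam A [beam_parameters()] object.
#' @param grid_spacing_A Real-space grid spacing, Angstrom.
#' @param grid_size Grid points per side.
#' @return An object of class `probe_field` with fields `amplitude`
#'   (complex matrix), `grid_spacing_A`, `plane_z_A`, `beam`.
#' @export
make_probe <- function(beam, grid_spacing_A, grid_size) {
  lam <- .lambda_A(beam)
  alpha <- .alpha_rad(beam)
  if (grid_spacing_A > lam / (4 * alpha) * (1 + 1e-9)) {
    stop(sprintf(
      "grid spacing %.3g A undersamples the %.3g mrad aperture (need <= %.3g A)",
      grid_spacing_A, beam$csa_mrad, lam / (4 * alpha)), call. = FALSE)
  }
  g <- fft_freq_grids(grid_size, grid_size, grid_spacing_A)
  theta2 <- (lam^2) * (g$kx^2 + g$ky^2)  # theta^2 in rad^2
  ap <- theta2 <= alpha^2
  df_A <- beam$defocus_nm * 10
  cs_A <- beam$cs_mm * 1e7
  chi <- (2 * pi / lam) * (-df_A * theta2 / 2 + cs_A * theta2^2 / 4)
  psi_k <- matrix(0 + 0i, grid_size, grid_size)
  psi_k[ap] <- exp(1i * chi[ap])
  psi <- fftshift2(ifft2(psi_k))  # centre the probe on the grid
  psi <- psi / sqrt(sum(Mod(psi)^2))
  border <- max(Mod(psi[c(1, grid_size), ])^2, Mod(psi[, c(1, grid_size)])^2)
  if (border > 1e-4 * max(Mod(psi)^2)) {
    warning("probe intensity at the grid border exceeds 1e-4 of the peak; ",
            "enlarge the grid", call. = FALSE)
  }
  structure(
    list(amplitude = psi, grid_spacing_A = grid_spacing_A, plane_z_A = 0,
         beam = beam),
    class = "probe_field"
  )
}

#' Numerically measured probe intensity FWHM
#'
#' Full width at half maximum of the in-plane probe intensity, measured on a
#' fine radial profile through the peak. For an aberration-free aperture
#' this is the Airy width, about \eqn{0.51 \lambda/\alpha} - roughly half
#' the "effective probe diameter" \eqn{\lambda/(2\alpha)}.
#'
#' @param probe A [make_probe()] object.
#' @return FWHM in Angstrom.
#' @export
probe_fwhm <- function(probe) {
  inten <- Mod(probe$amplitude)^2
  pk <- which(inten == max(inten), arr.ind = TRUE)[1, ]
  f <- 8L
  prof <- .fourier_upsample1(inten[, pk[2]], f)
  prof <- prof / max(prof)
  fine_dx <- probe$grid_spacing_A / f
  p <- which.max(prof)
  m <- length(prof)
  cross <- function(step) {
    i <- p
    d <- 0
    repeat {
      j <- ((i - 1 + step) %% m) + 1
      d <- d + 1
      if (prof[j] < 0.5) {
        frac <- (prof[i] - 0.5) / (prof[i] - prof[j])
        return(d - 1 + frac)
      }
      i <- j
      if (d >= m) return(m / 2) # never drops below half max
    }
  }
  (cross(1L) + cross(-1L)) * fine_dx
}

# band-limited (Fourier) upsampling of a periodic 1D signal by factor f
.fourier_upsample1 <- function(x, f) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * f
  Y <- rep(0 + 0i, m)
  h <- ceiling(n / 2)
  Y[seq_len(h)] <- X[seq_len(h)]
  if (n - h > 0) Y[(m - (n - h) + 1):m] <- X[(h + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Axial extent of the focused probe
#'
#' Propagates the probe along z by the angular-spectrum method and returns
#' the axial range over which the peak in-plane intensity stays at or above
#' 80 percent of its in-focus value. Proportional to the depth of focus
#' \eqn{2\lambda/\alpha^2}.
#'
#' @param beam A [beam_parameters()] object.
#' @param grid_spacing_A Grid spacing for the numerical probe; defaults to
#'   an adequate sampling of the aperture.
#' @param grid_size Grid side, default 256.
#' @param n_z Number of z samples on each side of focus.
#' @return Extent in nm.
#' @export
probe_axial_extent <- function(beam, grid_spacing_A = NULL, grid_size = 256,
                               n_z = 60) {
  lam <- .lambda_A(beam)
  alpha <- .alpha_rad(beam)
  if (is.null(grid_spacing_A)) grid_spacing_A <- lam / (5 * alpha)
  b0 <- beam
  b0$defocus_nm <- 0
  probe <- make_probe(b0, grid_spacing_A, grid_size)
  g <- fft_freq_grids(grid_size, grid_size, grid_spacing_A)
  k2 <- g$kx^2 + g$ky^2
  psi_k <- fft2(probe$amplitude)
  dof_A <- depth_of_focus(beam) * 10
  zs <- seq(-1.5 * dof_A, 1.5 * dof_A, length.out = 2 * n_z + 1)
  peak <- vapply(zs, function(z) {
    max(Mod(ifft2(psi_k * exp(-1i * pi * lam * z * k2)))^2)
  }, numeric(1))
  peak <- peak / peak[n_z + 1]
  inside <- peak >= 0.8
  dz <- zs[2] - zs[1]
  sum(inside) * dz / 10  # nm
}
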