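#' Multislice propagation of the probe through a specimen
#'
#' Alternates phase gratings \eqn{t_s(r) = \exp(i\sigma V_s(r))} with
#' Fresnel propagation over the slice thickness. Both operations are
#' unitary, so the total intensity is conserved. The probe and specimen
#' must share grid spacing and shape.
#'
#' @param probe A [make_probe()] object (unit total intensity).
#' @param specimen A [specimen_potential()].
#' @param sigma Interaction constant, rad/(V*A); defaults to the
#'   relativistic value for the probe's voltage.
#' @return Complex matrix: the exit wave at the bottom of the specimen.
#' @export
multislice_exit_wave <- function(probe, specimen, sigma = NULL) {
  stopifnot(inherits(probe, "probe_field"), inherits(specimen, "specimen_potential"))
  d <- dim(specimen$slices)
  if (!all(dim(probe$amplitude) == d[1:2])) {
    stop("probe and specimen grids do not match", call. = FALSE)
  }
  if (abs(probe$grid_spacing_A - specimen$voxel_xy_A) > 1e-9) {
    stop("probe and specimen grid spacings do not match", call. = FALSE)
  }
  if (specimen$slice_dz_A <= 0) stop("slice_dz must be positive", call. = FALSE)
  if (is.null(sigma)) sigma <- interaction_sigma(probe$beam$voltage_kv)
  lam <- .lambda_A(probe$beam)
  g <- fft_freq_grids(d[1], d[2], specimen$voxel_xy_A)
  prop <- exp(-1i * pi * lam * specimen$slice_dz_A * (g$kx^2 + g$ky^2))
  psi <- probe$amplitude
  for (s in seq_len(d[3])) {
    psi <- ifft2(fft2(psi * exp(1i * sigma * specimen$slices[, , s])) * prop)
  }
  psi
}

#' Far-field diffraction pattern (CBED) of an exit wave
#'
#' Squared modulus of the Fourier transform of the wave, with angular axes
#' calibrated by the wavelength and grid spacing
#' (\eqn{\theta = \lambda k}). Parseval-consistent: the total CBED
#' intensity equals the real-space total intensity. Stored centred
#' (DC in the middle).
#'
#' @param exit_wave Complex matrix (e.g. from [multislice_exit_wave()]).
#' @param grid_spacing_A Real-space grid spacing, Angstrom.
#' @param beam A [beam_parameters()] (for the angular calibration).
#' @return An object of class `cbed_pattern` with fields `intensity`
#'   (centred grid) and `angular_spacing_mrad`.
#' @export
cbed <- function(exit_wave, grid_spacing_A, beam) {
  G <- fft2(exit_wave)
  inten <- Re(G * Conj(G)) / length(G)
  lam <- .lambda_A(beam)
  structure(
    list(intensity = fftshift2(inten),
         angular_spacing_mrad = lam / (nrow(inten) * grid_spacing_A) * 1e3),
    class = "cbed_pattern"
  )
}

# angular coordinate grids (mrad, centred layout) for a cbed_pattern
.cbed_theta <- function(pattern) {
  n1 <- nrow(pattern$intensity); n2 <- ncol(pattern$intensity)
  tx <- (seq_len(n1) - (floor(n1 / 2) + 1)) * pattern$angular_spacing_mrad
  ty <- (seq_len(n2) - (floor(n2 / 2) + 1)) * pattern$angular_spacing_mrad
  list(tx = matrix(tx, n1, n2), ty = matrix(ty, n1, n2, byrow = TRUE))
}

#' Centre of mass of a CBED pattern
#'
#' Intensity-weighted first moment over scattering angle - the ideal COM
#' signal that the segmented detector approximates.
#'
#' @param pattern A [cbed()] pattern.
#' @return Length-2 numeric (x, y), mrad.
#' @export
com <- function(pattern) {
  tot <- sum(pattern$intensity)
  if (tot <= 0) stop("zero total intensity", call. = FALSE)
  th <- .cbed_theta(pattern)
  c(sum(pattern$intensity * th$tx), sum(pattern$intensity * th$ty)) / tot
}

#' Quadrant detector signals for one CBED pattern
#'
#' Integrates the pattern over the four quadrant masks (annulus between
#' hole and outer radius; area-weighted edge pixels), plus the hole, the
#' flux beyond the detector, and an optional ADF annulus outside the
#' bright-field disk. The quadrants, hole and outside flux partition the
#' total intensity.
#'
#' @param pattern A [cbed()] pattern.
#' @param det A [detector_geometry()].
#' @return Named list `A`, `B`, `C`, `D`, `adf`, `hole`, `outside`, `total`.
#' @export
quadrant_signals <- function(pattern, det) {
  th <- .cbed_theta(pattern)
  if (det$outer_radius_mrad > max(abs(th$tx))) {
    stop("detector extends beyond the simulated angular field", call. = FALSE)
  }
  m <- .detector_masks(det, th$tx, th$ty)
  I <- pattern$intensity
  list(A = sum(I * m$A), B = sum(I * m$B), C = sum(I * m$C), D = sum(I * m$D),
       adf = sum(I * m$adf), hole = sum(I * m$hole),
       outside = sum(I * m$outside), total = sum(I))
}

#' Quadrant image stack
#'
#' Container for the four quadrant images over scan positions (expected or
#' Poisson-sampled electron counts per dwell), the optional ADF image, and
#' optionally the ideal COM component images recorded during simulation.
#'
#' @param A,B,C,D Real matrices over scan positions.
#' @param pixel_size_A Scan pixel size.
#' @param scan_rotation_deg Scan rotation used during acquisition.
#' @param adf Optional ADF image.
#' @param com_x,com_y Optional ideal-COM component images (mrad).
#' @param electrons_per_dwell Expected electrons per dwell used for scaling.
#' @param noisy Whether the values are Poisson counts.
#' @return An object of class `quadrant_images`.
#' @export
quadrant_images <- function(A, B, C, D, pixel_size_A, scan_rotation_deg = 0,
                            adf = NULL, com_x = NULL, com_y = NULL,
                            electrons_per_dwell = 1, noisy = FALSE) {
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(C)), all(dim(A) == dim(D)))
  structure(
    list(A = A, B = B, C = C, D = D, adf = adf, com_x = com_x, com_y = com_y,
         pixel_size_A = pixel_size_A, scan_rotation_deg = scan_rotation_deg,
         electrons_per_dwell = electrons_per_dwell, noisy = noisy),
    class = "quadrant_images"
  )
}

#' @export
print.quadrant_images <- function(x, ...) {
  cat(sprintf("<quadrant_images> %d x %d scan, %g A/px, rotation %g deg, %s\n",
              nrow(x$A), ncol(x$A), x$pixel_size_A, x$scan_rotation_deg,
              if (x$noisy) "Poisson counts" else "expected counts"))
  invisible(x)
}

#' Simulate a full scan through a specimen
#'
#' Line-by-line raster: at each scan position the probe is shifted by a
#' Fourier phase ramp (sub-pixel exact), propagated through the specimen by
#' the multislice method, transformed to the far field, and integrated over
#' the quadrant masks. Quadrant values are expected electron counts per
#' dwell (`electrons_per_dwell` from the plan; 1 if no plan is given). A
#' non-zero scan rotation rotates the detector-frame quadrant boundaries
#' relative to the scan axes, exactly as a rotated raster does on the
#' instrument.
#'
#' The specimen grid is treated as periodic; the scan raster (`scan`) is
#' centred on the specimen field of view and may use a different step than
#' the simulation grid.
#'
#' @param specimen A [specimen_potential()].
#' @param beam A [beam_parameters()].
#' @param scan A [scan_geometry()].
#' @param det A [detector_geometry()]; default: camera length set for the
#'   beam via [set_camera_length()].
#' @param plan Optional [plan_acquisition()] result; supplies
#'   `electrons_per_dwell` and the aliasing warning.
#' @param record_com Also record the ideal COM components at each position.
#' @param record_adf Also record the ADF annulus signal.
#' @param sigma Interaction constant override, rad/(V*A).
#' @return A [quadrant_images()] object.
#' @export
scan_image <- function(specimen, beam, scan, det = NULL, plan = NULL,
                       record_com = FALSE, record_adf = FALSE, sigma = NULL) {
  stopifnot(inherits(specimen, "specimen_potential"),
            inherits(beam, "beam_parameters"), inherits(scan, "scan_geometry"))
  if (is.null(det)) det <- set_camera_length(detector_geometry(), beam)
  if (!is.null(plan) && plan$aliased) {
    warning("scan pixel size exceeds lambda/(4 alpha): the image will be aliased",
            call. = FALSE)
  }
  epd <- if (is.null(plan)) 1 else plan$electrons_per_dwell
  d <- dim(specimen$slices)
  n1 <- d[1]; n2 <- d[2]; nz <- d[3]
  if (n1 != n2) stop("scan_image requires a square specimen grid", call. = FALSE)
  dxy <- specimen$voxel_xy_A
  if (scan$fov_A > n1 * dxy + 1e-6 || scan$fov_A > n2 * dxy + 1e-6) {
    stop("scan field of view exceeds the specimen extent", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- interaction_sigma(beam$voltage_kv)
  lam <- .lambda_A(beam)

  # periodic-grid convention: the probe's wrapped Airy tail is part of the
  # model here, so the border diagnostic of make_probe does not apply
  probe <- suppressWarnings(make_probe(beam, dxy, n1))
  Fp <- fft2(probe$amplitude)
  g <- fft_freq_grids(n1, n2, dxy)
  prop <- exp(-1i * pi * lam * specimen$slice_dz_A * (g$kx^2 + g$ky^2))
  trans <- vector("list", nz)
  for (s in seq_len(nz)) trans[[s]] <- exp(1i * sigma * specimen$slices[, , s])

  # detector masks on the unshifted frequency grid (theta = lambda k, mrad)
  tx_u <- lam * g$kx * 1e3
  ty_u <- lam * g$ky * 1e3
  if (det$outer_radius_mrad > max(abs(tx_u))) {
    stop("detector extends beyond the simulated angular field", call. = FALSE)
  }
  masks <- .detector_masks(det, tx_u, ty_u,
                           offset_deg = det$quadrant_offset_deg - scan$scan_rotation_deg)
  mA <- as.vector(masks$A); mB <- as.vector(masks$B)
  mC <- as.vector(masks$C); mD <- as.vector(masks$D)
  mADF <- as.vector(masks$adf)

  ns <- scan$n_pixels
  # raster positions centred on the specimen FOV, relative to the probe
  # centre (make_probe centres the probe at grid index n %/% 2 + 1)
  cx <- (n1 %/% 2) * dxy
  cyc <- (n2 %/% 2) * dxy
  # pixel i sits at offset + (i-1) * step: a scan that covers the whole
  # specimen at the grid step lands exactly on the object grid points
  x0 <- (n1 * dxy - scan$fov_A) / 2 + (seq_len(ns) - 1) * scan$pixel_size_A - cx
  y0 <- (n2 * dxy - scan$fov_A) / 2 + (seq_len(ns) - 1) * scan$pixel_size_A - cyc
  A <- B <- C <- D <- matrix(0, ns, ns)
  adf <- if (record_adf) matrix(0, ns, ns) else NULL
  cx <- cy <- if (record_com) matrix(0, ns, ns) else NULL
  ntot <- n1 * n2
  # Fp pre-multiplied by the x phase ramp per scan column (recycles down
  # columns); the y ramp is applied as a per-row constant matrix
  Fpx <- lapply(x0, function(x) Fp * exp(-2i * pi * g$kx[, 1] * x))
  ramp_y <- lapply(y0, function(y) {
    matrix(exp(-2i * pi * g$ky[1, ] * y), n1, n2, byrow = TRUE)
  })
  # inverse transforms in the hot loop are left unnormalized; the final
  # intensity is rescaled once by ntot^-(2 nz + 3)
  nrm <- ntot^-(2 * nz + 3)
  for (jy in seq_len(ns)) {       # line-by-line raster
    ry <- ramp_y[[jy]]
    for (jx in seq_len(ns)) {
      psi <- stats::fft(Fpx[[jx]] * ry, inverse = TRUE)
      for (s in seq_len(nz)) {
        psi <- stats::fft(stats::fft(psi * trans[[s]]) * prop, inverse = TRUE)
      }
      G <- stats::fft(psi)
      gr <- Re(G); gi <- Im(G)
      Iv <- (gr * gr + gi * gi) * nrm
      A[jx, jy] <- sum(Iv * mA); B[jx, jy] <- sum(Iv * mB)
      C[jx, jy] <- sum(Iv * mC); D[jx, jy] <- sum(Iv * mD)
      if (record_adf) adf[jx, jy] <- sum(Iv * mADF)
      if (record_com) {
        tot <- sum(Iv)
        cx[jx, jy] <- sum(Iv * tx_u) / tot
        cy[jx, jy] <- sum(Iv * ty_u) / tot
      }
    }
  }
  quadrant_images(A * epd, B * epd, C * epd, D * epd,
                  pixel_size_A = scan$pixel_size_A,
                  scan_rotation_deg = scan$scan_rotation_deg,
                  adf = if (record_adf) adf * epd else NULL,
                  com_x = cx, com_y = cy,
                  electrons_per_dwell = epd, noisy = FALSE)
}

#' Add quadrant-level shot noise
#'
#' Replaces each quadrant image (and the ADF image, if present) by an
#' independent Poisson draw with the expected counts as mean - noise enters
#' at the quadrant detection level. Reproducible under the given seed.
#'
#' @param q A [quadrant_images()] object with expected counts.
#' @param seed RNG seed.
#' @return A `quadrant_images` object with `noisy = TRUE`.
#' @export
add_shot_noise <- function(q, seed = 1) {
  stopifnot(inherits(q, "quadrant_images"))
  draw <- function(m) {
    if (is.null(m)) return(NULL)
    if (any(m < 0)) stop("expected counts must be non-negative", call. = FALSE)
    matrix(stats::rpois(length(m), as.vector(m)), nrow(m), ncol(m))
  }
  local_seed(seed, {
    q$A <- draw(q$A); q$B <- draw(q$B); q$C <- draw(q$C); q$D <- draw(q$D)
    q$adf <- draw(q$adf)
  })
  q$noisy <- TRUE
  q
}
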