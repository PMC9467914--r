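#' DPC vector field from quadrant images
#'
#' Forms the detector-frame differential phase contrast components from
#' opposite-quadrant differences - x: (A+D)-(B+C), y: (A+B)-(C+D) with
#' quadrants labeled counterclockwise from the detector +x axis - and
#' rotates them by `-scan_rotation` into the scan frame. Only at zero scan
#' rotation is the DPC vector a pure quadrant subtraction with no mixing of
#' components.
#'
#' @param q A [quadrant_images()] object.
#' @param scan_rotation_deg Scan rotation; defaults to the value recorded
#'   in `q`.
#' @return An object of class `dpc_field` with fields `x`, `y`,
#'   `frame = "scan"`, `pixel_size_A`.
#' @export
dpc_vector <- function(q, scan_rotation_deg = q$scan_rotation_deg) {
  stopifnot(inherits(q, "quadrant_images"))
  for (nm in c("A", "B", "C", "D")) {
    if (is.null(q[[nm]])) stop("missing quadrant image ", nm, call. = FALSE)
  }
  dx <- (q$A + q$D) - (q$B + q$C)
  dy <- (q$A + q$B) - (q$C + q$D)
  th <- -scan_rotation_deg * pi / 180
  structure(
    list(x = cos(th) * dx - sin(th) * dy,
         y = sin(th) * dx + cos(th) * dy,
         frame = "scan", pixel_size_A = q$pixel_size_A),
    class = "dpc_field"
  )
}

#' DPC field from recorded ideal-COM components
#'
#' Wraps the `com_x`/`com_y` images recorded by
#' [scan_image()]`(record_com = TRUE)` as a scan-frame DPC field (the COM
#' is simulated in scan coordinates directly).
#'
#' @param q A [quadrant_images()] object carrying COM images.
#' @return A `dpc_field`.
#' @export
com_vector <- function(q) {
  if (is.null(q$com_x) || is.null(q$com_y)) {
    stop("no COM images recorded; rerun scan_image(record_com = TRUE)", call. = FALSE)
  }
  structure(
    list(x = q$com_x, y = q$com_y, frame = "scan", pixel_size_A = q$pixel_size_A),
    class = "dpc_field"
  )
}

#' iDPC image container
#'
#' A real scalar image with mean zero (the k = 0 component is nulled by the
#' integration) and a pixel size.
#'
#' @param values Real matrix.
#' @param pixel_size_A Pixel size, Angstrom.
#' @return An object of class `idpc_image`.
#' @export
idpc_image <- function(values, pixel_size_A) {
  structure(list(values = values, pixel_size_A = pixel_size_A),
            class = "idpc_image")
}

#' @export
print.idpc_image <- function(x, ...) {
  cat(sprintf("<idpc_image> %d x %d px, %g A/px, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size_A,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integrate a DPC vector field to the iDPC image
#'
#' Fourier-space integration
#' \deqn{I(k) = \frac{k_x D_x(k) + k_y D_y(k)}{2\pi i\,(|k|^2 + \epsilon)}}
#' with the k = 0 term set to zero (mean-zero output). For a conservative
#' field \eqn{D = \nabla\phi} on a periodic grid this recovers \eqn{\phi}
#' up to an additive constant. The optional Tikhonov `eps` (units 1/A^2)
#' damps the low-frequency amplification for noisy data.
#'
#' @param d A [dpc_vector()] field in the scan frame.
#' @param eps Regularization, default 0.
#' @return An [idpc_image()].
#' @export
integrate_dpc <- function(d, eps = 0) {
  stopifnot(inherits(d, "dpc_field"))
  if (!identical(d$frame, "scan")) {
    stop("DPC field must be rotated into the scan frame before integration",
         call. = FALSE)
  }
  if (is.null(d$pixel_size_A)) stop("pixel size not set", call. = FALSE)
  n1 <- nrow(d$x); n2 <- ncol(d$x)
  g <- fft_freq_grids(n1, n2, d$pixel_size_A)
  k2 <- g$kx^2 + g$ky^2
  denom <- 2i * pi * (k2 + eps)
  num <- g$kx * fft2(d$x) + g$ky * fft2(d$y)
  Ik <- num / denom
  Ik[1, 1] <- 0
  if (eps == 0) Ik[k2 == 0] <- 0
  idpc_image(Re(ifft2(Ik)), d$pixel_size_A)
}

#' Gaussian high-pass preprocessing
#'
#' Multiplies the spectrum by `1 - G(k)` where `G` is the Gaussian low-pass
#' whose *real-space* kernel has the stated full width at half maximum
#' (default 251 A, the preprocessing used for display and particle
#' picking). Removes the DC term entirely. The image is mirror-padded by
#' 10 percent before filtering to suppress wrap-around.
#'
#' @param img An [idpc_image()] (or plain matrix plus `pixel_size_A`).
#' @param fwhm_A Real-space FWHM of the complementary low-pass kernel, A.
#' @param pixel_size_A Required if `img` is a bare matrix.
#' @param pad Mirror-pad fraction (0 disables padding).
#' @return An [idpc_image()].
#' @export
gaussian_highpass <- function(img, fwhm_A = 251, pixel_size_A = NULL, pad = 0.1) {
  if (inherits(img, "idpc_image")) {
    v <- img$values
    pixel_size_A <- img$pixel_size_A
  } else {
    v <- img
    if (is.null(pixel_size_A)) stop("pixel_size_A required", call. = FALSE)
  }
  if (fwhm_A <= 2 * pixel_size_A) {
    stop("high-pass FWHM is not resolvable on this grid", call. = FALSE)
  }
  n1 <- nrow(v); n2 <- ncol(v)
  p1 <- ceiling(n1 * pad); p2 <- ceiling(n2 * pad)
  vp <- .mirror_pad(v, p1, p2)
  sig_r <- fwhm_A / (2 * sqrt(2 * log(2)))
  g <- fft_freq_grids(nrow(vp), ncol(vp), pixel_size_A)
  G <- exp(-2 * pi^2 * sig_r^2 * (g$kx^2 + g$ky^2))
  out <- Re(ifft2(fft2(vp) * (1 - G)))
  out <- out[p1 + seq_len(n1), p2 + seq_len(n2)]
  idpc_image(out, pixel_size_A)
}

.mirror_pad <- function(v, p1, p2) {
  if (p1 == 0 && p2 == 0) return(v)
  n1 <- nrow(v); n2 <- ncol(v)
  ix <- c(rev(seq_len(min(p1, n1))), seq_len(n1),
          n1 + 1 - seq_len(min(p1, n1)))
  iy <- c(rev(seq_len(min(p2, n2))), seq_len(n2),
          n2 + 1 - seq_len(min(p2, n2)))
  v[ix, iy]
}

#' Reconstruct an iDPC image from quadrant images
#'
#' Convenience chain: [dpc_vector()] then [integrate_dpc()], optionally
#' followed by the [gaussian_highpass()] preprocessing.
#'
#' @param q A [quadrant_images()] object.
#' @param scan_rotation_deg Scan rotation (defaults to the recorded value).
#' @param eps Integration regularization.
#' @param highpass_fwhm_A If non-`NULL`, apply the Gaussian high-pass with
#'   this FWHM.
#' @return An [idpc_image()].
#' @export
reconstruct_idpc <- function(q, scan_rotation_deg = q$scan_rotation_deg,
                             eps = 0, highpass_fwhm_A = NULL) {
  img <- integrate_dpc(dpc_vector(q, scan_rotation_deg), eps = eps)
  if (!is.null(highpass_fwhm_A)) img <- gaussian_highpass(img, highpass_fwhm_A)
  img
}

#' Contrast transfer function of the iDPC imaging chain
#'
#' Computes the CTF numerically as the grating response of the full chain:
#' a weak random phase object with unit-magnitude spectrum is scanned
#' through the simulator (probe, multislice phase grating, far field,
#' quadrant or ideal-COM detection, DPC integration) and the CTF is the
#' ratio of output to input spectral amplitude at every frequency sample.
#' The CTF is defined so that, for a weak phase object,
#' `idpc = IFFT(CTF(k) * FFT(sigma * projected_potential))`.
#'
#' For an aberration-free beam the CTF is non-negative, decays towards the
#' cutoff `2 alpha / lambda` and vanishes beyond it; quadrant detection adds
#' a fourfold azimuthal modulation at low frequency which is absent for
#' ideal COM detection.
#'
#' @param beam A [beam_parameters()].
#' @param det A [detector_geometry()]; default camera-length-scaled for the
#'   beam.
#' @param n Grid side (scan and simulation grid coincide).
#' @param pixel_size_A Grid spacing; default `lambda/(5 alpha)` so the
#'   cutoff falls at 80 percent of Nyquist.
#' @param detector `"quadrant"`, `"com"`, or `"both"`.
#' @param phase_eps Peak phase of the probe object, rad (weak-phase regime).
#' @param seed Seed for the random test object.
#' @return An object of class `ctf_profile` with centred `values`,
#'   `frequency_spacing` (1/A) and `cutoff` (1/A); for `"both"`, a list
#'   with elements `quadrant` and `com`.
#' @export
compute_ctf <- function(beam, det = NULL, n = 64, pixel_size_A = NULL,
                        detector = c("quadrant", "com", "both"),
                        phase_eps = 1e-3, seed = 1) {
  detector <- match.arg(detector)
  lam <- .lambda_A(beam)
  alpha <- .alpha_rad(beam)
  if (is.null(pixel_size_A)) pixel_size_A <- lam / (5 * alpha)
  if (pixel_size_A > lam / (4 * alpha)) {
    stop("frequency grid does not reach the 2 alpha / lambda cutoff", call. = FALSE)
  }
  if (is.null(det)) det <- set_camera_length(detector_geometry(), beam)
  sigma <- interaction_sigma(beam$voltage_kv)
  # weak phase object with |spectrum| = 1 at every k (perfect conditioning)
  phi <- local_seed(seed, {
    ph <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
    x <- Re(ifft2(exp(1i * ph)))
    x / max(abs(x)) * phase_eps
  })
  spec <- specimen_potential(matrix(phi / sigma, n, n), pixel_size_A,
                             slice_dz_A = 1)
  scan <- scan_geometry(pixel_size_A, n)
  q <- scan_image(spec, beam, scan, det = det,
                  record_com = (detector != "quadrant"))
  Fin <- fft2(phi)
  mk <- function(img) {
    ratio <- Re(fft2(img$values) / Fin)
    ratio[1, 1] <- 0
    structure(
      list(values = fftshift2(ratio),
           frequency_spacing = 1 / (n * pixel_size_A),
           cutoff = 2 * alpha / lam,
           beam = beam),
      class = "ctf_profile"
    )
  }
  out_q <- if (detector != "com") mk(integrate_dpc(dpc_vector(q))) else NULL
  out_c <- if (detector != "quadrant") mk(integrate_dpc(com_vector(q))) else NULL
  switch(detector,
         quadrant = out_q,
         com = out_c,
         both = list(quadrant = out_q, com = out_c))
}

#' @export
print.ctf_profile <- function(x, ...) {
  cat(sprintf("<ctf_profile> %d x %d samples, df %.4g 1/A, cutoff %.4g 1/A\n",
              nrow(x$values), ncol(x$values), x$frequency_spacing, x$cutoff))
  invisible(x)
}

# radial frequency grid (centred layout) of a ctf_profile / power spectrum
.centred_k <- function(n1, n2, df) {
  kx <- (seq_len(n1) - (floor(n1 / 2) + 1)) * df
  ky <- (seq_len(n2) - (floor(n2 / 2) + 1)) * df
  list(kx = matrix(kx, n1, n2), ky = matrix(ky, n1, n2, byrow = TRUE))
}

#' Azimuthal profile and fourfold modulation of a CTF
#'
#' Averages a centred frequency-grid image over azimuth within a radial
#' band and reports the relative magnitude of the \eqn{4\theta} Fourier
#' coefficient - the quantitative measure of the fourfold star pattern that
#' quadrant detection imprints at low spatial frequency.
#'
#' @param ctf A [compute_ctf()] profile.
#' @param k_band Radial band as a fraction of the cutoff, length 2.
#' @param n_bins Azimuthal bins.
#' @return List with `theta`, `profile`, and `fourfold` (|c4| / c0).
#' @export
ctf_fourfold <- function(ctf, k_band = c(0.05, 0.35), n_bins = 72) {
  n1 <- nrow(ctf$values); n2 <- ncol(ctf$values)
  g <- .centred_k(n1, n2, ctf$frequency_spacing)
  r <- sqrt(g$kx^2 + g$ky^2)
  sel <- r >= k_band[1] * ctf$cutoff & r <= k_band[2] * ctf$cutoff
  az <- atan2(g$ky[sel], g$kx[sel]) %% (2 * pi)
  val <- ctf$values[sel]
  bin <- pmin(floor(az / (2 * pi) * n_bins) + 1, n_bins)
  prof <- vapply(seq_len(n_bins), function(b) mean(val[bin == b]), numeric(1))
  theta <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  ok <- is.finite(prof)
  c0 <- mean(prof[ok])
  c4 <- abs(mean(prof[ok] * exp(-4i * theta[ok])))
  list(theta = theta, profile = prof, fourfold = c4 / abs(c0))
}

#' Radial average of a CTF profile
#'
#' @param ctf A [compute_ctf()] profile.
#' @return data.frame with columns `k` (1/A) and `ctf`.
#' @export
ctf_radial <- function(ctf) {
  n1 <- nrow(ctf$values); n2 <- ncol(ctf$values)
  g <- .centred_k(n1, n2, ctf$frequency_spacing)
  r <- sqrt(g$kx^2 + g$ky^2)
  shell <- round(r / ctf$frequency_spacing)
  ks <- sort(unique(shell[shell <= max(shell)]))
  prof <- vapply(ks, function(s) mean(ctf$values[shell == s]), numeric(1))
  data.frame(k = ks * ctf$frequency_spacing, ctf = prof)
}

#' Weak-phase-object forward image
#'
#' Fast linear surrogate for the full scan simulation on thin weak
#' specimens: filters `sigma * projected_potential` by the CTF. Protein
#' (positive potential) renders white.
#'
#' @param projected Projected potential matrix (V*A), or a
#'   [specimen_potential()] (projected internally).
#' @param ctf A [compute_ctf()] profile on the same grid.
#' @param sigma Interaction constant; defaults to the CTF's beam voltage.
#' @return An [idpc_image()].
#' @export
wpo_image <- function(projected, ctf, sigma = NULL) {
  if (inherits(projected, "specimen_potential")) {
    projected <- project_potential(projected)
  }
  if (!all(dim(projected) == dim(ctf$values))) {
    stop("projection and CTF grids do not match", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- interaction_sigma(ctf$beam$voltage_kv)
  H <- ifftshift2(ctf$values)
  out <- Re(ifft2(fft2(sigma * projected) * H))
  px <- 1 / (nrow(projected) * ctf$frequency_spacing)
  idpc_image(out - mean(out), px)
}

#' Signal-to-noise ratio of a particle in an image
#'
#' `(mean(signal) - mean(background)) / sd(background)`. Returns `Inf` when
#' the background has zero variance (noiseless image).
#'
#' @param img An [idpc_image()] or matrix.
#' @param signal_mask,background_mask Disjoint logical masks.
#' @return SNR (possibly `Inf`).
#' @export
snr_of_particle <- function(img, signal_mask, background_mask) {
  v <- if (inherits(img, "idpc_image")) img$values else img
  if (!any(signal_mask) || !any(background_mask)) {
    stop("empty mask", call. = FALSE)
  }
  if (any(signal_mask & background_mask)) {
    stop("signal and background masks overlap", call. = FALSE)
  }
  s <- mean(v[signal_mask])
  b <- mean(v[background_mask])
  sdb <- stats::sd(v[background_mask])
  if (sdb == 0) return(Inf)
  (s - b) / sdb
}
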