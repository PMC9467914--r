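#' Power spectrum of an image
#'
#' Squared modulus of the discrete Fourier transform, centred. For real
#' input the spectrum is centrosymmetric; the total spectral power obeys
#' Parseval's identity.
#'
#' @param img An [idpc_image()] or a real matrix.
#' @param pixel_size_A Pixel size if `img` is a bare matrix.
#' @return An object of class `power_spectrum`: centred `values`,
#'   `frequency_spacing` (1/A; per axis for non-square images the first
#'   axis is used).
#' @export
power_spectrum <- function(img, pixel_size_A = NULL) {
  if (inherits(img, "idpc_image")) {
    v <- img$values
    pixel_size_A <- img$pixel_size_A
  } else {
    v <- img
    if (is.null(pixel_size_A)) pixel_size_A <- 1
  }
  G <- fft2(v)
  structure(
    list(values = fftshift2(Re(G * Conj(G))),
         frequency_spacing = 1 / (nrow(v) * pixel_size_A),
         frequency_spacing_y = 1 / (ncol(v) * pixel_size_A),
         pixel_size_A = pixel_size_A),
    class = "power_spectrum"
  )
}

#' Radial average of a power spectrum
#'
#' Averages over annuli one frequency sample wide.
#'
#' @param ps A [power_spectrum()] (square grid).
#' @return data.frame with columns `k` (1/A) and `power`.
#' @export
radial_average <- function(ps) {
  n1 <- nrow(ps$values); n2 <- ncol(ps$values)
  g <- .centred_k(n1, n2, ps$frequency_spacing)
  r <- sqrt(g$kx^2 + g$ky^2)
  shell <- round(r / ps$frequency_spacing)
  ks <- 0:max(shell)
  prof <- vapply(ks, function(s) {
    sel <- shell == s
    if (any(sel)) mean(ps$values[sel]) else NA_real_
  }, numeric(1))
  data.frame(k = ks * ps$frequency_spacing, power = prof)
}

# Catmull-Rom bicubic interpolation of matrix v at (real-valued) indices
.bicubic <- function(v, xi, yi) {
  n1 <- nrow(v); n2 <- ncol(v)
  x0 <- floor(xi); y0 <- floor(yi)
  tx <- xi - x0; ty <- yi - y0
  wcr <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    cbind(-0.5 * t3 + t2 - 0.5 * t,
          1.5 * t3 - 2.5 * t2 + 1,
          -1.5 * t3 + 2 * t2 + 0.5 * t,
          0.5 * t3 - 0.5 * t2)
  }
  wx <- wcr(tx); wy <- wcr(ty)
  out <- numeric(length(xi))
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  for (a in 0:3) {
    row <- numeric(length(xi))
    ia <- cl(x0 - 1L + a, n1)
    for (b in 0:3) {
      jb <- cl(y0 - 1L + b, n2)
      row <- row + wy[, b + 1] * v[cbind(ia, jb)]
    }
    out <- out + wx[, a + 1] * row
  }
  out
}

#' Extract rotated helical segments from a micrograph
#'
#' Cuts square boxes centred on picked helix coordinates and rotates each
#' so the helical axis is vertical (along the second image axis).
#' Interpolation is bicubic (Catmull-Rom). The in-plane `angle` is the
#' angle of the helix axis measured counterclockwise from the image y axis,
#' in degrees; `angle = 0` is a pure crop.
#'
#' @param img An [idpc_image()] or matrix.
#' @param coords data.frame with columns `x`, `y` (Angstrom, origin at the
#'   first pixel) and `angle` (degrees).
#' @param box_A Box side, Angstrom.
#' @param pixel_size_A Pixel size if `img` is a bare matrix.
#' @return List of square matrices (one per coordinate row).
#' @export
extract_segments <- function(img, coords, box_A, pixel_size_A = NULL) {
  if (inherits(img, "idpc_image")) {
    v <- img$values
    pixel_size_A <- img$pixel_size_A
  } else {
    v <- img
    if (is.null(pixel_size_A)) stop("pixel_size_A required", call. = FALSE)
  }
  bp <- as.integer(round(box_A / pixel_size_A))
  half <- (bp - 1) / 2
  u <- (seq_len(bp) - 1) - half
  lapply(seq_len(nrow(coords)), function(i) {
    th <- coords$angle[i] * pi / 180
    cxi <- coords$x[i] / pixel_size_A + 1
    cyi <- coords$y[i] / pixel_size_A + 1
    # rotate the sampling frame by the segment angle
    xs <- outer(u * cos(th), -u * sin(th), `+`) + cxi
    ys <- outer(u * sin(th), u * cos(th), `+`) + cyi
    if (min(xs) < 1 || max(xs) > nrow(v) || min(ys) < 1 || max(ys) > ncol(v)) {
      stop("segment box falls outside the micrograph after rotation",
           call. = FALSE)
    }
    matrix(.bicubic(v, as.vector(xs), as.vector(ys)), bp, bp)
  })
}

#' Collapsed layer-line profile
#'
#' Sums the power spectra of in-plane-rotated helical segments (axis
#' vertical) and collapses the sum in the direction orthogonal to the
#' helical axis - summing over `|k_x| <=` `halfwidth` - into a 1D profile
#' along the meridional frequency axis.
#'
#' @param segments List of square matrices (from [extract_segments()]), or
#'   a single matrix / [idpc_image()].
#' @param pixel_size_A Pixel size of the segments.
#' @param halfwidth Integration half-width orthogonal to the axis, 1/A
#'   (default 1/50).
#' @return An object of class `layerline_profile`: data.frame-like list
#'   with `frequency` (1/A, ascending, meridional), `value`, and `peaks`
#'   (filled by [locate_layerlines()]).
#' @export
layerline_profile <- function(segments, pixel_size_A = NULL, halfwidth = 1 / 50) {
  if (inherits(segments, "idpc_image")) {
    pixel_size_A <- segments$pixel_size_A
    segments <- list(segments$values)
  }
  if (is.matrix(segments)) segments <- list(segments)
  if (length(segments) == 0) stop("no segments", call. = FALSE)
  dims <- dim(segments[[1]])
  for (s in segments) {
    if (!all(dim(s) == dims)) stop("segments must share a shape", call. = FALSE)
  }
  if (is.null(pixel_size_A)) stop("pixel_size_A required", call. = FALSE)
  ps_sum <- Reduce(`+`, lapply(segments, function(s) {
    power_spectrum(s, pixel_size_A)$values
  }))
  n1 <- dims[1]; n2 <- dims[2]
  dfx <- 1 / (n1 * pixel_size_A)
  dfy <- 1 / (n2 * pixel_size_A)
  g <- list(kx = matrix((seq_len(n1) - (floor(n1 / 2) + 1)) * dfx, n1, n2))
  keep_x <- abs(g$kx[, 1]) <= halfwidth
  collapsed <- colSums(ps_sum[keep_x, , drop = FALSE])
  ky <- (seq_len(n2) - (floor(n2 / 2) + 1)) * dfy
  pos <- ky > 0
  structure(
    list(frequency = ky[pos], value = collapsed[pos],
         frequency_spacing = dfy, halfwidth = halfwidth,
         pixel_size_A = pixel_size_A, peaks = NULL),
    class = "layerline_profile"
  )
}

#' @export
print.layerline_profile <- function(x, ...) {
  cat(sprintf("<layerline_profile> %d samples, df %.4g 1/A\n",
              length(x$frequency), x$frequency_spacing))
  if (!is.null(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Locate layer-line peaks on a reference comb
#'
#' Searches windows of +/- `window` (fractional) around the expected comb
#' positions `n / spacing_A`, takes the maximum with quadratic (three-point)
#' interpolation, and subtracts a local linear background interpolated
#' between the window edges.
#'
#' @param profile A [layerline_profile()].
#' @param spacing_A Real-space repeat defining the comb (e.g. 23).
#' @param orders Integer orders to search.
#' @param window Fractional half-window around each expected frequency.
#' @return The profile with `peaks`: data.frame with columns `order`,
#'   `frequency`, `height` (background-subtracted), `raw_height`,
#'   `background`, `detected`.
#' @export
locate_layerlines <- function(profile, spacing_A, orders = 1:2, window = 0.15) {
  f <- profile$frequency
  v <- profile$value
  rows <- lapply(orders, function(n) {
    f0 <- n / spacing_A
    sel <- which(f >= f0 * (1 - window) & f <= f0 * (1 + window))
    if (length(sel) < 3) {
      # coarse frequency sampling: fall back to the 3 samples nearest f0
      i0 <- which.min(abs(f - f0))
      sel <- intersect((i0 - 1):(i0 + 1), seq_along(f))
    }
    if (length(sel) < 3) {
      return(data.frame(order = n, frequency = NA_real_, height = NA_real_,
                        raw_height = NA_real_, background = NA_real_,
                        detected = FALSE))
    }
    # pick by prominence above the window's linear baseline, not by raw
    # value: collapsed spectra ride a steeply falling noise background, and
    # the raw maximum is biased towards the window's low-frequency edge
    base <- v[sel[1]] + (v[sel[length(sel)]] - v[sel[1]]) *
      (f[sel] - f[sel[1]]) / (f[sel[length(sel)]] - f[sel[1]])
    i <- sel[which.max(v[sel] - base)]
    # quadratic interpolation around the maximum
    if (i > 1 && i < length(v)) {
      y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
      dd <- y0 - 2 * y1 + y2
      delta <- if (dd < 0) 0.5 * (y0 - y2) / dd else 0
      delta <- max(min(delta, 0.5), -0.5)
      fpk <- f[i] + delta * profile$frequency_spacing
      vpk <- y1 - 0.25 * (y0 - y2) * delta
    } else {
      fpk <- f[i]; vpk <- v[i]
    }
    # local linear background between the window edges
    e1 <- sel[1]; e2 <- sel[length(sel)]
    bg <- v[e1] + (v[e2] - v[e1]) * (fpk - f[e1]) / (f[e2] - f[e1])
    # prominence: the peak must rise above the fluctuations of the window
    # excluding the peak triplet, and carry non-negligible power relative
    # to the whole profile
    off_peak <- sel[!sel %in% (i - 1):(i + 1)]
    sd_res <- if (length(off_peak) >= 2) {
      line_off <- v[e1] + (v[e2] - v[e1]) * (f[off_peak] - f[e1]) / (f[e2] - f[e1])
      stats::sd(v[off_peak] - line_off)
    } else 0
    det <- is.finite(vpk) && i != e1 && i != e2 &&
      vpk > bg + 2 * sd_res &&
      (vpk - bg) > 1e-9 * max(v)
    data.frame(order = n, frequency = fpk, height = vpk - bg,
               raw_height = vpk, background = bg, detected = det)
  })
  profile$peaks <- do.call(rbind, rows)
  profile
}

#' Second-over-first layer-line peak ratio
#'
#' Background-subtracted peak-height ratio of the second-order over the
#' first-order layer line (e.g. 1/11.5 over 1/23 for a 23 A helical
#' repeat). Both peaks must be detected above their local background;
#' otherwise the result is `NA` with attribute `flag`.
#'
#' @param profile A [layerline_profile()] carrying peaks for orders 1 and 2
#'   (run [locate_layerlines()] first, or pass `spacing_A` to do it here).
#' @param spacing_A Optional repeat to (re)locate peaks.
#' @return Ratio II/I (numeric), or `NA` flagged with the missing order.
#' @export
peak_ratio <- function(profile, spacing_A = NULL) {
  if (!is.null(spacing_A)) {
    profile <- locate_layerlines(profile, spacing_A, orders = 1:2)
  }
  pk <- profile$peaks
  if (is.null(pk)) stop("no peaks located; run locate_layerlines()", call. = FALSE)
  p1 <- pk[pk$order == 1, ]; p2 <- pk[pk$order == 2, ]
  if (nrow(p1) != 1 || nrow(p2) != 1 || !p1$detected || !p2$detected) {
    out <- NA_real_
    attr(out, "flag") <- "peak not detected above local background"
    return(out)
  }
  p2$height / p1$height
}

#' Calibrate the pixel size against helical layer lines
#'
#' Matches detected layer-line frequencies to the expected comb
#' `{n / reference_spacing, n = 1, 2, ...}` by least squares in the scale
#' factor, and returns the corrected pixel size. A detected frequency
#' `f_obs = s * n / reference` means the true pixel size is `s` times the
#' nominal one.
#'
#' @param profile A [layerline_profile()].
#' @param reference_spacing_A Calibration repeat, default 22.03.
#' @param orders Comb orders used for matching.
#' @param window Fractional search window around each comb position.
#' @return List with `scale`, `pixel_size_A` (corrected), `n_peaks`,
#'   `residual` (RMS frequency misfit after scaling).
#' @export
calibrate_pixel_size <- function(profile, reference_spacing_A = 22.03,
                                 orders = 1:2, window = 0.15) {
  prof <- locate_layerlines(profile, reference_spacing_A, orders = orders,
                            window = window)
  pk <- prof$peaks[prof$peaks$detected, ]
  if (nrow(pk) == 0) stop("no layer line detected", call. = FALSE)
  g <- pk$order / reference_spacing_A
  s <- sum(pk$frequency * g) / sum(g^2)
  list(scale = s,
       pixel_size_A = profile$pixel_size_A * s,
       n_peaks = nrow(pk),
       residual = sqrt(mean((pk$frequency - s * g)^2)))
}

#' Guinier B factor from a radial amplitude profile
#'
#' Linear regression of `ln F` on `k^2` over the fit range;
#' `B = -4 * slope`. Sharpening multiplies amplitudes by `exp(+B k^2 / 4)`.
#'
#' @param k Spatial frequencies, 1/A.
#' @param amplitude Radial structure-factor amplitudes (positive).
#' @param fit_range Length-2 frequency range (1/A) used for the fit.
#' @return An object of class `guinier_fit`: `b_factor` (A^2),
#'   `intercept`, `fit_range`, `residual` (RMS of ln F residuals),
#'   `n_shells`.
#' @export
guinier_bfactor <- function(k, amplitude, fit_range = range(k[k > 0])) {
  sel <- k >= fit_range[1] & k <= fit_range[2]
  if (sum(sel) < 5) stop("need at least 5 shells in the fit range", call. = FALSE)
  if (any(amplitude[sel] <= 0)) {
    stop("amplitudes must be positive within the fit range", call. = FALSE)
  }
  fit <- stats::lm(log(amplitude[sel]) ~ I(k[sel]^2))
  structure(
    list(b_factor = -4 * unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         fit_range = fit_range,
         residual = sqrt(mean(stats::resid(fit)^2)),
         n_shells = sum(sel)),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> B = %.3g A^2 over k in [%.3g, %.3g] 1/A (%d shells)\n",
              x$b_factor, x$fit_range[1], x$fit_range[2], x$n_shells))
  invisible(x)
}

#' Apply Guinier sharpening to amplitudes
#'
#' @param k Spatial frequencies, 1/A.
#' @param amplitude Amplitudes to sharpen.
#' @param b_factor B factor, A^2 (positive sharpens).
#' @return Sharpened amplitudes `amplitude * exp(+B k^2 / 4)`.
#' @export
guinier_sharpen <- function(k, amplitude, b_factor) {
  amplitude * exp(b_factor * k^2 / 4)
}

#' Particle-number B factor (Rosenthal-Henderson regression)
#'
#' Regression of `ln N` (number of asymmetric units) on `1/d^2`
#' (reciprocal squared resolution); `B = 2 * slope`. Measures how many
#' particles are needed per increment of resolution.
#'
#' @param points data.frame with columns `n_particles` and `resolution_A`.
#' @return B factor in A^2. Degenerate inputs (fewer than 3 points, or no
#'   spread in resolution) raise an error.
#' @export
rosenthal_bfactor <- function(points) {
  stopifnot(all(c("n_particles", "resolution_A") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  x <- 1 / points$resolution_A^2
  if (stats::sd(x) == 0) {
    stop("resolution-independent points: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(log(points$n_particles) ~ x)
  2 * unname(stats::coef(fit)[2])
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the two volumes' spectra,
#' shells one frequency sample wide, no masking. The resolution is the
#' first crossing of the 0.143 threshold, linearly interpolated between
#' shells.
#'
#' @param half1,half2 Real 3D arrays of identical shape.
#' @param voxel_A Voxel size, Angstrom.
#' @return An object of class `fsc_curve`: data.frame fields `k` (1/A) and
#'   `fsc`, plus `resolution_A` (at 0.143; `NA` if never crossed).
#' @export
fsc <- function(half1, half2, voxel_A = 1) {
  if (!all(dim(half1) == dim(half2))) stop("volume shapes differ", call. = FALSE)
  d <- dim(half1)
  F1 <- stats::fft(half1)
  F2 <- stats::fft(half2)
  kx <- fft_freq(d[1], voxel_A)
  ky <- fft_freq(d[2], voxel_A)
  kz <- fft_freq(d[3], voxel_A)
  df <- 1 / (max(d) * voxel_A)
  r <- sqrt(outer(outer(kx^2, ky^2, `+`), kz^2, `+`))
  shell <- as.vector(round(r / df))
  nmax <- floor(min(d) / 2)
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  sn <- rowsum(as.vector(num), shell)
  s1 <- rowsum(as.vector(p1), shell)
  s2 <- rowsum(as.vector(p2), shell)
  lev <- as.integer(rownames(sn))
  keep <- lev <= nmax
  corr <- sn[keep] / sqrt(s1[keep] * s2[keep])
  ks <- lev[keep] * df
  res <- NA_real_
  below <- which(corr < 0.143)
  below <- below[below > 1]
  if (length(below) > 0) {
    i <- below[1]
    f0 <- ks[i - 1]; f1 <- ks[i]
    c0 <- corr[i - 1]; c1 <- corr[i]
    kc <- f0 + (c0 - 0.143) / (c0 - c1) * (f1 - f0)
    res <- 1 / kc
  }
  structure(list(k = ks, fsc = corr, resolution_A = res), class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells, resolution at 0.143: %s\n",
              length(x$k),
              if (is.na(x$resolution_A)) "not reached"
              else sprintf("%.3g A", x$resolution_A)))
  invisible(x)
}
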