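# Shared fixtures, memoized so expensive simulations run once per session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# analytic 2D Gaussian and its gradient on a periodic grid
gaussian_field <- function(n = 64, px = 1, sigma = 6) {
  x <- (seq_len(n) - 1) * px
  cx <- x[n %/% 2 + 1]
  X <- matrix(x, n, n); Y <- t(X)
  phi <- exp(-((X - cx)^2 + (Y - cx)^2) / (2 * sigma^2))
  g <- idpcstem:::fft_freq_grids(n, n, px)
  list(
    phi = phi,
    gx = Re(idpcstem:::ifft2(idpcstem:::fft2(phi) * 2i * pi * g$kx)),
    gy = Re(idpcstem:::ifft2(idpcstem:::fft2(phi) * 2i * pi * g$ky)),
    px = px
  )
}

as_dpc <- function(x, y, px) {
  structure(list(x = x, y = y, frame = "scan", pixel_size_A = px),
            class = "dpc_field")
}

# small TMV-like rod that fits a 138 A periodic box (two 69 A repeats)
small_rod <- function(voxel = 1.15, n = 120, slice_dz = 30) {
  memo(sprintf("rod_%g_%d", voxel, n), {
    helical_phantom(helix_spec(outer_radius_A = 60), length_A = 138,
                    voxel_xy_A = voxel, slice_dz_A = slice_dz, n_xy = n)
  })
}

# CTF pair (quadrant + ideal COM) at 4.5 mrad on a 64^2 grid
ctf_pair <- function() {
  memo("ctf_pair_45", {
    compute_ctf(beam_parameters(300, 4.5), n = 64, detector = "both", seed = 7)
  })
}

# a thin weak random-blob specimen for linearity / WPO checks
weak_blob_specimen <- function(n = 64, px = 1, scale = 0.5) {
  f <- gaussian_field(n, px, sigma = 5)
  sigma <- interaction_sigma(300)
  specimen_potential(matrix(scale * f$phi / sigma / 1000, n, n), px, 1)
}

uniform_specimen <- function(...) idpcstem:::uniform_specimen(...)

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(sqrt(sum((actual - expected)^2) / sum(expected^2)), tol)
}
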