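test_that("DPC vector forms opposite-quadrant differences and rotates", {
  A <- matrix(2, 4, 4); B <- matrix(1, 4, 4)
  C <- matrix(0.5, 4, 4); D <- matrix(1.5, 4, 4)
  q <- quadrant_images(A, B, C, D, pixel_size_A = 1)
  d0 <- dpc_vector(q, 0)
  expect_equal(d0$x[1, 1], (2 + 1.5) - (1 + 0.5))  # (A+D)-(B+C)
  expect_equal(d0$y[1, 1], (2 + 1) - (0.5 + 1.5))  # (A+B)-(C+D)
  expect_identical(d0$frame, "scan")
  # equal quadrants -> zero field
  qe <- quadrant_images(A, A, A, A, pixel_size_A = 1)
  de <- dpc_vector(qe, 0)
  expect_true(all(de$x == 0) && all(de$y == 0))
  # rotation by 90 deg swaps components with one sign flip: R(-90)(x,y)=(y,-x)
  d90 <- dpc_vector(q, 90)
  expect_equal(d90$x, d0$y, tolerance = 1e-12)
  expect_equal(d90$y, -d0$x, tolerance = 1e-12)
  q$A <- NULL
  expect_error(dpc_vector(q), "missing quadrant")
})

test_that("Fourier integration inverts the gradient exactly", {
  f <- gaussian_field(64, 1, 6)
  rec <- integrate_dpc(as_dpc(f$gx, f$gy, 1))
  target <- f$phi - mean(f$phi)
  expect_rel_error(rec$values, target, 1e-6)
  expect_equal(mean(rec$values), 0, tolerance = 1e-12)
  # zero field -> zero image
  z <- integrate_dpc(as_dpc(f$gx * 0, f$gy * 0, 1))
  expect_true(all(z$values == 0))
  # linearity to 1e-10
  f2 <- gaussian_field(64, 1, 3)
  ra <- integrate_dpc(as_dpc(2 * f$gx + 3 * f2$gx, 2 * f$gy + 3 * f2$gy, 1))
  rb <- integrate_dpc(as_dpc(f2$gx, f2$gy, 1))
  expect_lt(max(abs(ra$values - 2 * rec$values - 3 * rb$values)), 1e-10)
  # detector-frame input is a contract error
  d_det <- as_dpc(f$gx, f$gy, 1)
  d_det$frame <- "detector"
  expect_error(integrate_dpc(d_det), "scan frame")
})

test_that("Gaussian high-pass removes DC, passes fine detail, squares gain", {
  n <- 128
  const <- idpc_image(matrix(5, n, n), 2)
  expect_lt(max(abs(gaussian_highpass(const, 251)$values)), 1e-10)
  # pure sinusoid at period << 251 A passes essentially unattenuated:
  # oracle 1 - G at that frequency
  period <- 16  # A, with 2 A pixels
  x <- matrix((seq_len(n) - 1) * 2, n, n)
  s <- sin(2 * pi * x / period)
  hp <- gaussian_highpass(idpc_image(s, 2), 251, pad = 0)
  gain <- sqrt(sum(hp$values^2) / sum(s^2))
  sig_r <- 251 / (2 * sqrt(2 * log(2)))
  oracle <- 1 - exp(-2 * pi^2 * sig_r^2 / period^2)
  expect_gt(gain, 0.99)
  expect_equal(gain, oracle, tolerance = 1e-3)
  # applying (1 - G) twice squares the gain at a (grid-periodic) low
  # frequency
  xl <- matrix((seq_len(n) - 1) * 4, n, n)   # 512 A extent
  sl <- sin(2 * pi * xl / 256)
  h1 <- gaussian_highpass(idpc_image(sl, 4), 251, pad = 0)
  h2 <- gaussian_highpass(h1, 251, pad = 0)
  g1 <- sqrt(sum(h1$values^2) / sum(sl^2))
  g2 <- sqrt(sum(h2$values^2) / sum(sl^2))
  expect_equal(g2, g1^2, tolerance = 1e-6)
  expect_lt(g1, 0.99)
  expect_error(gaussian_highpass(idpc_image(s, 130), 251), "not resolvable")
})

test_that("iDPC CTF is positive, band-limited and fourfold for quadrants", {
  cc <- ctf_pair()
  for (ctf in cc) {
    k <- idpcstem:::.centred_k(nrow(ctf$values), ncol(ctf$values),
                               ctf$frequency_spacing)
    r <- sqrt(k$kx^2 + k$ky^2)
    peak <- max(ctf$values)
    # vanishes beyond the 2 alpha / lambda cutoff
    expect_lt(max(abs(ctf$values[r > ctf$cutoff * 1.05])), 1e-6 * peak)
    # no contrast reversal anywhere sampled (aberration-free)
    expect_gt(min(ctf$values[r < ctf$cutoff * 0.98]), -1e-6 * peak)
    # azimuthal average decays monotonically over the mid band
    ra <- ctf_radial(ctf)
    sel <- ra$k > 0.2 * ctf$cutoff & ra$k < 0.9 * ctf$cutoff
    expect_true(all(diff(ra$ctf[sel]) < 0))
    # k = 0 nulled by the mean-zero convention
    mid <- floor(dim(ctf$values) / 2) + 1
    expect_equal(ctf$values[mid[1], mid[2]], 0)
  }
  # fourfold azimuthal modulation: present for quadrants, absent for COM
  f4q <- ctf_fourfold(cc$quadrant)$fourfold
  f4c <- ctf_fourfold(cc$com)$fourfold
  expect_gt(f4q, 0.01)
  expect_gt(f4q, 5 * f4c)
})

test_that("WPO surrogate matches the full pipeline on a thin weak object", {
  cc <- ctf_pair()
  ctf <- cc$quadrant
  n <- nrow(ctf$values)
  px <- 1 / (n * ctf$frequency_spacing)
  b <- beam_parameters(300, 4.5)
  f <- gaussian_field(n, px, sigma = 4)
  sh <- 17
  pot <- (f$phi + 0.6 * f$phi[c((sh + 1):n, 1:sh), c((2 * sh + 1):n, 1:(2 * sh))]) * 150
  spec <- specimen_potential(matrix(pot, n, n), px, 1)
  q <- scan_image(spec, b, scan_geometry(px, n))
  full <- integrate_dpc(dpc_vector(q))
  sur <- wpo_image(spec, ctf)
  ncc <- stats::cor(as.vector(full$values), as.vector(sur$values))
  expect_gt(ncc, 0.98)
  # protein (positive potential) renders white in both
  expect_gt(stats::cor(as.vector(pot), as.vector(full$values)), 0.9)
  # zero potential -> zero image
  z <- wpo_image(matrix(0, n, n), ctf)
  expect_true(all(z$values == 0))
  # end-to-end linearity in the weak-phase regime (1% tolerance)
  q2 <- scan_image(specimen_potential(matrix(2 * pot, n, n), px, 1), b,
                   scan_geometry(px, n))
  full2 <- integrate_dpc(dpc_vector(q2))
  expect_rel_error(full2$values, 2 * full$values, 0.01)
})

test_that("CTF deconvolution over its support recovers the projection", {
  cc <- ctf_pair()
  ctf <- cc$quadrant
  n <- nrow(ctf$values)
  px <- 1 / (n * ctf$frequency_spacing)
  f <- gaussian_field(n, px, sigma = 3)
  sigma <- interaction_sigma(300)
  img <- wpo_image(f$phi * 100, ctf)
  # eps-regularized division over the CTF support
  H <- idpcstem:::ifftshift2(ctf$values)
  Fi <- idpcstem:::fft2(img$values)
  eps <- 1e-3 * max(abs(H))
  dec <- Re(idpcstem:::ifft2(Fi * H / (H^2 + eps^2)))
  # compare band-limited projection (restricted to the support) to result
  ref_k <- idpcstem:::fft2(sigma * f$phi * 100)
  ref_k[H < 0.05 * max(H)] <- 0
  ref <- Re(idpcstem:::ifft2(ref_k))
  ref <- ref - mean(ref)
  expect_rel_error(dec[abs(ref) > 1e-9], ref[abs(ref) > 1e-9], 0.01)
})

test_that("SNR measures particle contrast and flags zero-noise", {
  v <- matrix(0, 32, 32)
  v[12:20, 12:20] <- 1
  sig <- v > 0.5
  bg <- !sig
  expect_equal(snr_of_particle(v, sig, bg), Inf)
  set.seed(1)
  vn <- v + matrix(rnorm(32^2, sd = 0.25), 32, 32)
  snr <- snr_of_particle(vn, sig, bg)
  expect_equal(snr, 4, tolerance = 0.15)
  expect_error(snr_of_particle(v, sig, sig), "overlap")
  expect_error(snr_of_particle(v, matrix(FALSE, 32, 32), bg), "empty")
})

test_that("doubling the dose raises SNR by about sqrt(2)", {
  # expected quadrant counts scale linearly with dose, so Poisson draws at
  # dose and 2x dose come from rescaled means; Monte-Carlo over seeds
  b <- beam_parameters(300, 4.5)
  n <- 64; px <- 0.7
  f <- gaussian_field(n, px, sigma = 4)
  spec <- specimen_potential(matrix(f$phi * 250, n, n), px, 1)
  q <- scan_image(spec, b, scan_geometry(px, n))
  epd <- 300 * px^2
  scale_q <- function(q, s) {
    for (nm in c("A", "B", "C", "D")) q[[nm]] <- q[[nm]] * s
    q
  }
  r <- sqrt((matrix(seq_len(n), n, n) - 33)^2 +
            (matrix(seq_len(n), n, n, byrow = TRUE) - 33)^2)
  sig <- r < 6
  bg <- r > 14
  snrs <- vapply(1:100, function(s) {
    i1 <- reconstruct_idpc(add_shot_noise(scale_q(q, epd), s))
    i2 <- reconstruct_idpc(add_shot_noise(scale_q(q, 2 * epd), s))
    c(snr_of_particle(i1, sig, bg), snr_of_particle(i2, sig, bg))
  }, numeric(2))
  ratio <- mean(snrs[2, ]) / mean(snrs[1, ])
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
})

test_that("CTF matches the independent sideband (overlap-integral) oracle", {
  # first-order expansion of a cosine phase grating: the exit spectrum is
  # the probe aperture plus two sidebands at +/- k0 (shift theorem); the
  # quadrant response at scan position r0 is built directly in k-space,
  # with no multislice and no scan loop, and integrated analytically over
  # one grating period
  b <- beam_parameters(300, 4.5)
  det <- set_camera_length(detector_geometry(), b)
  cc <- ctf_pair()
  ctf <- cc$quadrant
  n <- nrow(ctf$values)
  px <- 1 / (n * ctf$frequency_spacing)
  g <- idpcstem:::fft_freq_grids(n, n, px)
  lam <- b$wavelength_pm * 1e-2
  alpha <- b$csa_mrad * 1e-3
  Ak <- matrix(0, n, n)
  Ak[(lam^2) * (g$kx^2 + g$ky^2) <= alpha^2] <- 1
  Ak <- Ak / sqrt(sum(Ak^2))           # unit total intensity
  tx <- lam * g$kx * 1e3; ty <- lam * g$ky * 1e3
  masks <- idpcstem:::.detector_masks(det, tx, ty)
  eps <- 1e-4
  oracle <- function(m0) {             # grating at k0 = m0 * df along x
    k0 <- m0 * ctf$frequency_spacing
    shift <- function(M, s) M[((seq_len(n) - 1 - s) %% n) + 1, ]
    r0s <- seq(0, 1 / k0, length.out = 9)[-9]
    dx <- vapply(r0s, function(r0) {
      Psi <- Ak +
        (1i * eps / 2) * shift(Ak,  m0) * exp(2i * pi * k0 * r0) +
        (1i * eps / 2) * shift(Ak, -m0) * exp(-2i * pi * k0 * r0)
      I <- Re(Psi * Conj(Psi))
      (sum(I * masks$A) + sum(I * masks$D)) -
        (sum(I * masks$B) + sum(I * masks$C))
    }, numeric(1))
    # k0 Fourier coefficient of Dx(r0); integrate_dpc kernel at (k0, 0)
    coef <- 2 * mean(dx * exp(-2i * pi * k0 * r0s))
    Re(k0 * coef / (2i * pi * k0^2)) / eps
  }
  mid <- floor(n / 2) + 1
  for (m0 in c(3, 6, 10)) {
    measured <- ctf$values[mid + m0, mid]
    expect_equal(oracle(m0), measured, tolerance = 0.02)
  }
})
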