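test_that("power spectrum is centrosymmetric and Parseval-consistent", {
  set.seed(4)
  img <- matrix(rnorm(48 * 48), 48, 48)
  ps <- power_spectrum(img, 1.5)
  v <- idpcstem:::ifftshift2(ps$values)
  # Hermitian symmetry of a real input: P(k) = P(-k)
  idx <- c(1, 48:2)
  expect_equal(v, v[idx, idx], tolerance = 1e-9)
  expect_equal(sum(ps$values), 48^2 * sum(img^2), tolerance = 1e-8)
  # single sinusoid -> two symmetric peaks at its frequency
  x <- matrix((seq_len(64) - 1), 64, 64)
  s <- cos(2 * pi * 8 * x / 64)
  pss <- power_spectrum(s, 1)
  pk <- which(pss$values > 0.5 * max(pss$values), arr.ind = TRUE)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk[, 1]), c(25, 41))  # +/- 8 samples from centre (33)
})

test_that("radial average puts a lattice peak in the right shell", {
  x <- matrix((seq_len(64) - 1) * 0.5, 64, 64)
  s <- cos(2 * pi * x / 2.0)  # 2 A lattice at 0.5 A pixels
  ra <- radial_average(power_spectrum(s, 0.5))
  expect_equal(ra$k[which.max(ra$power * (ra$k > 0))], 0.5, tolerance = 0.02)
})

test_that("segment extraction rotates the helix axis to vertical", {
  # synthetic rod at 30 degrees: after extraction the variance along x
  # collapses (moment-of-inertia axis oracle)
  n <- 192; px <- 1
  x <- matrix(seq_len(n) - n / 2, n, n); y <- t(x)
  th <- 30 * pi / 180
  d <- abs(x * cos(th) + y * sin(th))   # distance from a line at 30 deg to y
  rod <- exp(-d^2 / (2 * 9))
  segs <- extract_segments(rod, data.frame(x = (n / 2 - 1) * px,
                                           y = (n / 2 - 1) * px,
                                           angle = 30),
                           box_A = 64, pixel_size_A = px)
  seg <- segs[[1]]
  prof_x <- rowMeans(seg)   # rod now vertical: x profile peaked at centre
  com_x <- sum(seq_along(prof_x) * prof_x) / sum(prof_x)
  expect_equal(com_x, (length(prof_x) + 1) / 2, tolerance = 0.6)
  ix <- sum(prof_x * (seq_along(prof_x) - com_x)^2) / sum(prof_x)
  prof_y <- colMeans(seg)         # y profile nearly flat
  expect_lt(sqrt(ix), 6)          # x spread equals the rod width, not the box
  expect_lt(stats::sd(prof_y) / mean(prof_y), 0.05)
  # angle 0 is a pure crop
  crop <- extract_segments(rod, data.frame(x = 95, y = 95, angle = 0),
                           box_A = 33, pixel_size_A = px)[[1]]
  expect_equal(crop, rod[80:112, 80:112], tolerance = 1e-9)
  # rotating a segment by its own angle twice is not idempotent
  twice <- extract_segments(seg, data.frame(x = 31, y = 31, angle = 30),
                            box_A = 32, pixel_size_A = px)[[1]]
  expect_gt(max(abs(twice - seg[1:32, 1:32])), 0.01)
  expect_error(extract_segments(rod, data.frame(x = 5, y = 5, angle = 45),
                                box_A = 64, pixel_size_A = px), "outside")
})

test_that("layer-line profiles are additive and flag missing peaks", {
  ph <- small_rod()
  pr <- project_potential(ph)
  p1 <- layerline_profile(pr, ph$voxel_xy_A)
  pk <- layerline_profile(list(pr, pr, pr), ph$voxel_xy_A)
  expect_equal(pk$value, 3 * p1$value, tolerance = 1e-12)
  # white noise: no comb peak detected above local background at 5 sigma
  set.seed(8)
  noise <- matrix(rnorm(96^2), 96, 96)
  pn <- locate_layerlines(layerline_profile(noise, 1.4375), 23, orders = 1:2)
  bg_sd <- stats::sd(pn$value)
  expect_true(all(pn$peaks$height < 5 * bg_sd, na.rm = TRUE))
  expect_error(layerline_profile(list(), 1), "no segments")
  expect_error(layerline_profile(list(pr, pr[1:10, 1:10]), 1.4), "share")
})

test_that("peak ratio responds quadratically to amplitude and to damping", {
  # synthetic two-harmonic profile on a known comb
  n <- 256; px <- 1
  y <- matrix(0, n, n)
  yy <- matrix((seq_len(n) - 1) * px, n, n, byrow = TRUE)
  base <- cos(2 * pi * yy / 32) + 0.5 * cos(2 * pi * yy / 16)
  prof <- locate_layerlines(layerline_profile(base, px), 32, orders = 1:2)
  r1 <- peak_ratio(prof)
  expect_equal(r1, 0.25, tolerance = 0.02)   # power = amplitude^2
  dbl <- cos(2 * pi * yy / 32) + 1.0 * cos(2 * pi * yy / 16)
  r2 <- peak_ratio(locate_layerlines(layerline_profile(dbl, px), 32, 1:2))
  expect_equal(r2 / r1, 4, tolerance = 0.05) # doubling amplitude quadruples
  # equal heights -> ratio 1
  eq <- cos(2 * pi * yy / 32) + cos(2 * pi * yy / 16)
  expect_equal(peak_ratio(locate_layerlines(layerline_profile(eq, px), 32, 1:2)),
               1, tolerance = 0.02)
  # exp(-B k^2 / 4) damping with B > 0 strictly decreases the ratio
  prof_d <- layerline_profile(eq, px)
  damp <- exp(-800 * prof_d$frequency^2 / 4)^2  # power damps twice
  prof_d$value <- prof_d$value * damp
  rd <- peak_ratio(locate_layerlines(prof_d, 32, 1:2))
  expect_lt(rd, 1)
  # missing peak -> flagged NA
  one <- cos(2 * pi * yy / 32)
  rna <- peak_ratio(locate_layerlines(layerline_profile(one, px), 32, 1:2))
  expect_true(is.na(rna))
  expect_match(attr(rna, "flag"), "not detected")
})

test_that("pixel-size calibration recovers deliberate miscalibration", {
  ph <- small_rod()
  pr <- project_potential(ph)
  # identity: profile generated at the true pixel size, comb = true repeat
  prof <- layerline_profile(pr, ph$voxel_xy_A)
  cal <- calibrate_pixel_size(prof, reference_spacing_A = 23)
  expect_equal(cal$scale, 1, tolerance = 0.005)
  # mislabeled pixel size (+5%): frequencies shift, scale recovers it
  prof_bad <- layerline_profile(pr, ph$voxel_xy_A * 1.05)
  # observed frequencies are 1.05x too low; fitted scale ~ 1/1.05
  cal2 <- calibrate_pixel_size(prof_bad, reference_spacing_A = 23)
  expect_equal(cal2$scale, 1 / 1.05, tolerance = 0.005)
  # corrected pixel size equals the true one within 0.5%
  expect_equal(cal2$pixel_size_A, ph$voxel_xy_A, tolerance = 0.005)
  # calibrate -> rescale -> calibrate is a fixed point
  prof_fixed <- layerline_profile(pr, cal2$pixel_size_A)
  cal3 <- calibrate_pixel_size(prof_fixed, reference_spacing_A = 23)
  expect_equal(cal3$scale, 1, tolerance = 0.005)
  # two-peak fit reduces residual on comb-consistent data vs one peak
  cal_two <- calibrate_pixel_size(prof, 23, orders = 1:2)
  expect_gte(cal_two$n_peaks, 2)
  expect_error(calibrate_pixel_size(
    layerline_profile(matrix(0, 64, 64), 1), 23), "no layer line")
})

test_that("Guinier estimator recovers an injected B factor", {
  k <- seq(0.02, 0.3, by = 0.01)
  flat <- rep(2, length(k))
  expect_equal(guinier_bfactor(k, flat)$b_factor, 0, tolerance = 1e-9)
  damped <- flat * exp(-100 * k^2 / 4)
  fit <- guinier_bfactor(k, damped)
  expect_equal(fit$b_factor, 100, tolerance = 1e-6)
  # with multiplicative noise the estimate stays within 1 A^2
  set.seed(2)
  noisy <- damped * exp(rnorm(length(k), sd = 0.01))
  expect_equal(guinier_bfactor(k, noisy)$b_factor, 100, tolerance = 1)
  # sharpening then refitting gives B = 0
  sharp <- guinier_sharpen(k, damped, 100)
  expect_equal(guinier_bfactor(k, sharp)$b_factor, 0, tolerance = 1e-6)
  expect_error(guinier_bfactor(k[1:3], damped[1:3]), "5 shells")
  expect_error(guinier_bfactor(k, -damped), "positive")
})

test_that("particle-number B factor inverts its generating model", {
  d <- c(8, 6, 5, 4, 3.5)
  B <- 93
  n <- exp(1.2 + (B / 2) / d^2)
  pts <- data.frame(n_particles = n, resolution_A = d)
  expect_equal(rosenthal_bfactor(pts), 93, tolerance = 1e-9)
  set.seed(5)
  pts_noisy <- data.frame(n_particles = n * exp(rnorm(5, sd = 0.02)),
                          resolution_A = d)
  expect_equal(rosenthal_bfactor(pts_noisy), 93, tolerance = 2)
  # scaling all N leaves B unchanged (absorbed in the intercept)
  pts10 <- pts; pts10$n_particles <- pts$n_particles * 10
  expect_equal(rosenthal_bfactor(pts10), rosenthal_bfactor(pts))
  expect_error(rosenthal_bfactor(pts[1:2, ]), "3 points")
  same <- data.frame(n_particles = c(10, 20, 30), resolution_A = 4)
  expect_error(rosenthal_bfactor(same), "undefined")
})

test_that("FSC is 1 for identical volumes and finds a known band limit", {
  set.seed(6)
  n <- 48
  v <- array(rnorm(n^3), c(n, n, n))
  f1 <- fsc(v, v, voxel_A = 2)
  expect_true(all(abs(f1$fsc - 1) < 1e-9))
  # independent noise volumes decorrelate beyond the first shells
  w <- array(rnorm(n^3), c(n, n, n))
  f0 <- fsc(v, w, voxel_A = 2)
  expect_lt(max(abs(f0$fsc[-(1:3)])), 0.12)
  # band-limited common signal + independent noise: crossing at the limit
  kx <- idpcstem:::fft_freq(n, 2)
  r <- sqrt(outer(outer(kx^2, kx^2, `+`), kx^2, `+`))
  keep <- r <= 0.125
  Fs <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), c(n, n, n))
  Fs[!keep] <- 0
  s <- Re(stats::fft(Fs, inverse = TRUE)) / n^3
  s <- s / stats::sd(s)
  h1 <- s + array(rnorm(n^3, sd = 0.15), c(n, n, n))
  h2 <- s + array(rnorm(n^3, sd = 0.15), c(n, n, n))
  fb <- fsc(h1, h2, voxel_A = 2)
  expect_false(is.na(fb$resolution_A))
  df <- fb$k[2] - fb$k[1]
  expect_lt(abs(1 / fb$resolution_A - 0.125), 1.5 * df)
  expect_error(fsc(v, w[1:10, , ]), "differ")
})

test_that("II/I layer-line ratio increases with the beam CSA", {
  # linear (weak-phase) surrogate: the same rod filtered by the chain CTF
  # at each CSA; pixel 69/64 A stays below lambda/(4 alpha) up to 4.5 mrad
  px <- 69 / 64
  rod <- helical_phantom(helix_spec(outer_radius_A = 25), length_A = 69,
                         voxel_xy_A = px, slice_dz_A = 25, n_xy = 64)
  pr <- project_potential(rod)
  ratios <- vapply(c(2, 3, 4.5), function(a) {
    ctf <- compute_ctf(beam_parameters(300, a), n = 64, pixel_size_A = px,
                       seed = 3)
    img <- wpo_image(pr, ctf)
    peak_ratio(locate_layerlines(layerline_profile(img), 23, orders = 1:2))
  }, numeric(1))
  expect_true(all(is.finite(ratios)))
  expect_true(all(diff(ratios) > 0))
})
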