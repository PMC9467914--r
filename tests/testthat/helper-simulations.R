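# Expensive shared simulations (memoized per test session).
# Problem sizes are scaled versions of the experiment: 96^2 scans over a
# 138 A field (two 69 A helical repeats) instead of 4096^2 over ~1 um.

# full noisy acquisition of the TMV-like rod at 3.0 mrad, 35 e-/A^2
rod_scan_3mrad <- function() {
  memo("rod_scan_3mrad", {
    ph <- small_rod()  # 96^2 grid, 1.4375 A voxels
    b <- beam_parameters(300, 3.0, current_pa = 4)
    sc <- scan_geometry(ph$voxel_xy_A, dim(ph$slices)[1])
    pl <- plan_acquisition(b, sc, 35)
    q <- scan_image(ph, b, sc, plan = pl)
    list(phantom = ph, beam = b, scan = sc, plan = pl, q = q,
         noisy = add_shot_noise(q, 42))
  })
}

# the same rod sampled for a 2.0 mrad beam (cutoff 4.9 A); several noisy
# realizations stand in for independent helical segments whose power
# spectra are averaged, as in real layer-line processing
rod_scan_2mrad <- function() {
  memo("rod_scan_2mrad", {
    ph <- small_rod(voxel = 138 / 64, n = 64)
    b <- beam_parameters(300, 2.0, current_pa = 4)
    sc <- scan_geometry(ph$voxel_xy_A, 64)
    pl <- plan_acquisition(b, sc, 35)
    q <- scan_image(ph, b, sc, plan = pl)
    segs <- lapply(1:4, function(s) {
      reconstruct_idpc(add_shot_noise(q, s))$values
    })
    list(phantom = ph, beam = b, q = q, segments = segs)
  })
}

# noisy hemoglobin-like acquisition across CSAs at fixed dose; the 0.45 A
# scan step stays below lambda/(4 alpha) even at 10 mrad (0.49 A)
hemoglobin_snr <- function(csa_mrad, seed = 21) {
  memo(sprintf("hemo_snr_%g", csa_mrad), {
    fx <- make_fixture("hemoglobin_like", seed = 2, n_xy = 96,
                       voxel_xy_A = 0.45)
    b <- beam_parameters(300, csa_mrad, current_pa = 4)
    sc <- scan_geometry(0.45, 96)
    pl <- plan_acquisition(b, sc, 35)
    q <- add_shot_noise(scan_image(fx$specimen, b, sc, plan = pl), seed)
    img <- reconstruct_idpc(q)
    n <- 96
    cx <- (n + 1) / 2
    r <- sqrt((matrix(seq_len(n), n, n) - cx)^2 +
              (matrix(seq_len(n), n, n, byrow = TRUE) - cx)^2) * 0.45
    snr_of_particle(img, r < 11, r > 16 & r < 21)
  })
}
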