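#' Sliced specimen potential
#'
#' Container for a specimen's electrostatic potential, stored as an ordered
#' stack of 2D slices of *projected* potential (volt-Angstrom per slice),
#' ready for multislice propagation. The first array index runs along x,
#' the second along y (the conventional helical-axis direction), the third
#' along the beam (z).
#'
#' @param slices 3D numeric array `(nx, ny, n_slices)`, or a matrix for a
#'   single slice. Finite values, V*A per slice.
#' @param voxel_xy_A In-plane sampling, Angstrom.
#' @param slice_dz_A Slice thickness, Angstrom.
#' @return An object of class `specimen_potential` with derived
#'   `thickness_A = n_slices * slice_dz_A`.
#' @export
specimen_potential <- function(slices, voxel_xy_A, slice_dz_A) {
  if (is.matrix(slices)) slices <- array(slices, c(dim(slices), 1L))
  stopifnot(length(dim(slices)) == 3, voxel_xy_A > 0, slice_dz_A > 0)
  if (!all(is.finite(slices))) stop("specimen potential must be finite", call. = FALSE)
  structure(
    list(slices = slices, voxel_xy_A = voxel_xy_A, slice_dz_A = slice_dz_A,
         thickness_A = dim(slices)[3] * slice_dz_A),
    class = "specimen_potential"
  )
}

#' @export
print.specimen_potential <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<specimen_potential> %d x %d x %d voxels, %g A/px xy, %g A/slice (%g A thick)\n",
              d[1], d[2], d[3], x$voxel_xy_A, x$slice_dz_A, x$thickness_A))
  invisible(x)
}

#' Projected potential of a specimen
#'
#' Sum of the slice stack along the beam direction (V*A).
#'
#' @param specimen A [specimen_potential()] object.
#' @return Matrix `(nx, ny)`.
#' @export
project_potential <- function(specimen) {
  rowSums(specimen$slices, dims = 2)
}

#' Helix geometry specification
#'
#' Parameters of a helical rod phantom. `axial_repeat_A` is the helical
#' pitch (one full turn); the subunit lattice has `subunits_per_repeat`
#' subunits every `turns_per_repeat` turns, so the rise per subunit is
#' `axial_repeat_A * turns_per_repeat / subunits_per_repeat` and the twist is
#' `360 * turns_per_repeat / subunits_per_repeat` degrees. The defaults
#' emulate a TMV-like rod: 90 A outer radius (18 nm diameter), 23 A pitch,
#' 49 subunits per 3 turns (rise 1.41 A, twist 22.04 deg), giving layer
#' lines at n/23 A^-1 carrying low Bessel orders n.
#'
#' @param outer_radius_A Outer radius of the rod, Angstrom.
#' @param axial_repeat_A Helical pitch, Angstrom.
#' @param subunits_per_repeat Subunits per `turns_per_repeat` turns.
#' @param turns_per_repeat Turns spanned by `subunits_per_repeat` subunits.
#' @param subunit_sigma_A Gaussian blob width of one subunit, Angstrom.
#'   The 2.5 A default keeps the axial second harmonic (the 11.5 A layer
#'   line) at a realistic fraction of the first; wider blobs damp the
#'   harmonics as `exp(-2 pi^2 sigma^2 k^2)`.
#' @return An object of class `helix_spec`.
#' @export
helix_spec <- function(outer_radius_A = 90, axial_repeat_A = 23,
                       subunits_per_repeat = 49, turns_per_repeat = 3,
                       subunit_sigma_A = 2.5) {
  stopifnot(axial_repeat_A > 0, subunits_per_repeat >= 1, turns_per_repeat >= 1,
            outer_radius_A > 0, subunit_sigma_A > 0)
  structure(
    list(outer_radius_A = outer_radius_A, axial_repeat_A = axial_repeat_A,
         subunits_per_repeat = subunits_per_repeat,
         turns_per_repeat = turns_per_repeat,
         subunit_sigma_A = subunit_sigma_A),
    class = "helix_spec"
  )
}

# rise (A) and twist (rad) per subunit
.helix_rise <- function(spec) {
  spec$axial_repeat_A * spec$turns_per_repeat / spec$subunits_per_repeat
}
.helix_twist <- function(spec) {
  2 * pi * spec$turns_per_repeat / spec$subunits_per_repeat
}

#' Helical rod phantom
#'
#' A rod built as a sum of Gaussian blobs on a helical lattice, axis along
#' y at the grid centre, beam along z. The blob centres sit on a cylinder
#' of radius `outer_radius - 2 * sigma` so the density stays inside the
#' stated outer radius. Periodic in y with the full crystallographic repeat
#' `axial_repeat * turns_per_repeat`; blobs are wrapped so a grid whose y
#' extent is an integer number of repeats tiles seamlessly.
#'
#' @param spec A [helix_spec()].
#' @param length_A Rod length along y, Angstrom (blobs populate this range).
#' @param voxel_xy_A In-plane voxel size (must resolve the blob width).
#' @param slice_dz_A Slice thickness along the beam.
#' @param n_xy Grid points per side (square xy grid). Defaults to covering
#'   `length_A`.
#' @param amplitude Projected-potential scale of one subunit blob, V*A.
#'   The default makes a full rod's peak projected potential a few hundred
#'   V*A - the scale of protein contrast against vitreous ice - so phases
#'   stay in the weak-phase regime (about 0.2 rad peak at 300 kV).
#' @return A [specimen_potential()] spanning the rod diameter in z.
#' @export
helical_phantom <- function(spec, length_A, voxel_xy_A, slice_dz_A = 15,
                            n_xy = NULL, amplitude = 100) {
  stopifnot(inherits(spec, "helix_spec"))
  if (voxel_xy_A > spec$subunit_sigma_A) {
    stop("voxel must not exceed the subunit blob width (sampling error)", call. = FALSE)
  }
  if (is.null(n_xy)) n_xy <- as.integer(round(length_A / voxel_xy_A))
  r_blob <- max(spec$outer_radius_A - 2 * spec$subunit_sigma_A,
                spec$outer_radius_A / 2)
  rise <- .helix_rise(spec)
  twist <- .helix_twist(spec)
  period_A <- spec$axial_repeat_A * spec$turns_per_repeat
  n_sub <- ceiling(length_A / rise)
  i <- seq_len(n_sub) - 1
  yc <- (i * rise) %% length_A               # wrap into the grid
  phi <- i * twist
  xc <- r_blob * cos(phi)
  zc <- r_blob * sin(phi)
  # grid coordinates, origin at centre (x, z), y from 0
  nz <- max(1L, as.integer(ceiling(2 * spec$outer_radius_A / slice_dz_A)))
  x <- (seq_len(n_xy) - (n_xy %/% 2 + 1)) * voxel_xy_A
  y <- (seq_len(n_xy) - 1) * voxel_xy_A
  zmid <- (seq_len(nz) - 0.5) * slice_dz_A - nz * slice_dz_A / 2
  sig <- spec$subunit_sigma_A
  slices <- array(0, c(n_xy, n_xy, nz))
  # per-slice z weight: integral of the blob's z-Gaussian over the slice
  for (s in seq_len(nz)) {
    z0 <- zmid[s] - slice_dz_A / 2
    z1 <- zmid[s] + slice_dz_A / 2
    wz <- stats::pnorm(z1, zc, sig) - stats::pnorm(z0, zc, sig)
    keep <- wz > 1e-8
    if (!any(keep)) next
    plane <- matrix(0, n_xy, n_xy)
    for (b in which(keep)) {
      gx <- exp(-(x - xc[b])^2 / (2 * sig^2))
      # wrap the blob in y (periodic rod)
      dy <- abs(y - yc[b])
      dy <- pmin(dy, length_A - dy)
      gy <- exp(-dy^2 / (2 * sig^2))
      plane <- plane + (amplitude * wz[b]) * outer(gx, gy)
    }
    slices[, , s] <- plane
  }
  out <- specimen_potential(slices, voxel_xy_A, slice_dz_A)
  out$helix <- spec
  out$period_A <- period_A
  out
}

#' Gold-lattice resolution phantom
#'
#' A crystalline test object: a 2D cosine lattice with first-order spacing
#' `d_spacing_A` (2.35 A by default, the strongest gold reflection) riding
#' on a weak amorphous background, extended uniformly through `thickness_A`.
#' Its power spectrum has first-order peaks at `1/d_spacing_A`, which an
#' imaging chain transfers only if its cutoff `2 alpha / lambda` reaches
#' that frequency.
#'
#' @param d_spacing_A Lattice spacing, Angstrom.
#' @param thickness_A Film thickness, Angstrom.
#' @param voxel_xy_A In-plane voxel size; must be at most `d_spacing_A / 4`.
#' @param n_xy Grid points per side.
#' @param slice_dz_A Slice thickness, Angstrom.
#' @param amplitude Lattice modulation amplitude per slice, V*A.
#' @param background_rms RMS of the amorphous background per slice, V*A.
#' @param seed Seed for the background (deterministic given seed).
#' @return A [specimen_potential()].
#' @export
gold_lattice_phantom <- function(d_spacing_A = 2.35, thickness_A = 100,
                                 voxel_xy_A = 0.5, n_xy = 128,
                                 slice_dz_A = 25, amplitude = 300,
                                 background_rms = 10, seed = 1) {
  if (voxel_xy_A > d_spacing_A / 4) {
    stop("voxel must be at most d_spacing/4", call. = FALSE)
  }
  nz <- max(1L, as.integer(ceiling(thickness_A / slice_dz_A)))
  x <- (seq_len(n_xy) - 1) * voxel_xy_A
  # snap the lattice frequency to the periodic grid so wrap is seamless
  f0 <- round(n_xy * voxel_xy_A / d_spacing_A) / (n_xy * voxel_xy_A)
  lattice <- amplitude * (outer(cos(2 * pi * f0 * x), rep(1, n_xy)) +
                          outer(rep(1, n_xy), cos(2 * pi * f0 * x)))
  slices <- array(0, c(n_xy, n_xy, nz))
  local_seed(seed, {
    for (s in seq_len(nz)) {
      bg <- matrix(stats::rnorm(n_xy^2, sd = background_rms), n_xy, n_xy)
      slices[, , s] <- lattice / nz * 1 + bg
    }
  })
  out <- specimen_potential(slices, voxel_xy_A, slice_dz_A)
  out$d_spacing_A <- 1 / f0
  out
}

# Element -> atomic number for the simple Gaussian atom model
.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, Fe = 26, Au = 79)

#' Rasterize an atom list into a sliced potential
#'
#' Each atom contributes an isotropic 3D Gaussian whose integrated strength
#' scales as Z^0.8 (a simple monotone proxy for scattering power).
#' Deterministic given the input.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom;
#'   x, y relative to grid origin at the lower corner, z within
#'   `[0, thickness]`).
#' @param voxel_xy_A In-plane voxel size, Angstrom.
#' @param n_xy Grid points per side.
#' @param thickness_A Slab thickness covered by the slice stack.
#' @param slice_dz_A Slice thickness.
#' @param sigma_A Gaussian width per atom, Angstrom.
#' @param amplitude Integrated projected potential of a Z = 6 atom, V*A
#'   (about 30 V*A for carbon).
#' @return A [specimen_potential()].
#' @export
atoms_to_potential <- function(atoms, voxel_xy_A, n_xy, thickness_A,
                               slice_dz_A = 25, sigma_A = 1.5, amplitude = 30) {
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  z_num <- .element_z[as.character(atoms$element)]
  if (any(is.na(z_num))) {
    stop("unknown element symbol: ",
         paste(unique(atoms$element[is.na(z_num)]), collapse = ", "),
         call. = FALSE)
  }
  nz <- max(1L, as.integer(ceiling(thickness_A / slice_dz_A)))
  x <- (seq_len(n_xy) - 1) * voxel_xy_A
  slices <- array(0, c(n_xy, n_xy, nz))
  if (nrow(atoms) > 0) {
    w <- amplitude * (z_num / 6)^0.8
    zmid <- (seq_len(nz) - 0.5) * slice_dz_A
    for (a in seq_len(nrow(atoms))) {
      gx <- exp(-(x - atoms$x[a])^2 / (2 * sigma_A^2))
      gy <- exp(-(x - atoms$y[a])^2 / (2 * sigma_A^2))
      z0 <- zmid - slice_dz_A / 2
      wz <- stats::pnorm(z0 + slice_dz_A, atoms$z[a], sigma_A) -
        stats::pnorm(z0, atoms$z[a], sigma_A)
      for (s in which(wz > 1e-8)) {
        slices[, , s] <- slices[, , s] + (w[a] * wz[s]) * outer(gx, gy)
      }
    }
  }
  specimen_potential(slices, voxel_xy_A, slice_dz_A)
}

#' Vitreous-ice slab
#'
#' A statistical stand-in for amorphous ice: a uniform mean potential plus
#' band-limited Gaussian fluctuations with a given correlation length.
#' Reproducible under a fixed seed.
#'
#' @param thickness_A Slab thickness, Angstrom.
#' @param voxel_xy_A In-plane voxel size.
#' @param n_xy Grid points per side.
#' @param slice_dz_A Slice thickness.
#' @param mean_potential Mean projected potential per slice, V*A (default
#'   3.5 V - the inner potential of vitreous ice - times the slice
#'   thickness).
#' @param rms_fluctuation RMS of the fluctuations per slice, V*A (default
#'   0.2 V/A of thickness).
#' @param correlation_length_A Gaussian correlation length of the
#'   fluctuations, Angstrom.
#' @param seed RNG seed.
#' @return A [specimen_potential()].
#' @export
ice_layer <- function(thickness_A, voxel_xy_A, n_xy, slice_dz_A = 25,
                      mean_potential = 3.5 * slice_dz_A,
                      rms_fluctuation = 0.2 * slice_dz_A,
                      correlation_length_A = 3, seed = 1) {
  stopifnot(thickness_A > 0)
  nz <- max(1L, as.integer(ceiling(thickness_A / slice_dz_A)))
  g <- fft_freq_grids(n_xy, n_xy, voxel_xy_A)
  filt <- exp(-2 * pi^2 * correlation_length_A^2 * (g$kx^2 + g$ky^2))
  slices <- array(0, c(n_xy, n_xy, nz))
  local_seed(seed, {
    for (s in seq_len(nz)) {
      w <- matrix(stats::rnorm(n_xy^2), n_xy, n_xy)
      f <- Re(ifft2(fft2(w) * filt))
      if (rms_fluctuation > 0) {
        f <- f * (rms_fluctuation / stats::sd(as.vector(f)))
      } else {
        f <- 0
      }
      slices[, , s] <- mean_potential + f
    }
  })
  specimen_potential(slices, voxel_xy_A, slice_dz_A)
}

#' Superpose specimen potentials
#'
#' Voxel-wise sum of two or more [specimen_potential()] objects on matching
#' xy grids. Stacks of unequal slice counts are centre-aligned and
#' zero-padded, so the composite thickness is the maximum of the inputs.
#'
#' @param ... `specimen_potential` objects.
#' @return A [specimen_potential()].
#' @export
compose_specimens <- function(...) {
  specs <- list(...)
  stopifnot(length(specs) >= 1)
  for (s in specs) stopifnot(inherits(s, "specimen_potential"))
  d1 <- dim(specs[[1]]$slices)[1:2]
  v <- specs[[1]]$voxel_xy_A
  dz <- specs[[1]]$slice_dz_A
  for (s in specs[-1]) {
    if (!identical(dim(s$slices)[1:2], d1) || s$voxel_xy_A != v ||
        s$slice_dz_A != dz) {
      stop("specimen grids do not match", call. = FALSE)
    }
  }
  nz <- max(vapply(specs, function(s) dim(s$slices)[3], integer(1)))
  acc <- array(0, c(d1, nz))
  for (s in specs) {
    n <- dim(s$slices)[3]
    off <- (nz - n) %/% 2
    acc[, , off + seq_len(n)] <- acc[, , off + seq_len(n)] + s$slices
  }
  specimen_potential(acc, v, dz)
}

# uniform (vacuum if value = 0) specimen, handy in tests
uniform_specimen <- function(value, voxel_xy_A, n_xy, n_slices = 1,
                             slice_dz_A = 25) {
  specimen_potential(array(value, c(n_xy, n_xy, n_slices)), voxel_xy_A, slice_dz_A)
}
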