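#' Segmented-detector geometry
#'
#' Geometry of the annular four-quadrant detector, expressed on the angular
#' (mrad) scale at the detector plane. The physical detector has eight
#' segments, but the radial split is hard-wired away, leaving four quadrant
#' read-outs; quadrants A, B, C, D run counterclockwise starting from the
#' +x detector axis at `quadrant_offset_deg`. The central hole has one
#' sixth the outer radius by default.
#'
#' @param outer_radius_mrad Outer detector radius.
#' @param hole_radius_mrad Central hole radius; default `outer/6`.
#' @param quadrant_offset_deg Azimuth of the A/D boundary (the detector +x
#'   axis), degrees.
#' @param bf_disk_radius_mrad Radius of the bright-field disk on the
#'   detector (the beam CSA as scaled by the camera length). Defaults to
#'   the aperture semi-angle placement set later by [set_camera_length()].
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(outer_radius_mrad = 6,
                              hole_radius_mrad = outer_radius_mrad / 6,
                              quadrant_offset_deg = 0,
                              bf_disk_radius_mrad = 4 * hole_radius_mrad) {
  stopifnot(hole_radius_mrad > 0,
            hole_radius_mrad < bf_disk_radius_mrad,
            bf_disk_radius_mrad <= outer_radius_mrad)
  structure(
    list(outer_radius_mrad = outer_radius_mrad,
         hole_radius_mrad = hole_radius_mrad,
         quadrant_offset_deg = quadrant_offset_deg,
         bf_disk_radius_mrad = bf_disk_radius_mrad),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> hole %.3g / bf disk %.3g / outer %.3g mrad, offset %g deg\n",
    x$hole_radius_mrad, x$bf_disk_radius_mrad, x$outer_radius_mrad,
    x$quadrant_offset_deg))
  invisible(x)
}

#' Set the camera length for a beam
#'
#' Rescales the detector geometry so the bright-field disk of the beam
#' covers the detector with a radius four times the central-hole radius
#' (and hence two thirds of the outer radius, with the hole at one sixth).
#' On the angular scale this pins `bf_disk_radius` to the beam CSA and
#' scales hole and outer radius accordingly. Idempotent.
#'
#' @param det A [detector_geometry()].
#' @param beam A [beam_parameters()].
#' @return A rescaled `detector_geometry`.
#' @export
set_camera_length <- function(det, beam) {
  alpha <- beam$csa_mrad
  detector_geometry(
    outer_radius_mrad = 1.5 * alpha,
    hole_radius_mrad = alpha / 4,
    quadrant_offset_deg = det$quadrant_offset_deg,
    bf_disk_radius_mrad = alpha
  )
}

# Region masks over an (unshifted) angular grid. Edge pixels are
# area-weighted by 4x4 supersampling; the subsample offsets straddle the
# pixel centre so no subsample falls exactly on a quadrant boundary (which
# would bias opposite-quadrant differences). Returns quadrant
# masks (boundaries at offset_deg + {0, 90, 180, 270}), the hole, the
# complement (outside the detector annulus), and an ADF annulus outside
# the BF disk. Masks partition: hole + A + B + C + D + outside = 1.
.detector_masks <- function(det, theta_x, theta_y, offset_deg = NULL) {
  if (is.null(offset_deg)) offset_deg <- det$quadrant_offset_deg
  n1 <- nrow(theta_x); n2 <- ncol(theta_x)
  dx <- abs(theta_x[2, 1] - theta_x[1, 1])
  dy <- abs(theta_y[1, 2] - theta_y[1, 1])
  ss <- c(-3, -1, 1, 3) / 8
  A <- B <- C <- D <- hole <- matrix(0, n1, n2)
  off <- offset_deg * pi / 180
  for (ox in ss) for (oy in ss) {
    tx <- theta_x + ox * dx
    ty <- theta_y + oy * dy
    r <- sqrt(tx^2 + ty^2)
    in_hole <- r < det$hole_radius_mrad
    in_ann <- !in_hole & r <= det$outer_radius_mrad
    az <- (atan2(ty, tx) - off) %% (2 * pi)
    q <- floor(az / (pi / 2))  # 0..3 -> A..D counterclockwise
    A <- A + (in_ann & q == 0)
    B <- B + (in_ann & q == 1)
    C <- C + (in_ann & q == 2)
    D <- D + (in_ann & q == 3)
    hole <- hole + in_hole
  }
  r0 <- sqrt(theta_x^2 + theta_y^2)
  adf <- (r0 > det$bf_disk_radius_mrad * 1.1) & (r0 <= det$outer_radius_mrad)
  s <- length(ss)^2
  list(A = A / s, B = B / s, C = C / s, D = D / s, hole = hole / s,
       outside = 1 - (A + B + C + D + hole) / s, adf = adf + 0)
}
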