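# Minimal MRC2014 I/O. Written by hand because no R MRC reader is
# available; covers the subset this package needs: mode 2 (float32)
# images/volumes, voxel size in the header, machine-stamp endianness.

#' Read an MRC2014 image or volume
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32); returns the data as
#' a numeric array with the voxel size recovered from the cell dimensions.
#' Big-endian files are handled via the machine stamp.
#'
#' @param path File path.
#' @return List with `data` (2D matrix if nz = 1, else 3D array),
#'   `voxel_A` (length 3), `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("truncated MRC header", call. = FALSE)
  machst <- hdr_raw[213:214]
  endian <- if (identical(as.integer(machst), c(0x11L, 0x11L))) "big" else "little"
  ints <- readBin(hdr_raw, "integer", n = 56, size = 4, endian = endian)
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  floats <- readBin(hdr_raw[41:64], "numeric", n = 6, size = 4, endian = endian)
  cella <- floats[1:3]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5) ||
      !(mode %in% c(0L, 1L, 2L))) {
    stop("malformed or unsupported MRC header (mode ", mode, ")", call. = FALSE)
  }
  n <- nx * ny * nz
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endian))
  if (length(dat) < n) stop("truncated MRC data section", call. = FALSE)
  voxel <- ifelse(c(mx, my, mz) > 0, cella / c(mx, my, mz), 1)
  data <- if (nz == 1) matrix(dat, nx, ny) else array(dat, c(nx, ny, nz))
  list(data = data, voxel_A = voxel, mode = mode)
}

#' Write an MRC2014 image or volume
#'
#' Writes mode 2 (float32, little-endian), x fastest, with the voxel size
#' recorded in the cell dimensions and the origin at zero.
#'
#' @param data 2D matrix or 3D array.
#' @param path Output path.
#' @param voxel_A Voxel size in Angstrom (scalar or length 3).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, voxel_A = 1) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  d <- dim(data)
  voxel <- rep(voxel_A, length.out = 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * voxel)              # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))  # dmin dmax dmean
  wi(if (d[3] > 1) 1 else 0) # ispg
  wi(0)                      # nsymbt
  writeBin(raw(100), con)    # extra (words 25-49)
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(data)))                    # rms
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a quadrant stack with its JSON sidecar
#'
#' Persists the four quadrant images (plus ADF if present) as a
#' multi-section MRC file and the acquisition description (beam, scan,
#' detector, seed) as a JSON sidecar next to it.
#'
#' @param q A [quadrant_images()] object.
#' @param path Output MRC path; the sidecar is `paste0(path, ".json")`.
#' @param meta Named list merged into the sidecar (beam, scan, detector,
#'   seed, ...).
#' @return `path`, invisibly.
#' @export
write_quadrant_stack <- function(q, path, meta = list()) {
  layers <- list(q$A, q$B, q$C, q$D)
  if (!is.null(q$adf)) layers <- c(layers, list(q$adf))
  stack <- array(unlist(layers), c(dim(q$A), length(layers)))
  write_mrc(stack, path, voxel_A = q$pixel_size_A)
  side <- c(list(layers = c("A", "B", "C", "D", if (!is.null(q$adf)) "ADF"),
                 pixel_size_A = q$pixel_size_A,
                 scan_rotation_deg = q$scan_rotation_deg,
                 electrons_per_dwell = q$electrons_per_dwell,
                 noisy = q$noisy),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a quadrant stack written by [write_quadrant_stack()]
#'
#' @param path MRC path with a `.json` sidecar next to it.
#' @return A [quadrant_images()] object; the sidecar is attached as
#'   attribute `sidecar`.
#' @export
read_quadrant_stack <- function(path) {
  m <- read_mrc(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  st <- m$data
  q <- quadrant_images(st[, , 1], st[, , 2], st[, , 3], st[, , 4],
                       pixel_size_A = side$pixel_size_A,
                       scan_rotation_deg = side$scan_rotation_deg,
                       adf = if (dim(st)[3] >= 5) st[, , 5] else NULL,
                       electrons_per_dwell = side$electrons_per_dwell,
                       noisy = isTRUE(side$noisy))
  attr(q, "sidecar") <- side
  q
}
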