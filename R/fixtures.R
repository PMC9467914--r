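#' Standard synthetic specimens
#'
#' Deterministic fixtures emulating the specimens this kind of experiment
#' images, at the study conditions:
#' \describe{
#'   \item{`tmv_raft`}{parallel TMV-like helical rods (18 nm diameter,
#'     23 A pitch) lying side by side in a 300 A vitreous-ice slab; the
#'     raft thickness (one rod, 180 A) sits inside the 18-54 nm range of
#'     typical specimen regions.}
#'   \item{`gold`}{a gold-on-carbon resolution standard: 2.35 A lattice on
#'     an amorphous background, 100 A thick.}
#'   \item{`hemoglobin_like`}{a globular cluster of light atoms (a
#'     hemoglobin-sized blob with four iron sites) embedded in ice.}
#' }
#'
#' @param name One of `"tmv_raft"`, `"gold"`, `"hemoglobin_like"`.
#' @param seed RNG seed for the stochastic components (ice, background).
#' @param n_xy Grid points per side.
#' @param voxel_xy_A In-plane voxel size, Angstrom.
#' @return List with `specimen` (a [specimen_potential()]) and `config`
#'   (a serializable run configuration, see [run_config()]).
#' @export
make_fixture <- function(name = c("tmv_raft", "gold", "hemoglobin_like"),
                         seed = 1, n_xy = NULL, voxel_xy_A = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    tmv_raft = {
      if (is.null(n_xy)) n_xy <- 256
      if (is.null(voxel_xy_A)) voxel_xy_A <- 1.5
      fov <- n_xy * voxel_xy_A
      hx <- helix_spec()  # TMV defaults: 90 A radius, 23 A pitch
      rod <- helical_phantom(hx, length_A = fov, voxel_xy_A = voxel_xy_A,
                             slice_dz_A = 30, n_xy = n_xy)
      n_rods <- max(1L, floor(fov / (2 * hx$outer_radius_A)))
      raft <- rod$slices
      if (n_rods > 1) {
        sh <- as.integer(round(2 * hx$outer_radius_A / voxel_xy_A))
        for (r in seq_len(n_rods - 1)) {
          idx <- ((seq_len(n_xy) - 1 + r * sh) %% n_xy) + 1
          raft <- raft + rod$slices[idx, , , drop = FALSE]
        }
      }
      rods <- specimen_potential(raft, voxel_xy_A, rod$slice_dz_A)
      ice <- ice_layer(300, voxel_xy_A, n_xy, slice_dz_A = rod$slice_dz_A,
                       seed = seed)
      out <- compose_specimens(rods, ice)
      out$helix <- hx
      out
    },
    gold = {
      if (is.null(n_xy)) n_xy <- 192
      if (is.null(voxel_xy_A)) voxel_xy_A <- 0.5
      gold_lattice_phantom(d_spacing_A = 2.35, thickness_A = 100,
                           voxel_xy_A = voxel_xy_A, n_xy = n_xy, seed = seed)
    },
    hemoglobin_like = {
      if (is.null(n_xy)) n_xy <- 128
      if (is.null(voxel_xy_A)) voxel_xy_A <- 0.45
      fov <- n_xy * voxel_xy_A
      atoms <- local_seed(seed, {
        n_at <- 300
        r <- 15 * (stats::runif(n_at))^(1 / 3)   # uniform ball, 30 A diameter
        th <- acos(stats::runif(n_at, -1, 1))
        ph <- stats::runif(n_at, 0, 2 * pi)
        data.frame(
          element = sample(c("C", "N", "O", "S"), n_at, replace = TRUE,
                           prob = c(0.6, 0.2, 0.18, 0.02)),
          x = fov / 2 + r * sin(th) * cos(ph),
          y = fov / 2 + r * sin(th) * sin(ph),
          z = 25 + r * cos(th))
      })
      atoms <- rbind(atoms, data.frame(
        element = "Fe",
        x = fov / 2 + c(6, -6, 0, 0), y = fov / 2 + c(0, 0, 6, -6),
        z = rep(25, 4)))
      mol <- atoms_to_potential(atoms, voxel_xy_A, n_xy, thickness_A = 50,
                                slice_dz_A = 25)
      ice <- ice_layer(50, voxel_xy_A, n_xy, slice_dz_A = 25,
                       correlation_length_A = 2, seed = seed)
      compose_specimens(mol, ice)
    })
  cfg <- run_config(
    fixture = name, seed = seed,
    n_xy = dim(spec$slices)[1], voxel_xy_A = spec$voxel_xy_A,
    slice_dz_A = spec$slice_dz_A
  )
  list(specimen = spec, config = cfg)
}

#' Run configuration
#'
#' A fully serializable description of a simulation run: every field is a
#' scalar or plain list so the configuration round-trips losslessly through
#' YAML. A seed is mandatory for any stochastic stage.
#'
#' @param ... Named scalar fields (beam, scan, detector, phantom, dose,
#'   seed, paths...).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (is.null(cfg$seed)) stop("run_config requires a seed", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a [run_config()]; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run record emitted alongside outputs
#'
#' Snapshot of the configuration, package version, derived plan and a
#' timestamp; written as JSON next to every output artifact so any
#' stochastic output is reproducible from its record alone.
#'
#' @param cfg A [run_config()].
#' @param plan Optional [plan_acquisition()] result.
#' @param path If non-`NULL`, write the record as JSON here.
#' @return The record (list), invisibly if written.
#' @export
run_record <- function(cfg, plan = NULL, path = NULL) {
  rec <- list(
    config = unclass(cfg),
    version = as.character(utils::packageVersion("idpcstem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(plan)) {
    rec$plan <- list(dwell_time_us = plan$dwell_time_us,
                     frame_time_s = plan$frame_time_s,
                     total_dose = plan$total_dose,
                     electrons_per_dwell = plan$electrons_per_dwell,
                     aliased = plan$aliased)
  }
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rec))
  }
  rec
}
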