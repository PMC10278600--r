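#' Simulation configuration for synthetic QPI movies
#'
#' Bundles the acquisition geometry and the cell-population parameters used by
#' [simulate_movie()]. Defaults emulate a 20 h recording at 5-minute intervals
#' (241 frames) with a 10x objective: 0.65 um pixels, 0.66 um illumination and
#' a specific refraction increment of 0.18 um^3/pg.
#'
#' @param n_cells number of cells seeded in the field.
#' @param field_size integer vector `c(height, width)` in pixels.
#' @param pixel_size pixel pitch in the sample plane, um/pixel.
#' @param frame_interval time between frames, minutes.
#' @param n_frames number of frames (>= 2); 241 corresponds to 20 h at 5 min.
#' @param wavelength illumination wavelength, um.
#' @param alpha specific refraction increment, um^3/pg.
#' @param cell_mass_mean,cell_mass_sd dry mass distribution of seeded cells, pg.
#' @param cell_radius_mean,cell_radius_sd visible cell radius (the 3-sigma
#'   footprint of the dry-mass profile), um.
#' @param speed_mean stationary mean migration speed, um/h.
#' @param persistence_time directional persistence time of the
#'   Ornstein-Uhlenbeck velocity process, minutes.
#' @param elongation major/minor axis ratio of the dry-mass profile (>= 1).
#' @param division_rate division events per cell per hour (0 disables
#'   divisions).
#' @param drug_effect multiplicative factor applied to `speed_mean`,
#'   emulating a migrastatic (< 1 slows cells down).
#' @param drug_circ_shift fraction in `[0, 1]` by which the drug rounds cells
#'   up (0 = no change, 1 = fully circular).
#' @param noise_sd per-pixel Gaussian phase noise, radians.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   movies.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_movie()]
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 5, field_size = c(128, 128), n_frames = 10)
#' cfg$n_frames
sim_config <- function(n_cells = 20,
                       field_size = c(512, 512),
                       pixel_size = 0.65,
                       frame_interval = 5,
                       n_frames = 241,
                       wavelength = 0.66,
                       alpha = 0.18,
                       cell_mass_mean = 250,
                       cell_mass_sd = 50,
                       cell_radius_mean = 15,
                       cell_radius_sd = 2,
                       speed_mean = 30,
                       persistence_time = 60,
                       elongation = 2,
                       division_rate = 0,
                       drug_effect = 1,
                       drug_circ_shift = 0,
                       noise_sd = 0,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), field_size = as.integer(field_size),
    pixel_size = pixel_size, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), wavelength = wavelength, alpha = alpha,
    cell_mass_mean = cell_mass_mean, cell_mass_sd = cell_mass_sd,
    cell_radius_mean = cell_radius_mean, cell_radius_sd = cell_radius_sd,
    speed_mean = speed_mean, persistence_time = persistence_time,
    elongation = elongation, division_rate = division_rate,
    drug_effect = drug_effect, drug_circ_shift = drug_circ_shift,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_cells >= 1, length(cfg$field_size) == 2, all(cfg$field_size >= 16),
    cfg$pixel_size > 0, cfg$frame_interval > 0, cfg$n_frames >= 2,
    cfg$wavelength > 0, cfg$alpha > 0,
    cfg$cell_mass_mean > 0, cfg$cell_mass_sd >= 0,
    cfg$cell_radius_mean > 0, cfg$cell_radius_sd >= 0,
    cfg$speed_mean >= 0, cfg$persistence_time > 0,
    cfg$elongation >= 1, cfg$division_rate >= 0,
    cfg$drug_effect > 0, cfg$drug_circ_shift >= 0, cfg$drug_circ_shift <= 1,
    cfg$noise_sd >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells,",
      paste(x$field_size, collapse = "x"), "px,",
      x$n_frames, "frames @", x$frame_interval, "min\n")
  cat("  speed", x$speed_mean, "um/h x drug_effect", x$drug_effect,
      "| persistence", x$persistence_time, "min | noise",
      x$noise_sd, "rad | seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.phase_movie <- function(x, ...) {
  d <- dim(x$phase)
  cat("phase_movie:", d[1], "x", d[2], "px,", d[3], "frames,",
      "pixel", x$pixel_size, "um, interval", x$frame_interval, "min\n")
  invisible(x)
}
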