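#' Write a phase movie as multi-page 32-bit float TIFF with JSON sidecar
#'
#' Phase (radians) is stored one frame per TIFF page in 32-bit floating
#' point. Acquisition metadata goes to `<path>.json`
#' (`pixel_size_um`, `frame_interval_min`, `wavelength_um`,
#' `alpha_um3_per_pg`, and the simulation seed when known).
#'
#' @param movie a `phase_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phase_movie <- function(movie, path) {
  # the TIFF writer stores floats in [0, 1]; keep the affine scale in the
  # sidecar so reading restores radians exactly (to 32-bit precision)
  lo <- min(movie$phase); hi <- max(movie$phase)
  scl <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(movie$phase)[3]),
                   function(f) (movie$phase[, , f] - lo) / scl)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = movie$pixel_size,
               frame_interval_min = movie$frame_interval,
               wavelength_um = movie$wavelength,
               alpha_um3_per_pg = movie$alpha,
               phase_offset_rad = lo, phase_scale_rad = scl,
               seed = if (!is.null(movie$config)) movie$config$seed else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase movie written by [write_phase_movie()]
#'
#' @param path TIFF path; metadata is read from `<path>.json` if present,
#'   otherwise supply it via `...` (`pixel_size`, `frame_interval`,
#'   `wavelength`, `alpha`).
#' @param ... metadata overrides.
#' @return A `phase_movie`.
#' @export
read_phase_movie <- function(path, ...) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  phase <- array(0, c(H, W, length(pages)))
  for (f in seq_along(pages)) phase[, , f] <- pages[[f]]
  meta <- list(pixel_size = 0.65, frame_interval = 5,
               wavelength = 0.66, alpha = 0.18)
  side <- paste0(path, ".json")
  offset <- 0; scl <- 1
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta$pixel_size <- js$pixel_size_um %||% meta$pixel_size
    meta$frame_interval <- js$frame_interval_min %||% meta$frame_interval
    meta$wavelength <- js$wavelength_um %||% meta$wavelength
    meta$alpha <- js$alpha_um3_per_pg %||% meta$alpha
    offset <- js$phase_offset_rad %||% 0
    scl <- js$phase_scale_rad %||% 1
  }
  phase <- phase * scl + offset
  ovr <- list(...)
  for (nm in intersect(names(ovr), names(meta))) meta[[nm]] <- ovr[[nm]]
  structure(c(list(phase = phase), meta, list(ground_truth = NULL, config = NULL)),
            class = "phase_movie")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-frame label images as a 16-bit multi-page TIFF
#'
#' Labels (integers, 0 = background) are scaled by 1/65535 for storage and
#' restored on read; up to 65535 labels per frame.
#'
#' @param labels list of integer label matrices.
#' @param path output path.
#' @export
write_label_movie <- function(labels, path) {
  stopifnot(max(vapply(labels, max, 1)) < 65536)
  tiff::writeTIFF(lapply(labels, function(l) l / 65535),
                  path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_movie
#' @export
read_label_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    storage.mode(p) <- "double"
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
}

#' Write the simulator's ground truth as CSV
#'
#' One row per cell per frame: `frame`, `cell_id`, `t_h`, `x_um`, `y_um`,
#' `mass_pg`.
#'
#' @param movie a `phase_movie` carrying ground truth.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(movie, path) {
  gt <- movie$ground_truth$frames
  stopifnot(!is.null(gt))
  write.csv(gt[, c("frame", "cell_id", "t_h", "x_um", "y_um", "mass_pg")],
            path, row.names = FALSE)
  invisible(path)
}
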