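# programmatic fixtures shared across the test files

# rasterised disc mask of radius r pixels, with margin
disc_mask <- function(r, margin = 3) {
  n <- 2 * r + 2 * margin + 1
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

rect_mask <- function(h, w, pad = 2) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# phase frame with isotropic Gaussian blobs (independent of the package's
# rasteriser): centers in pixels (x = col0, y = row0), sigma in pixels,
# peak phase in radians
blob_phase <- function(n, centers, sigma_px, peak_rad, trunc = 4) {
  ph <- matrix(0, n, n)
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  for (k in seq_len(nrow(centers))) {
    r2 <- ((X - centers[k, 1])^2 + (Y - centers[k, 2])^2) / sigma_px^2
    ph <- ph + ifelse(r2 <= trunc^2, peak_rad * exp(-r2 / 2), 0)
  }
  ph
}

# minimal phase_movie wrapper around a list of phase frames
fake_movie <- function(frames, pixel_size = 1, frame_interval = 5,
                       wavelength = 0.66, alpha = 0.18) {
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  ph <- array(0, c(H, W, length(frames)))
  for (f in seq_along(frames)) ph[, , f] <- frames[[f]]
  structure(list(phase = ph, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 wavelength = wavelength, alpha = alpha,
                 ground_truth = NULL, config = NULL),
            class = "phase_movie")
}

# feature table for a set of straight-line tracks: one row per frame
straight_track_features <- function(track_id, t_h, x0, y0, vx, vy,
                                    circ = 50, dens = 0.3, mass = 250) {
  data.frame(track_id = track_id, frame = seq_along(t_h), time_h = t_h,
             mass_pg = mass, area_um2 = mass / dens,
             perimeter_um = 100, circularity_pct = circ,
             density_pg_per_um2 = dens,
             x_um = x0 + vx * t_h, y_um = y0 + vy * t_h,
             border = FALSE)
}

small_sim <- function(...) {
  args <- list(n_cells = 4, field_size = c(256, 256), n_frames = 20,
               cell_radius_mean = 12, cell_radius_sd = 1.5, seed = 42)
  ovr <- list(...)
  for (nm in names(ovr)) args[[nm]] <- ovr[[nm]]
  do.call(sim_config, args)
}
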