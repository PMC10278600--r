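#' Segment one phase frame into cell labels
#'
#' Foreground detection operates on the dry-mass density map. A core
#' threshold is chosen by `threshold_policy` — by default Otsu's method on
#' the density histogram, floored at `noise_floor_k` (3) times the robust
#' background noise sd (1.4826 * MAD) — and then extended by hysteresis down
#' to the noise floor: connected components of the low mask are kept when
#' they contain core pixels. This keeps the faint dry-mass tails of each cell
#' inside its mask (an Otsu cut alone discards a substantial mass fraction
#' and would bias the dry-mass sums low), while pure noise pixels stay
#' excluded. Holes are filled, touching cells are split by a watershed on the
#' smoothed density map seeded from its local maxima, components smaller than
#' `min_area` are discarded, and border-touching objects are flagged.
#'
#' @param phase phase map in radians (one frame).
#' @param pixel_size um/pixel.
#' @param wavelength,alpha acquisition constants for the phase-to-density
#'   conversion (um, um^3/pg).
#' @param min_area minimum object area, um^2.
#' @param threshold_policy `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold density threshold in pg/um^2 when
#'   `threshold_policy = "fixed"`.
#' @param noise_floor_k multiplier on the robust background noise sd for the
#'   threshold floor and the hysteresis low level.
#' @param ws_smooth_sigma_um Gaussian smoothing (um) of the density map
#'   before watershed seeding.
#' @param ws_tolerance watershed merge tolerance as a fraction of the frame's
#'   density maximum; saddles shallower than this do not split objects.
#' @return List with `labels` (integer matrix, 0 background) and `table`
#'   (`label`, `area_um2`, `x_um`, `y_um` mass-weighted centroid, `border`).
#' @export
segment_frame <- function(phase, pixel_size,
                          wavelength = 0.66, alpha = 0.18,
                          min_area = 50,
                          threshold_policy = c("otsu", "fixed"),
                          fixed_threshold = NULL,
                          noise_floor_k = 3,
                          ws_smooth_sigma_um = 2,
                          ws_tolerance = 0.05) {
  threshold_policy <- match.arg(threshold_policy)
  if (any(!is.finite(phase))) stop("segment_frame: non-finite pixels in phase map")
  dens <- dry_mass_density(phase, wavelength, alpha)
  H <- nrow(dens); W <- ncol(dens)

  sigma_bg <- mad(dens)   # robust: cells occupy a minority of pixels
  floor_thr <- noise_floor_k * sigma_bg
  thr <- switch(threshold_policy,
                otsu = max(otsu_threshold(as.vector(dens)), floor_thr),
                fixed = {
                  if (is.null(fixed_threshold)) stop("segment_frame: fixed_threshold required")
                  fixed_threshold
                })
  core <- dens > thr
  empty <- list(labels = matrix(0L, H, W),
                table = data.frame(label = integer(), area_um2 = numeric(),
                                   x_um = numeric(), y_um = numeric(),
                                   border = logical()))
  if (!any(core)) return(empty)

  # hysteresis: extend cores down to the noise floor
  low_thr <- max(floor_thr, 1e-9 * max(dens))
  low <- dens > low_thr
  ll <- EBImage::bwlabel(EBImage::Image(low * 1))
  keep <- setdiff(unique(ll[core]), 0)
  mask <- matrix(as.vector(ll) %in% keep, H, W)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0

  # watershed on the smoothed density map (normalised height)
  sm <- EBImage::gblur(EBImage::Image(dens / max(dens)),
                       sigma = max(1, ws_smooth_sigma_um / pixel_size))
  ws <- EBImage::watershed(EBImage::imageData(sm) * mask, tolerance = ws_tolerance, ext = 3)
  lab <- matrix(as.integer(EBImage::imageData(ws)), H, W)

  # watershed occasionally leaves a label with tiny detached slivers; keep
  # each label's largest 8-connected component so masks are single objects
  for (l in setdiff(unique(as.vector(lab)), 0L)) {
    pix <- which(lab == l, arr.ind = TRUE)
    r0 <- min(pix[, 1]); r1 <- max(pix[, 1]); c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == l
    cc <- label8(sub)
    if (max(cc) > 1) {
      main <- which.max(tabulate(cc[cc > 0]))
      drop <- sub & cc != main
      lab[r0:r1, c0:c1][drop] <- 0L
    }
  }

  # area filter + sequential relabel
  px_area <- pixel_size^2
  cnt <- tabulate(lab[lab > 0])
  ok <- which(cnt * px_area >= min_area)
  if (length(ok) == 0) return(empty)
  remap <- integer(max(lab) + 1L)
  remap[ok + 1L] <- seq_along(ok)
  lab <- matrix(remap[lab + 1L], H, W)

  tabl <- lapply(seq_along(ok), function(l) {
    pix <- which(lab == l, arr.ind = TRUE)
    wts <- pmax(dens[pix], 0)
    if (sum(wts) == 0) wts <- rep(1, nrow(pix))
    data.frame(label = l,
               area_um2 = nrow(pix) * px_area,
               x_um = sum(wts * (pix[, 2] - 1)) / sum(wts) * pixel_size,
               y_um = sum(wts * (pix[, 1] - 1)) / sum(wts) * pixel_size,
               border = any(pix[, 1] %in% c(1L, H) | pix[, 2] %in% c(1L, W)))
  })
  list(labels = lab, table = do.call(rbind, tabl))
}

#' Segment every frame of a phase movie
#'
#' @param movie a `phase_movie`.
#' @param ... passed to [segment_frame()].
#' @param quiet suppress progress messages.
#' @return List with `labels` (list of label matrices) and `table`
#'   (per-frame object table with a `frame` column), ready for
#'   [link_tracks()].
#' @export
segment_movie <- function(movie, ..., quiet = TRUE) {
  n_fr <- dim(movie$phase)[3]
  labels <- vector("list", n_fr)
  tabs <- vector("list", n_fr)
  for (f in seq_len(n_fr)) {
    sg <- segment_frame(movie$phase[, , f], movie$pixel_size,
                        movie$wavelength, movie$alpha, ...)
    labels[[f]] <- sg$labels
    if (nrow(sg$table)) tabs[[f]] <- cbind(frame = f, sg$table)
    if (!quiet && f %% 50 == 0) message("segmented frame ", f, "/", n_fr)
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  list(labels = labels, table = tab,
       pixel_size = movie$pixel_size, frame_interval = movie$frame_interval)
}

#' Otsu threshold on a value vector
#'
#' Maximises the between-class variance over a 256-bin histogram. Exposed
#' because segmentation thresholds are worth inspecting.
#'
#' @param v numeric vector.
#' @param n_bins histogram bins.
#' @return Threshold value.
#' @export
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(w)
  mu1 <- cumsum(w * mids)
  muT <- mu1[n_bins]
  bc <- (muT * w1 - mu1)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}
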