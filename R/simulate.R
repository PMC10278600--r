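#' Simulate a quantitative phase time-lapse movie with ground truth
#'
#' Generates a synthetic QPI recording of adherent cells migrating by a
#' persistent random walk, as a stack of phase maps in radians, together with
#' exact per-frame ground truth. Each cell is an anisotropic 2-D Gaussian
#' dry-mass profile truncated at 3 sigma, its long axis aligned with the
#' instantaneous velocity, rasterised so that the integrated dry mass over the
#' footprint equals the cell's nominal mass exactly. Velocities follow a
#' stationary Ornstein-Uhlenbeck process whose scale is set so that the mean
#' sampled step speed equals `speed_mean * drug_effect`; directional
#' persistence is controlled by `persistence_time`. Cells reflect at the field
#' edges (tracks stay complete) and keep a minimum pairwise centre distance so
#' that neighbours never fuse. Phase is obtained from dry-mass density by
#' `phi = M * 2 * pi * alpha / lambda`, plus optional Gaussian phase noise.
#'
#' With `division_rate > 0`, a dividing cell rounds up over the 3 frames
#' before the split and is then replaced by two daughters of half mass;
#' lineage is recorded in the ground truth.
#'
#' @param config a [sim_config()].
#' @param rasterize render the phase stack (default). With `FALSE` only the
#'   motion model runs and `phase` is `NULL` — handy for Monte-Carlo studies
#'   of the ground-truth motion statistics.
#' @param quiet suppress progress output.
#'
#' @return An object of class `phase_movie`: a list with
#'   \describe{
#'     \item{phase}{numeric array `c(height, width, n_frames)`, radians.}
#'     \item{pixel_size, frame_interval, wavelength, alpha}{acquisition
#'       metadata (um/pixel, min, um, um^3/pg).}
#'     \item{ground_truth}{list with `frames` (one row per cell per frame:
#'       `frame`, `cell_id`, `t_h`, `x_um`, `y_um`, `mass_pg`, `sigma_maj_um`,
#'       `sigma_min_um`, `theta`) and `cells` (per-cell summary: lifetime,
#'       lineage, true mean speed um/h, true meandering index).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' mv <- simulate_movie(sim_config(n_cells = 3, field_size = c(128, 128),
#'                                 n_frames = 5, seed = 7))
#' dim(mv$phase)
simulate_movie <- function(config, rasterize = TRUE, quiet = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  H <- cfg$field_size[1]; W <- cfg$field_size[2]
  px <- cfg$pixel_size
  Ly <- H * px; Lx <- W * px
  dt_h <- cfg$frame_interval / 60
  n_fr <- cfg$n_frames

  # population draws
  mass <- pmax(rnorm(cfg$n_cells, cfg$cell_mass_mean, cfg$cell_mass_sd),
               0.2 * cfg$cell_mass_mean)
  radius <- pmax(rnorm(cfg$n_cells, cfg$cell_radius_mean, cfg$cell_radius_sd),
                 0.3 * cfg$cell_radius_mean)
  if (sum(pi * radius^2) > 0.8 * Lx * Ly) {
    stop("simulate_movie: total cell area exceeds the 80% field-density limit; ",
         "reduce n_cells or cell_radius, or enlarge the field")
  }

  # effective axis ratio after the drug's rounding shift
  e_drug <- 1 + (cfg$elongation - 1) * (1 - cfg$drug_circ_shift)

  # stationary OU scale: |v| is Rayleigh, E|v| = sigma * sqrt(pi/2);
  # displacement per frame is v * dt, so mean sampled step speed is E|v|
  target_speed <- cfg$speed_mean * cfg$drug_effect
  sig_v <- target_speed / sqrt(pi / 2)
  a_ou <- exp(-cfg$frame_interval / cfg$persistence_time)
  innov_sd <- sig_v * sqrt(1 - a_ou^2)

  # mutable per-cell state; daughters are appended as they are born
  cell <- list()
  place_margin <- function(r) pmin(3 * r, min(Lx, Ly) / 2 - px)
  positions <- matrix(NA_real_, 0, 2)
  for (i in seq_len(cfg$n_cells)) {
    m <- place_margin(radius[i])
    ok <- FALSE
    for (try in seq_len(5000)) {
      p <- c(runif(1, m, Lx - m), runif(1, m, Ly - m))
      if (nrow(positions) == 0 ||
          all(sqrt(rowSums(sweep(positions, 2, p)^2)) >=
              0.75 * (radius[seq_len(nrow(positions))] + radius[i]))) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("simulate_movie: could not place cells without overlap; ",
                  "field too crowded (80% density limit applies)")
    positions <- rbind(positions, p)
    v0 <- rnorm(2, 0, sig_v)
    cell[[i]] <- list(id = i, parent = NA_integer_, born = 1L,
                      mass = mass[i], radius = radius[i],
                      pos = p, vel = v0,
                      theta = if (sqrt(sum(v0^2)) > 1e-9) atan2(v0[2], v0[1]) else runif(1, 0, pi),
                      alive = TRUE, split_at = NA_integer_)
  }
  next_id <- cfg$n_cells + 1L
  p_div <- cfg$division_rate * dt_h

  reflect <- function(x, lo, hi) {
    # fold back into [lo, hi]; flips sign an odd number of times when reflected
    flips <- 0L
    while (x < lo || x > hi) {
      if (x < lo) x <- 2 * lo - x else x <- 2 * hi - x
      flips <- flips + 1L
    }
    list(x = x, flip = flips %% 2L == 1L)
  }

  rows <- vector("list", n_fr)
  state_row <- function(cl, f) {
    e_eff <- e_drug
    if (!is.na(cl$split_at)) {
      # round up over the 3 frames preceding the split
      k <- cl$split_at - f
      e_eff <- 1 + (e_drug - 1) * max(0, min(1, (k - 0) / 3))
    }
    s_iso <- cl$radius / 3
    data.frame(frame = f, cell_id = cl$id, t_h = (f - 1) * dt_h,
               x_um = cl$pos[1], y_um = cl$pos[2], mass_pg = cl$mass,
               sigma_maj_um = s_iso * sqrt(e_eff),
               sigma_min_um = s_iso / sqrt(e_eff),
               theta = cl$theta)
  }
  rows[[1]] <- do.call(rbind, lapply(cell, state_row, f = 1L))

  for (f in 2:n_fr) {
    alive_idx <- which(vapply(cell, `[[`, TRUE, "alive"))
    # OU velocity update
    for (i in alive_idx) {
      cell[[i]]$vel <- a_ou * cell[[i]]$vel + rnorm(2, 0, innov_sd)
    }
    # excluded volume, resolved in velocity space before moving: pairs that
    # would end the step closer than contact distance and are approaching
    # exchange their radial velocity components (equal-mass elastic
    # exchange, akin to contact inhibition of locomotion). This preserves
    # the population speed distribution; the residual positional clamp
    # below then rarely engages.
    if (length(alive_idx) > 1) {
      for (ii in seq_along(alive_idx)) {
        for (jj in seq_len(ii - 1L)) {
          i <- alive_idx[ii]; j <- alive_idx[jj]
          dmin <- 0.75 * (cell[[i]]$radius + cell[[j]]$radius)
          pn_i <- cell[[i]]$pos + cell[[i]]$vel * dt_h
          pn_j <- cell[[j]]$pos + cell[[j]]$vel * dt_h
          if (sqrt(sum((pn_i - pn_j)^2)) < dmin) {
            d <- cell[[i]]$pos - cell[[j]]$pos
            dist <- sqrt(sum(d^2))
            u <- if (dist > 1e-9) d / dist else c(1, 0)
            vi_r <- sum(cell[[i]]$vel * u); vj_r <- sum(cell[[j]]$vel * u)
            if (vi_r - vj_r < 0) {  # approaching
              cell[[i]]$vel <- cell[[i]]$vel + (vj_r - vi_r) * u
              cell[[j]]$vel <- cell[[j]]$vel + (vi_r - vj_r) * u
            }
          }
        }
      }
    }
    # Euler position update with reflective boundaries
    for (i in alive_idx) {
      cl <- cell[[i]]
      cl$pos <- cl$pos + cl$vel * dt_h
      m <- place_margin(cl$radius)
      rx <- reflect(cl$pos[1], m, Lx - m); ry <- reflect(cl$pos[2], m, Ly - m)
      cl$pos <- c(rx$x, ry$x)
      if (rx$flip) cl$vel[1] <- -cl$vel[1]
      if (ry$flip) cl$vel[2] <- -cl$vel[2]
      sp <- sqrt(sum(cl$vel^2))
      if (sp > 1e-9) cl$theta <- atan2(cl$vel[2], cl$vel[1])
      cell[[i]] <- cl
    }
    # residual overlap clamp (e.g. multi-body contacts)
    if (length(alive_idx) > 1) {
      for (ii in seq_along(alive_idx)) {
        for (jj in seq_len(ii - 1L)) {
          i <- alive_idx[ii]; j <- alive_idx[jj]
          d <- cell[[i]]$pos - cell[[j]]$pos
          dist <- sqrt(sum(d^2))
          dmin <- 0.75 * (cell[[i]]$radius + cell[[j]]$radius)
          if (dist < dmin) {
            u <- if (dist > 1e-9) d / dist else c(1, 0)
            shift <- (dmin - dist) / 2
            m_i <- place_margin(cell[[i]]$radius); m_j <- place_margin(cell[[j]]$radius)
            cell[[i]]$pos <- pmin(pmax(cell[[i]]$pos + u * shift, c(m_i, m_i)),
                                  c(Lx - m_i, Ly - m_i))
            cell[[j]]$pos <- pmin(pmax(cell[[j]]$pos - u * shift, c(m_j, m_j)),
                                  c(Lx - m_j, Ly - m_j))
          }
        }
      }
    }
    # schedule and execute divisions
    if (p_div > 0) {
      for (i in alive_idx) {
        if (is.na(cell[[i]]$split_at) && runif(1) < p_div && f + 3L <= n_fr) {
          cell[[i]]$split_at <- f + 3L
        }
      }
    }
    for (i in alive_idx) {
      cl <- cell[[i]]
      if (!is.na(cl$split_at) && f == cl$split_at) {
        cell[[i]]$alive <- FALSE
        u <- runif(1, 0, 2 * pi); dir <- c(cos(u), sin(u))
        r_d <- cl$radius / sqrt(2)
        for (s in c(-1, 1)) {
          pos_d <- cl$pos + s * dir * 0.8 * r_d
          m <- place_margin(r_d)
          pos_d <- pmin(pmax(pos_d, c(m, m)), c(Lx - m, Ly - m))
          v_d <- rnorm(2, 0, sig_v)
          cell[[next_id]] <- list(id = next_id, parent = cl$id, born = f,
                                  mass = cl$mass / 2, radius = r_d,
                                  pos = pos_d, vel = v_d,
                                  theta = atan2(v_d[2], v_d[1]),
                                  alive = TRUE, split_at = NA_integer_)
          next_id <- next_id + 1L
        }
      }
    }
    alive_idx <- which(vapply(cell, `[[`, TRUE, "alive"))
    rows[[f]] <- do.call(rbind, lapply(cell[alive_idx], state_row, f = f))
  }
  gt_frames <- do.call(rbind, rows)
  rownames(gt_frames) <- NULL

  # rasterise dry-mass density and convert to phase
  phase <- if (rasterize) array(0, dim = c(H, W, n_fr)) else NULL
  phase_per_density <- 2 * pi * cfg$alpha / cfg$wavelength
  for (f in if (rasterize) seq_len(n_fr) else integer(0)) {
    dens <- matrix(0, H, W)
    fr <- gt_frames[gt_frames$frame == f, , drop = FALSE]
    for (k in seq_len(nrow(fr))) {
      dens <- add_gaussian_cell(dens, fr$x_um[k], fr$y_um[k], fr$mass_pg[k],
                                fr$sigma_maj_um[k], fr$sigma_min_um[k],
                                fr$theta[k], px)
    }
    fp <- dens * phase_per_density
    if (cfg$noise_sd > 0) fp <- fp + rnorm(H * W, 0, cfg$noise_sd)
    phase[, , f] <- fp
    if (!quiet && f %% 50 == 0) message("rasterised frame ", f, "/", n_fr)
  }

  # per-cell ground-truth motion summaries from the realised paths
  cells <- lapply(split(gt_frames, gt_frames$cell_id), function(d) {
    d <- d[order(d$frame), ]
    steps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    path <- sum(steps)
    eucl <- sqrt((d$x_um[nrow(d)] - d$x_um[1])^2 + (d$y_um[nrow(d)] - d$y_um[1])^2)
    data.frame(cell_id = d$cell_id[1],
               parent = cell[[d$cell_id[1]]]$parent,
               born_frame = d$frame[1], last_frame = d$frame[nrow(d)],
               mass_pg = d$mass_pg[1], radius_um = cell[[d$cell_id[1]]]$radius,
               mean_speed_um_h = if (length(steps)) mean(steps) / dt_h else NA_real_,
               meandering = if (path > 0) eucl / path else 0)
  })
  gt_cells <- do.call(rbind, cells)
  rownames(gt_cells) <- NULL

  structure(list(phase = phase, pixel_size = px,
                 frame_interval = cfg$frame_interval,
                 wavelength = cfg$wavelength, alpha = cfg$alpha,
                 ground_truth = list(frames = gt_frames, cells = gt_cells),
                 config = cfg),
            class = "phase_movie")
}

# Add one truncated anisotropic Gaussian dry-mass blob to a density map.
# The profile is rescaled so the rasterised footprint integrates to mass_pg
# exactly (pixel area px^2), making ground-truth mass exact by construction.
add_gaussian_cell <- function(dens, cx, cy, mass_pg, s_maj, s_min, theta, px) {
  H <- nrow(dens); W <- ncol(dens)
  r_ext <- 3 * s_maj
  c0 <- max(1L, floor((cx - r_ext) / px) + 1L)
  c1 <- min(W, ceiling((cx + r_ext) / px) + 1L)
  r0 <- max(1L, floor((cy - r_ext) / px) + 1L)
  r1 <- min(H, ceiling((cy + r_ext) / px) + 1L)
  if (c0 > c1 || r0 > r1) return(dens)
  xs <- (seq(c0, c1) - 1) * px - cx
  ys <- (seq(r0, r1) - 1) * px - cy
  ct <- cos(theta); st <- sin(theta)
  Xm <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Ym <- matrix(ys, nrow = length(ys), ncol = length(xs))
  u <- (Xm * ct + Ym * st) / s_maj
  w <- (-Xm * st + Ym * ct) / s_min
  r2 <- u^2 + w^2
  g <- ifelse(r2 <= 9, exp(-r2 / 2), 0)
  s <- sum(g)
  if (s > 0) {
    dens[r0:r1, c0:c1] <- dens[r0:r1, c0:c1] + g * (mass_pg / (s * px^2))
  }
  dens
}

#' Forward model of an off-axis hologram
#'
#' Encodes a phase map into carrier fringes:
#' `I(x, y) = 1 + contrast * cos(2 * pi * (fx * x + fy * y) + phi(x, y))`,
#' with pixel coordinates starting at 0. The carrier must sit below Nyquist
#' (0.5 cycles/pixel) and high enough that the Fourier sidebands separate from
#' the autocorrelation term.
#'
#' @param phase_map numeric matrix, radians.
#' @param carrier_frequency carrier in cycles/pixel; a scalar is taken along
#'   x (columns), or give `c(fx, fy)`.
#' @param fringe_contrast fringe modulation depth in `[0, 1]`.
#' @return Intensity matrix (non-negative) with attributes `carrier` and
#'   `contrast`, class `hologram`.
#' @seealso [reconstruct_phase()]
#' @export
simulate_hologram <- function(phase_map, carrier_frequency, fringe_contrast = 0.8) {
  stopifnot(is.matrix(phase_map), all(is.finite(phase_map)),
            fringe_contrast >= 0, fringe_contrast <= 1)
  f <- carrier_frequency
  if (length(f) == 1) f <- c(f, 0)
  fm <- sqrt(sum(f^2))
  if (fm >= 0.5) stop("simulate_hologram: carrier at or above Nyquist (0.5 cycles/pixel)")
  if (fm < 0.05) stop("simulate_hologram: carrier too low to separate the sidebands; ",
                      "use at least 0.05 cycles/pixel")
  H <- nrow(phase_map); W <- ncol(phase_map)
  X <- matrix(0:(W - 1), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1), H, W)
  I <- 1 + fringe_contrast * cos(2 * pi * (f[1] * X + f[2] * Y) + phase_map)
  structure(I, carrier = f, contrast = fringe_contrast, class = c("hologram", "matrix"))
}
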