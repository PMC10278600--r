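test_that("config validation enforces the physical invariants", {
  expect_error(sim_config(n_frames = 1))
  expect_error(sim_config(elongation = 0.5))
  expect_error(sim_config(alpha = 0))
  expect_error(sim_config(drug_effect = 0))
  # paper-style acquisition: 20 h at 5-minute intervals is 241 frames
  cfg <- sim_config()
  expect_equal(cfg$n_frames, 241)
  expect_equal(cfg$frame_interval, 5)
})

test_that("a motionless noise-free cell keeps WCG and mass constant", {
  cfg <- small_sim(n_cells = 1, speed_mean = 0, noise_sd = 0, n_frames = 6,
                   elongation = 1)
  mv <- simulate_movie(cfg)
  gt <- mv$ground_truth$frames
  expect_equal(length(unique(gt$x_um)), 1)
  expect_equal(length(unique(gt$y_um)), 1)
  # recompute mass per frame from the rendered phase
  px <- mv$pixel_size
  masses <- sapply(seq_len(dim(mv$phase)[3]), function(f) {
    sum(dry_mass_density(mv$phase[, , f], mv$wavelength, mv$alpha)) * px^2
  })
  expect_equal(max(masses) - min(masses), 0, tolerance = 1e-8)
  expect_equal(masses[1], gt$mass_pg[1], tolerance = 1e-6)
})

test_that("identical seed and config give bit-identical movies", {
  cfg <- small_sim(seed = 7, noise_sd = 0.02, n_frames = 5)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$phase, b$phase)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("rendered dry mass matches ground truth cell by cell", {
  cfg <- small_sim(n_cells = 3, n_frames = 3, noise_sd = 0)
  mv <- simulate_movie(cfg)
  px <- mv$pixel_size
  for (f in 1:3) {
    dens <- dry_mass_density(mv$phase[, , f], mv$wavelength, mv$alpha)
    gt <- mv$ground_truth$frames
    tot <- sum(gt$mass_pg[gt$frame == f])
    expect_equal(sum(dens) * px^2, tot, tolerance = 0.01)
  }
})

test_that("overcrowded configurations are rejected by the density limit", {
  expect_error(simulate_movie(sim_config(n_cells = 60, field_size = c(128, 128),
                                         cell_radius_mean = 15)),
               "density limit")
})

test_that("sampled step speeds recover the commanded mean speed", {
  # empirical mean step length / interval vs speed_mean * drug_effect
  for (eff in c(1, 0.5)) {
    sp <- sapply(1:3, function(s) {
      mv <- simulate_movie(sim_config(n_cells = 10, speed_mean = 30,
                                      drug_effect = eff, n_frames = 241,
                                      seed = s), rasterize = FALSE)
      mean(mv$ground_truth$cells$mean_speed_um_h)
    })
    expect_lt(abs(mean(sp) / (30 * eff) - 1), 0.10)
  }
})

test_that("ground-truth meandering rises with persistence and reaches 1", {
  # large sparse field so boundary reflections do not fold the paths
  mi <- sapply(c(5, 60, 1e5), function(P) {
    mv <- simulate_movie(sim_config(n_cells = 6, field_size = c(3000, 3000),
                                    persistence_time = P, n_frames = 121,
                                    seed = 2), rasterize = FALSE)
    mean(mv$ground_truth$cells$meandering)
  })
  expect_true(all(diff(mi) > 0))
  expect_gt(mi[3], 0.99)
})

test_that("WCG paths are continuous and divisions halve mass with lineage", {
  cfg <- small_sim(n_cells = 4, n_frames = 40, division_rate = 0.4,
                   field_size = c(512, 512), seed = 8)
  mv <- simulate_movie(cfg, rasterize = FALSE)
  gt <- mv$ground_truth
  expect_gt(sum(!is.na(gt$cells$parent)), 0)
  for (cid in gt$cells$cell_id[!is.na(gt$cells$parent)]) {
    par <- gt$cells$parent[gt$cells$cell_id == cid]
    expect_equal(gt$cells$mass_pg[gt$cells$cell_id == cid],
                 gt$cells$mass_pg[gt$cells$cell_id == par] / 2)
  }
  # per-step displacement bounded (no teleporting within a track)
  dt_h <- cfg$frame_interval / 60
  for (cid in unique(gt$frames$cell_id)) {
    d <- gt$frames[gt$frames$cell_id == cid, ]
    if (nrow(d) < 2) next
    steps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    expect_lt(max(steps), 60 * dt_h * 20)  # generous bound ~20x mean speed
  }
})

test_that("hologram forward model produces the expected fringes", {
  n <- 128
  ph0 <- matrix(0, n, n)
  h <- simulate_hologram(ph0, 0.25, fringe_contrast = 0.6)
  x <- 0:(n - 1)
  expect_equal(unclass(h)[1, ], 1 + 0.6 * cos(2 * pi * 0.25 * x),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(h >= 0))
  # zero contrast: constant image
  expect_equal(max(simulate_hologram(ph0, 0.25, 0)) -
               min(simulate_hologram(ph0, 0.25, 0)), 0)
  expect_error(simulate_hologram(ph0, 0.6), "Nyquist")
  expect_error(simulate_hologram(ph0, 0.01), "too low")
})

test_that("a phase ramp displaces the Fourier sideband by its frequency", {
  n <- 256
  g <- 8 / n                      # ramp frequency, cycles/pixel
  f <- 64 / n                     # carrier
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  h <- simulate_hologram(2 * pi * g * X, f)
  spec <- Mod(stats::fft(unclass(h)[1, ]))
  spec[1] <- 0                    # drop DC
  peak_bin <- which.max(spec[1:(n / 2)]) - 1
  expect_equal(peak_bin, (f + g) * n)
})

test_that("phase movies and labels survive the TIFF round trip", {
  cfg <- small_sim(n_cells = 2, n_frames = 3, field_size = c(160, 160),
                   cell_radius_mean = 8, cell_radius_sd = 1, noise_sd = 0.01)
  mv <- simulate_movie(cfg)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_phase_movie(mv, tf)
  mv2 <- read_phase_movie(tf)
  expect_lt(max(abs(mv2$phase - mv$phase)), 1e-6)
  expect_equal(mv2$pixel_size, mv$pixel_size)
  expect_equal(mv2$wavelength, mv$wavelength)
  seg <- segment_movie(mv)
  lf <- withr::local_tempfile(fileext = ".tif")
  write_label_movie(seg$labels, lf)
  expect_identical(read_label_movie(lf), seg$labels)
  gt_csv <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(mv, gt_csv)
  gt <- read.csv(gt_csv)
  expect_named(gt, c("frame", "cell_id", "t_h", "x_um", "y_um", "mass_pg"))
})
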