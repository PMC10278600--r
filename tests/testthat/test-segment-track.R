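test_that("well-separated blobs segment into the right labels and centroids", {
  n <- 256
  centers <- rbind(c(60, 60), c(180, 170))
  phi <- blob_phase(n, centers, sigma_px = 12, peak_rad = 2)
  sg <- segment_frame(phi, pixel_size = 1)
  expect_equal(nrow(sg$table), 2)
  got <- sg$table[order(sg$table$x_um), ]
  expect_lt(max(abs(got$x_um - centers[, 1])), 1)
  expect_lt(max(abs(got$y_um - centers[, 2])), 1)
})

test_that("a pure-noise frame yields no labels", {
  set.seed(31)
  phi <- matrix(rnorm(256 * 256, 0, 0.02), 256, 256)
  sg <- segment_frame(phi, pixel_size = 0.65)
  expect_equal(nrow(sg$table), 0)
  expect_true(all(sg$labels == 0))
})

test_that("blobs overlapping by 30% of their radius are split by watershed", {
  n <- 256
  sigma <- 10; R <- 3 * sigma          # visible radius
  d <- 1.7 * R                          # centre distance: 30% radius overlap
  centers <- rbind(c(80, 120), c(80 + d, 120))
  phi <- blob_phase(n, centers, sigma_px = sigma, peak_rad = 2, trunc = 3)
  sg <- segment_frame(phi, pixel_size = 1)
  expect_equal(nrow(sg$table), 2)
})

test_that("non-finite pixels are rejected and min_area is monotone", {
  phi <- blob_phase(128, cbind(60, 60), sigma_px = 8, peak_rad = 2)
  bad <- phi; bad[5, 5] <- NA
  expect_error(segment_frame(bad, 1), "non-finite")
  counts <- sapply(c(10, 100, 400, 2000), function(a) {
    nrow(segment_frame(phi, 1, min_area = a)$table)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation conserves total dry mass on noise-free movies", {
  mv <- simulate_movie(small_sim(n_cells = 5, n_frames = 4, field_size = c(384, 384)))
  seg <- segment_movie(mv)
  px <- mv$pixel_size
  for (f in c(1, 4)) {
    dens <- dry_mass_density(mv$phase[, , f], mv$wavelength, mv$alpha)
    m_seg <- sum(dens[seg$labels[[f]] > 0]) * px^2
    m_gt <- sum(mv$ground_truth$frames$mass_pg[mv$ground_truth$frames$frame == f])
    expect_lt(abs(m_seg / m_gt - 1), 0.05)
  }
})

test_that("a single moving cell is linked into one full-length track", {
  mv <- simulate_movie(small_sim(n_cells = 1, n_frames = 241,
                                 field_size = c(192, 192), speed_mean = 20,
                                 cell_radius_mean = 10, cell_radius_sd = 0))
  trk <- link_tracks(segment_movie(mv))
  expect_equal(length(unique(trk$table$track_id)), 1)
  expect_equal(nrow(trk$table), 241)
})

test_that("optimal matching preserves identities when cells pass nearby", {
  # two tracks approaching to 12 um and moving apart, steps well under the
  # gate: greedy-by-order could swap them, minimal total distance cannot
  frames <- 21
  t <- seq_len(frames)
  xa <- 50 + 2 * t; ya <- rep(50, frames)
  xb <- 150 - 2 * t; yb <- rep(62, frames)
  tab <- rbind(
    data.frame(frame = t, label = 1L, x_um = xa, y_um = ya, border = FALSE),
    data.frame(frame = t, label = 2L, x_um = xb, y_um = yb, border = FALSE))
  seg <- list(labels = vector("list", frames), table = tab)
  seg$labels <- lapply(seq_len(frames), function(f) matrix(0L, 1, 1))
  trk <- link_tracks(seg, max_link_distance = 15)
  got <- trk$table
  ida <- unique(got$track_id[got$label == 1])
  idb <- unique(got$track_id[got$label == 2])
  expect_length(ida, 1)
  expect_length(idb, 1)
  expect_false(ida == idb)
})

test_that("a division closes the parent and opens two linked daughters", {
  frames <- 10
  tab <- do.call(rbind, lapply(seq_len(frames), function(f) {
    if (f <= 5) {
      data.frame(frame = f, label = 1L, x_um = 100 + f, y_um = 100, border = FALSE)
    } else {
      rbind(data.frame(frame = f, label = 1L, x_um = 100 + f, y_um = 92, border = FALSE),
            data.frame(frame = f, label = 2L, x_um = 100 + f, y_um = 108, border = FALSE))
    }
  }))
  seg <- list(labels = lapply(seq_len(frames), function(f) matrix(0L, 1, 1)),
              table = tab)
  trk <- link_tracks(seg, max_link_distance = 15)
  lin <- trk$lineage
  parent <- lin$track_id[is.na(lin$parent)]
  daughters <- lin$track_id[!is.na(lin$parent)]
  expect_length(parent, 1)
  expect_length(daughters, 2)
  expect_true(all(lin$parent[!is.na(lin$parent)] == parent))
  expect_equal(lin$end_frame[lin$track_id == parent], 5)
  expect_true(all(lin$start_frame[lin$track_id %in% daughters] == 6))
})

test_that("tracking tolerates short disappearances up to max_gap", {
  frames <- 9
  present <- setdiff(seq_len(frames), c(4, 5))
  tab <- data.frame(frame = present, label = 1L, x_um = 100 + 2 * present,
                    y_um = 50, border = FALSE)
  seg <- list(labels = lapply(seq_len(frames), function(f) matrix(0L, 1, 1)),
              table = tab)
  trk <- link_tracks(seg, max_link_distance = 15, max_gap = 2)
  expect_equal(length(unique(trk$table$track_id)), 1)
  trk2 <- link_tracks(seg, max_link_distance = 15, max_gap = 0)
  expect_equal(length(unique(trk2$table$track_id)), 2)
})

test_that("a table referencing frames beyond the movie errors", {
  seg <- list(labels = list(matrix(0L, 1, 1)),
              table = data.frame(frame = 2, label = 1L, x_um = 1, y_um = 1,
                                 border = FALSE))
  expect_error(link_tracks(seg), "beyond")
})
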