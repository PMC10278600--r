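test_that("circularity bins follow the four-class table with upward boundaries", {
  expect_equal(as.character(classify_circularity(30)), "Elongated")
  expect_equal(as.character(classify_circularity(80)), "Rounded")
  expect_equal(as.character(classify_circularity(25)), "Elongated")   # boundary up
  expect_equal(as.character(classify_circularity(50)), "Oval")
  expect_equal(as.character(classify_circularity(100)), "Rounded")
  expect_equal(as.character(classify_circularity(10)), "VeryElongated")
  expect_error(classify_circularity(0), "\\(0, 100\\]")
  expect_error(classify_circularity(100.5), "\\(0, 100\\]")
  # bins partition (0, 100]: classification is total
  v <- c(seq(0.5, 100, by = 0.5))
  expect_false(anyNA(classify_circularity(v)))
})

test_that("invasive calls require both displacement and directionality", {
  t <- c(0, 10, 20)
  # straight diagonal: euclid 141.4 um, MI 100%
  straight <- call_invasive(t, c(0, 50, 100), c(0, 50, 100), 20)
  expect_true(straight$invasive)
  expect_equal(straight$euclid_um, sqrt(2) * 100, tolerance = 1e-10)
  # long path, small net displacement: fails the distance arm
  wig <- call_invasive(c(0, 5, 10, 15, 20), c(0, 200, 50, 220, 50),
                       c(0, 0, 0, 0, 0), 20)
  expect_false(wig$invasive)
  # boundary: exactly 100 um and MI above threshold is NOT invasive (strict)
  edge <- call_invasive(c(0, 20), c(0, 100), c(0, 0), 20)
  expect_equal(edge$euclid_um, 100)
  expect_false(edge$invasive)
  # track ending long before the evaluation time is excluded
  expect_null(call_invasive(c(0, 5), c(0, 10), c(0, 0), 20))
})

test_that("invasive fraction counts eligible tracks only", {
  t <- seq(0, 20, by = 1 / 12)
  mk <- function(id, v) straight_track_features(id, t, 0, 0, v, 0)
  # 3 fast straight movers out of 10 cells
  feats <- do.call(rbind, c(lapply(1:3, function(i) mk(i, 10)),
                            lapply(4:10, function(i) mk(i, 2))))
  iv <- invasive_fraction(feats, 20)
  expect_equal(iv$fraction_pct, 30)
  expect_equal(iv$n_eligible, 10)
  # all stationary: 0%
  still <- do.call(rbind, lapply(1:5, function(i) mk(i, 0)))
  expect_equal(invasive_fraction(still, 20)$fraction_pct, 0)
  # monotone non-increasing in either threshold
  f1 <- invasive_fraction(feats, 20, dist_threshold = 100)$fraction_pct
  f2 <- invasive_fraction(feats, 20, dist_threshold = 150)$fraction_pct
  f3 <- invasive_fraction(feats, 20, mi_threshold = 60)$fraction_pct
  expect_lte(f2, f1)
  expect_lte(f3, f1)
})

test_that("control QC flags cell loss, morphology drift and speed drift", {
  t <- seq(0, 20, by = 1 / 12)
  healthy <- do.call(rbind, lapply(1:6, function(i) {
    straight_track_features(i, t, 10 * i, 5 * i, 3, 1)
  }))
  qc <- qc_control(healthy)
  expect_false(qc$flags$count_decrease)
  expect_false(qc$flags$morphology_drift)
  expect_false(qc$flags$speed_drift)

  # death-like scenario: half the cells vanish mid-way, survivors shrink
  # to 40% of their mass and stall in the second half
  dying <- do.call(rbind, lapply(1:6, function(i) {
    d <- straight_track_features(i, t, 10 * i, 5 * i, 3, 1)
    d$mass_pg <- 250 * (1 - 0.6 * d$time_h / 20)
    d$area_um2 <- d$mass_pg / 0.3
    if (i > 3) d <- d[d$time_h <= 10, ]
    d
  }))
  qc2 <- qc_control(dying)
  expect_true(qc2$flags$count_decrease)
  expect_true(qc2$flags$morphology_drift)
})

test_that("period summaries pool values and track density snapshots", {
  t <- seq(0, 20, by = 1 / 12)
  const <- do.call(rbind, lapply(1:4, function(i) {
    straight_track_features(i, t, 0, 0, 2, 0, dens = 0.3)
  }))
  s <- period_summaries(const)
  expect_equal(s$changes$change_pct, c(0, 0, 0))
  expect_equal(s$snapshots$density_pg_per_um2, rep(0.3, 3))

  # density doubling linearly over 20 h: 0 -> 20 h change is +100%
  lin <- const
  lin$density_pg_per_um2 <- 0.3 * (1 + lin$time_h / 20)
  s2 <- period_summaries(lin)
  expect_equal(s2$changes$change_pct[s2$changes$from_h == 0 &
                                     s2$changes$to_h == 20], 100)

  # exponential growth at 3%/h: first-10-h change matches exp(0.3) - 1
  ex <- const
  ex$density_pg_per_um2 <- 0.3 * exp(0.03 * ex$time_h)
  s3 <- period_summaries(ex)
  got <- s3$changes$change_pct[s3$changes$from_h == 0 & s3$changes$to_h == 10]
  expect_equal(got, 100 * (exp(0.3) - 1), tolerance = 0.03)

  # pooled populations split at the period boundary
  expect_setequal(unique(s$pooled$period), c("00.00-10.00", "10.00-20.00"))
})

test_that("a fast high-persistence population is overwhelmingly invasive", {
  # free-field conditions (large sparse field): the analytic joint bound
  # P(euclid > max(100, 0.25 * path)) ~ exp(-200^2 / (4 D t)) gives ~0.78
  # at 40 um/h with 2 h persistence over 20 h
  mv <- simulate_movie(sim_config(n_cells = 50, field_size = c(8000, 8000),
                                  speed_mean = 40, persistence_time = 120,
                                  n_frames = 241, seed = 3), rasterize = FALSE)
  gt <- mv$ground_truth$frames
  names(gt)[names(gt) == "cell_id"] <- "track_id"
  gt$time_h <- gt$t_h
  frac <- invasive_fraction(gt, 20)$fraction_pct
  expect_gte(frac, 70)
  expect_lte(frac, 90)
})

test_that("slowing cells down lowers the expected invasive fraction", {
  frac_at <- function(eff) {
    mean(sapply(1:3, function(s) {
      mv <- simulate_movie(sim_config(n_cells = 40, field_size = c(4000, 4000),
                                      drug_effect = eff, n_frames = 241,
                                      seed = s), rasterize = FALSE)
      gt <- mv$ground_truth$frames
      names(gt)[names(gt) == "cell_id"] <- "track_id"
      gt$time_h <- gt$t_h
      invasive_fraction(gt, 20)$fraction_pct
    }))
  }
  fr <- sapply(c(1, 0.6, 0.3), frac_at)
  expect_true(all(diff(fr) < 0))
})
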