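#' Circularity classes
#'
#' The four morphology bins used to screen for invasive phenotypes, with
#' half-open `[lo, hi)` boundaries (a printed boundary value is assigned
#' upward) except the last bin, which includes 100.
#'
#' @return `data.frame` with `class`, `lo`, `hi`, `morphology`, `state`.
#' @export
circularity_classes <- function() {
  data.frame(
    class = c("VeryElongated", "Elongated", "Oval", "Rounded"),
    lo = c(0, 25, 50, 75), hi = c(25, 50, 75, 100),
    morphology = c("Very elongated", "Elongated", "Oval", "Rounded"),
    state = c("Anomalous or migratory cell - probably invasive phenotype",
              "Probably migratory",
              "Resting state",
              "Dividing cell or cell undergoing cell death"))
}

#' Classify a circularity percentage into its morphology bin
#'
#' @param value circularity in percent, in `(0, 100]`.
#' @return Factor with levels `VeryElongated`, `Elongated`, `Oval`,
#'   `Rounded`.
#' @export
#' @examples
#' classify_circularity(c(30, 80, 25))
classify_circularity <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0) || any(value > 100)) {
    stop("classify_circularity: circularity must lie in (0, 100]")
  }
  cls <- circularity_classes()
  idx <- findInterval(value, cls$lo)  # [lo, hi) bins; 100 falls in the last
  factor(cls$class[idx], levels = cls$class)
}

#' Call the invasive phenotype of one track
#'
#' A cell is called invasive at an evaluation time when its Euclidean
#' displacement from the track origin exceeds 100 um AND its meandering
#' index exceeds 25% — the upper-right quadrant of the displacement /
#' directionality plot. Both thresholds are strict.
#'
#' @param t,x,y track times (h) and WCG coordinates (um).
#' @param eval_time evaluation time, hours (typically 10 or 20).
#' @param dist_threshold Euclidean displacement threshold, um.
#' @param mi_threshold meandering-index threshold, percent.
#' @return List `euclid_um`, `meandering_pct`, `invasive`; or `NULL` when
#'   the track is not alive at `eval_time` (excluded from denominators).
#' @export
call_invasive <- function(t, x, y, eval_time,
                          dist_threshold = 100, mi_threshold = 25) {
  o <- order(t); t <- t[o]; x <- x[o]; y <- y[o]
  frame_h <- if (length(t) >= 2) min(diff(t)) else Inf
  if (max(t) < eval_time - frame_h - 1e-9 || min(t) > eval_time) return(NULL)
  keep <- t <= eval_time + 1e-9
  if (sum(keep) < 2) return(NULL)
  pe <- path_and_euclid(t[keep], x[keep], y[keep])
  mi <- if (pe[["path_um"]] > 0) 100 * pe[["euclid_um"]] / pe[["path_um"]] else 0
  list(euclid_um = unname(pe[["euclid_um"]]),
       meandering_pct = unname(mi),
       invasive = pe[["euclid_um"]] > dist_threshold && mi > mi_threshold)
}

#' Fraction of invasive cells at an evaluation time
#'
#' `100 * invasive / eligible`, where the eligible denominator counts tracks
#' alive at `eval_time`.
#'
#' @param features feature table (or any data.frame with `track_id`,
#'   `time_h`, `x_um`, `y_um`).
#' @inheritParams call_invasive
#' @return List `fraction_pct`, `n_invasive`, `n_eligible`, and the
#'   per-track calls in `calls`. `fraction_pct` is `NA` when no track is
#'   eligible.
#' @export
invasive_fraction <- function(features, eval_time,
                              dist_threshold = 100, mi_threshold = 25) {
  calls <- list()
  for (id in unique(features$track_id)) {
    d <- features[features$track_id == id, ]
    cl <- call_invasive(d$time_h, d$x_um, d$y_um, eval_time,
                        dist_threshold, mi_threshold)
    if (!is.null(cl)) {
      calls[[length(calls) + 1]] <- data.frame(track_id = id,
                                               euclid_um = cl$euclid_um,
                                               meandering_pct = cl$meandering_pct,
                                               invasive = cl$invasive)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(track_id = integer(), euclid_um = numeric(),
               meandering_pct = numeric(), invasive = logical())
  n_el <- nrow(calls)
  list(fraction_pct = if (n_el) 100 * sum(calls$invasive) / n_el else NA_real_,
       n_invasive = sum(calls$invasive), n_eligible = n_el, calls = calls)
}

#' Quality control of a control condition
#'
#' A healthy untreated control should gain (or at least keep) cells, keep
#' mass and area roughly stable, and migrate at a roughly constant speed.
#' Raises advisory flags when (a) the cell count drops over the recording,
#' (b) the mean mass or area changes by more than `tau_morph`
#' (relative, default 0.3), or (c) the second-period mean speed deviates from
#' the first by more than `tau_speed` (relative, default 0.5). Flags report,
#' they never abort.
#'
#' @param features feature table of the control condition.
#' @param periods two analysis periods (hours).
#' @param tau_morph,tau_speed advisory thresholds (relative changes).
#' @return List of class `qc_report`: counts, relative changes, period
#'   speeds and logical flags.
#' @export
qc_control <- function(features, periods = list(c(0, 10), c(10, 20)),
                       tau_morph = 0.3, tau_speed = 0.5) {
  f0 <- min(features$frame); f1 <- max(features$frame)
  count_start <- length(unique(features$track_id[features$frame == f0]))
  count_end <- length(unique(features$track_id[features$frame == f1]))
  ok <- !features$border
  m0 <- mean(features$mass_pg[features$frame == f0 & ok])
  m1 <- mean(features$mass_pg[features$frame == f1 & ok])
  a0 <- mean(features$area_um2[features$frame == f0 & ok])
  a1 <- mean(features$area_um2[features$frame == f1 & ok])
  dyn <- track_dynamics(features, periods = periods)
  pn <- sort(setdiff(unique(dyn$period), "full"))
  sp1 <- mean(dyn$mean_speed_um_h[dyn$period == pn[1]], na.rm = TRUE)
  sp2 <- mean(dyn$mean_speed_um_h[dyn$period == pn[2]], na.rm = TRUE)
  mass_change <- (m1 - m0) / m0
  area_change <- (a1 - a0) / a0
  speed_change <- (sp2 - sp1) / sp1
  rep <- list(count_start = count_start, count_end = count_end,
              mass_rel_change = mass_change, area_rel_change = area_change,
              period_mean_speeds = c(sp1, sp2), speed_rel_change = speed_change,
              flags = list(
                count_decrease = count_end < count_start,
                morphology_drift = abs(mass_change) > tau_morph ||
                                   abs(area_change) > tau_morph,
                speed_drift = abs(speed_change) > tau_speed))
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: cells", x$count_start, "->", x$count_end, "\n")
  cat(sprintf("  mass %+.1f%%, area %+.1f%%, speed period2 vs 1 %+.1f%%\n",
              100 * x$mass_rel_change, 100 * x$area_rel_change,
              100 * x$speed_rel_change))
  fl <- names(Filter(isTRUE, x$flags))
  cat("  flags:", if (length(fl)) paste(fl, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Per-period morphology distributions and density snapshots
#'
#' Pools per-cell-per-frame circularity and density values over each
#' analysis period (the boxplot populations), and reports mean density
#' snapshots at the requested times (nearest frame within +/- 15 min) with
#' the pairwise percent changes `100 * (d_b - d_a) / d_a` between
#' consecutive snapshots and first-to-last. Border-touching cells are
#' excluded from the morphology pools.
#'
#' @param features feature table.
#' @param periods list of `c(t_a, t_b)` hours.
#' @param snapshot_times_h density snapshot times, hours.
#' @param snap_tol_h nearest-frame tolerance for snapshots, hours.
#' @return List `pooled` (rows: period, frame values of circularity and
#'   density), `snapshots` (`time_h`, `density_pg_per_um2`, `n_cells`),
#'   `changes` (`from_h`, `to_h`, `change_pct`).
#' @export
period_summaries <- function(features, periods = list(c(0, 10), c(10, 20)),
                             snapshot_times_h = c(0, 10, 20),
                             snap_tol_h = 0.25) {
  ok <- !features$border
  per_names <- vapply(periods, function(p) sprintf("%05.2f-%05.2f", p[1], p[2]), "")
  pooled <- do.call(rbind, lapply(seq_along(periods), function(k) {
    p <- periods[[k]]
    sel <- ok & features$time_h >= p[1] & features$time_h <= p[2] + 1e-9
    if (!any(sel)) return(NULL)
    data.frame(period = per_names[k],
               time_h = features$time_h[sel],
               track_id = features$track_id[sel],
               circularity_pct = features$circularity_pct[sel],
               density_pg_per_um2 = features$density_pg_per_um2[sel])
  }))
  times <- sort(unique(features$time_h))
  snaps <- do.call(rbind, lapply(snapshot_times_h, function(ts) {
    i <- which.min(abs(times - ts))
    if (abs(times[i] - ts) > snap_tol_h) {
      return(data.frame(time_h = ts, density_pg_per_um2 = NA_real_, n_cells = 0L))
    }
    sel <- ok & features$time_h == times[i]
    data.frame(time_h = ts,
               density_pg_per_um2 = mean(features$density_pg_per_um2[sel]),
               n_cells = sum(sel))
  }))
  pairs <- cbind(seq_len(nrow(snaps) - 1), seq_len(nrow(snaps) - 1) + 1)
  if (nrow(snaps) > 2) pairs <- rbind(pairs, c(1, nrow(snaps)))
  changes <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- snaps[pairs[r, 1], ]; b <- snaps[pairs[r, 2], ]
    data.frame(from_h = a$time_h, to_h = b$time_h,
               change_pct = 100 * (b$density_pg_per_um2 - a$density_pg_per_um2) /
                 a$density_pg_per_um2)
  }))
  list(pooled = pooled, snapshots = snaps, changes = changes)
}
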