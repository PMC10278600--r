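#' Per-step migration speeds
#'
#' `Speed(t_n) = |WCG(t_n) - WCG(t_(n-1))| / (t_n - t_(n-1))`, one value per
#' interval, um/h.
#'
#' @param t times, hours (strictly increasing).
#' @param x,y WCG coordinates, um.
#' @return Numeric vector of length `length(t) - 1`.
#' @export
step_speeds <- function(t, x, y) {
  stopifnot(length(t) >= 2, length(x) == length(t), length(y) == length(t))
  dt <- diff(t)
  if (any(dt == 0)) stop("step_speeds: duplicate timestamps")
  if (any(dt < 0)) stop("step_speeds: times must be increasing")
  sqrt(diff(x)^2 + diff(y)^2) / dt
}

#' Path length and Euclidean displacement of a track
#'
#' @inheritParams step_speeds
#' @return `c(path_um, euclid_um)`.
#' @export
path_and_euclid <- function(t, x, y) {
  o <- order(t)
  x <- x[o]; y <- y[o]
  c(path_um = sum(sqrt(diff(x)^2 + diff(y)^2)),
    euclid_um = sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2))
}

#' Meandering index of a track
#'
#' Net (Euclidean) displacement from the track origin divided by the summed
#' step lengths: 1 for straight motion, 0 for a closed path. A fully
#' stationary track (zero path length) returns 0 by convention.
#'
#' @inheritParams step_speeds
#' @param up_to evaluate over `[t0, up_to]`; `NULL` uses the whole track.
#' @return Dimensionless value in `[0, 1]`.
#' @export
meandering_index <- function(t, x, y, up_to = NULL) {
  if (!is.null(up_to)) {
    if (up_to < min(t)) stop("meandering_index: up_to precedes the track start")
    keep <- t <= up_to + 1e-9
    t <- t[keep]; x <- x[keep]; y <- y[keep]
  }
  if (length(t) < 2) stop("meandering_index: need at least 2 points")
  pe <- path_and_euclid(t, x, y)
  if (pe[["path_um"]] == 0) return(0)
  unname(pe[["euclid_um"]] / pe[["path_um"]])
}

#' Mean speed of a track within an analysis period
#'
#' Averages the step speeds whose interval end falls in `(t_a, t_b]`. Tracks
#' contributing fewer than `min_steps` steps in the period are excluded from
#' population statistics (returns `NA`); tracks not overlapping the period
#' also return `NA`.
#'
#' @inheritParams step_speeds
#' @param period `c(t_a, t_b)`, hours.
#' @param min_steps minimum number of steps (default 12, i.e. 1 h at 5-min
#'   sampling).
#' @return Mean speed um/h, or `NA`.
#' @export
period_mean_speed <- function(t, x, y, period, min_steps = 12) {
  o <- order(t)
  t <- t[o]; x <- x[o]; y <- y[o]
  if (length(t) < 2) return(NA_real_)
  sp <- step_speeds(t, x, y)
  t_end <- t[-1]
  sel <- t_end > period[1] + 1e-9 & t_end <= period[2] + 1e-9
  if (sum(sel) < min_steps) return(NA_real_)
  mean(sp[sel])
}

#' Per-track, per-period migration summary
#'
#' One row per track per period: mean speed, path length, Euclidean
#' displacement and meandering index computed over the steps inside the
#' period, plus full-track values for `period = "full"`.
#'
#' @param features feature table from [compute_features()] (needs
#'   `track_id`, `time_h`, `x_um`, `y_um`).
#' @param periods list of `c(t_a, t_b)` in hours; default the two 10-hour
#'   halves of a 20-hour recording.
#' @param min_steps see [period_mean_speed()].
#' @return `data.frame` with `track_id`, `period`, `mean_speed_um_h`,
#'   `path_length_um`, `euclid_um`, `meandering_pct`, `n_steps`.
#' @export
track_dynamics <- function(features,
                           periods = list(c(0, 10), c(10, 20)),
                           min_steps = 12) {
  per_names <- vapply(periods, function(p) sprintf("%05.2f-%05.2f", p[1], p[2]), "")
  out <- list()
  for (id in unique(features$track_id)) {
    d <- features[features$track_id == id, ]
    d <- d[order(d$time_h), ]
    if (nrow(d) < 2) next
    sp <- step_speeds(d$time_h, d$x_um, d$y_um)
    t_end <- d$time_h[-1]
    mk <- function(sel, label) {
      if (!any(sel)) return(NULL)
      # step k joins points k and k+1; periods select contiguous step runs
      pts <- seq(min(which(sel)), max(which(sel)) + 1)
      pe <- path_and_euclid(d$time_h[pts], d$x_um[pts], d$y_um[pts])
      data.frame(track_id = id, period = label,
                 mean_speed_um_h = if (sum(sel) >= min_steps) mean(sp[sel]) else NA_real_,
                 path_length_um = pe[["path_um"]],
                 euclid_um = pe[["euclid_um"]],
                 meandering_pct = if (pe[["path_um"]] > 0) 100 * pe[["euclid_um"]] / pe[["path_um"]] else 0,
                 n_steps = sum(sel))
    }
    for (k in seq_along(periods)) {
      sel <- t_end > periods[[k]][1] + 1e-9 & t_end <= periods[[k]][2] + 1e-9
      out[[length(out) + 1]] <- mk(sel, per_names[k])
    }
    out[[length(out) + 1]] <- mk(rep(TRUE, length(sp)), "full")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median-smooth WCG paths
#'
#' Replaces each track's WCG coordinates by a running median (default
#' 3-frame window). Tracking jitter inflates step speeds at fine sampling;
#' smoothing is therefore available but off by default everywhere in the
#' pipeline — raw 5-minute steps are the conventional report.
#'
#' @param features feature table with `track_id`, `time_h`, `x_um`, `y_um`.
#' @param window odd window size in frames.
#' @return The feature table with smoothed `x_um`, `y_um`.
#' @export
smooth_wcg <- function(features, window = 3) {
  stopifnot(window %% 2 == 1, window >= 1)
  if (window == 1) return(features)
  out <- lapply(split(features, features$track_id), function(d) {
    d <- d[order(d$time_h), ]
    if (nrow(d) > window) {
      d$x_um <- stats::runmed(d$x_um, window, endrule = "keep")
      d$y_um <- stats::runmed(d$y_um, window, endrule = "keep")
    }
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shift trajectories to a common origin (migration rose)
#'
#' Translates every track so its first WCG sits at `(0, 0)`, the standard
#' rose-plot representation of random 2-D migration.
#'
#' @param features feature table with `track_id`, `time_h`, `x_um`, `y_um`.
#' @return `data.frame` `track_id`, `t_h`, `dx_um`, `dy_um`.
#' @export
migration_rose <- function(features) {
  stopifnot(nrow(features) >= 1)
  out <- lapply(split(features, features$track_id), function(d) {
    d <- d[order(d$time_h), ]
    data.frame(track_id = d$track_id[1], t_h = d$time_h,
               dx_um = d$x_um - d$x_um[1], dy_um = d$y_um - d$y_um[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
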