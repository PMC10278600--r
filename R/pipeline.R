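#' Run the full screening pipeline on a batch of movies
#'
#' Orchestrates the whole assessment: for every configured movie —
#' simulated ([simulate_movie()]) or read from a phase TIFF
#' ([read_phase_movie()]) — runs segmentation, tracking, morphometry and
#' dynamics; then, per batch, compares every treated condition against the
#' control acquired in the same batch (per-period variance-gated t-tests on
#' per-cell mean speeds), computes invasive fractions at the evaluation
#' times, runs control QC and the per-period morphology summaries.
#' Treated conditions are never compared across batches; a batch without a
#' control is an error.
#'
#' @param config a list or path to a YAML file with entries:
#'   \describe{
#'     \item{seed}{integer; drives every stochastic step.}
#'     \item{movies}{list of `(condition, batch, is_control, path | sim)`;
#'       `sim` holds [sim_config()] overrides.}
#'     \item{acquisition}{`pixel_size_um`, `frame_interval_min`,
#'       `wavelength_um`, `alpha_um3_per_pg` (used for movies read from
#'       disk).}
#'     \item{analysis}{`periods` (list of 2-vectors, h), `min_area_um2`,
#'       `max_link_um`, `max_gap`, `min_steps`, `eval_times_h`.}
#'   }
#' @param out_dir if non-`NULL`, CSV/JSON outputs are written there.
#' @param quiet suppress progress messages.
#' @return List of class `pamp_run`: `dynamics`, `features`,
#'   `comparisons`, `invasive`, `qc`, `summaries`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  stopifnot(!is.null(cfg$movies), length(cfg$movies) >= 1)
  seed <- as.integer(cfg$seed %||% 1L)
  acq <- cfg$acquisition %||% list()
  ana <- list(periods = list(c(0, 10), c(10, 20)),
              min_area_um2 = 50, max_link_um = 15, max_gap = 2,
              min_steps = 12, eval_times_h = c(10, 20))
  for (nm in names(cfg$analysis)) ana[[nm]] <- cfg$analysis[[nm]]
  ana$periods <- lapply(ana$periods, as.numeric)

  conds <- vapply(cfg$movies, function(m) m$condition, "")
  if (anyDuplicated(conds)) stop("run_pipeline: duplicate condition names")
  batches <- vapply(cfg$movies, function(m) as.integer(m$batch %||% 1L), 1L)
  is_ctrl <- vapply(cfg$movies, function(m) isTRUE(m$is_control), TRUE)
  for (b in unique(batches)) {
    if (sum(is_ctrl[batches == b]) != 1) {
      stop("run_pipeline: batch ", b, " needs exactly one control; treated ",
           "conditions are only compared against the control of their own batch")
    }
  }

  features <- list(); dynamics <- list(); invasive <- list(); summaries <- list()
  for (i in seq_along(cfg$movies)) {
    mv_cfg <- cfg$movies[[i]]
    if (!quiet) message("processing condition ", conds[i])
    if (!is.null(mv_cfg$path)) {
      movie <- read_phase_movie(mv_cfg$path,
                                pixel_size = acq$pixel_size_um %||% 0.65,
                                frame_interval = acq$frame_interval_min %||% 5,
                                wavelength = acq$wavelength_um %||% 0.66,
                                alpha = acq$alpha_um3_per_pg %||% 0.18)
    } else {
      sim_args <- mv_cfg$sim %||% list()
      sim_args$seed <- as.integer((seed * 131L + i) %% 2147483647L)
      movie <- simulate_movie(do.call(sim_config, sim_args))
    }
    seg <- segment_movie(movie, min_area = ana$min_area_um2, quiet = quiet)
    trk <- link_tracks(seg, max_link_distance = ana$max_link_um,
                       max_gap = ana$max_gap)
    feats <- compute_features(movie, trk)
    features[[conds[i]]] <- feats
    dynamics[[conds[i]]] <- cbind(condition = conds[i],
                                  track_dynamics(feats, periods = ana$periods,
                                                 min_steps = ana$min_steps))
    invasive[[conds[i]]] <- do.call(rbind, lapply(ana$eval_times_h, function(et) {
      iv <- invasive_fraction(feats, et)
      data.frame(condition = conds[i], eval_time_h = et,
                 invasive_pct = iv$fraction_pct,
                 n_invasive = iv$n_invasive, n_eligible = iv$n_eligible)
    }))
    summaries[[conds[i]]] <- period_summaries(feats, periods = ana$periods)
    rm(movie, seg, trk); gc(FALSE)
  }

  per_names <- vapply(ana$periods, function(p) sprintf("%05.2f-%05.2f", p[1], p[2]), "")
  comparisons <- list()
  qc <- list()
  for (b in unique(batches)) {
    ctrl <- conds[batches == b & is_ctrl]
    qc[[ctrl]] <- qc_control(features[[ctrl]], periods = ana$periods)
    for (trt in conds[batches == b & !is_ctrl]) {
      for (pn in per_names) {
        dt <- dynamics[[trt]]; dc <- dynamics[[ctrl]]
        comparisons[[length(comparisons) + 1]] <-
          compare_speeds(dt$mean_speed_um_h[dt$period == pn],
                         dc$mean_speed_um_h[dc$period == pn],
                         condition = trt, period = pn)
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL
  invasive <- do.call(rbind, invasive)
  rownames(invasive) <- NULL
  dynamics <- do.call(rbind, dynamics)
  rownames(dynamics) <- NULL

  res <- structure(list(dynamics = dynamics, features = features,
                        comparisons = comparisons, invasive = invasive,
                        qc = qc, summaries = summaries,
                        config = list(seed = seed, analysis = ana,
                                      conditions = conds, batches = batches,
                                      is_control = is_ctrl,
                                      speed_statistic = "per-cell period mean speeds")),
                   class = "pamp_run")
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

#' @export
print.pamp_run <- function(x, ...) {
  cat("pamp_run:", length(x$features), "conditions\n")
  if (!is.null(x$comparisons)) {
    cat("speed comparisons vs batch control:\n")
    print(x$comparisons[, c("condition", "period", "mean_treated",
                            "mean_control", "speed_change_pct", "variant",
                            "t_p", "stars")], digits = 3)
  }
  invisible(x)
}

#' Write the CSV/JSON outputs of a pipeline run
#'
#' Emits per-condition feature and track-summary CSVs, the speed-comparison
#' table, invasive fractions, density snapshots, and one QC JSON per
#' control. Same input, same files: all output is deterministic.
#'
#' @param run a `pamp_run`.
#' @param out_dir output directory (created if missing).
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(run$features)) {
    write.csv(run$features[[cond]],
              file.path(out_dir, paste0("features_", cond, ".csv")),
              row.names = FALSE)
  }
  write.csv(run$dynamics, file.path(out_dir, "track_summary.csv"),
            row.names = FALSE)
  if (!is.null(run$comparisons)) {
    write.csv(run$comparisons, file.path(out_dir, "speed_comparison.csv"),
              row.names = FALSE)
  }
  write.csv(run$invasive, file.path(out_dir, "invasive_fractions.csv"),
            row.names = FALSE)
  snaps <- do.call(rbind, lapply(names(run$summaries), function(cond) {
    cbind(condition = cond, run$summaries[[cond]]$snapshots)
  }))
  write.csv(snaps, file.path(out_dir, "density_snapshots.csv"),
            row.names = FALSE)
  chg <- do.call(rbind, lapply(names(run$summaries), function(cond) {
    cbind(condition = cond, run$summaries[[cond]]$changes)
  }))
  write.csv(chg, file.path(out_dir, "density_changes.csv"), row.names = FALSE)
  for (cond in names(run$qc)) {
    jsonlite::write_json(unclass(run$qc[[cond]]),
                         file.path(out_dir, paste0("qc_", cond, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
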