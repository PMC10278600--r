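#' Migration rose plot
#'
#' Individual trajectories shifted to a common origin, axes in um.
#'
#' @param features feature table (or a `pamp_run` condition's features).
#' @return A ggplot object.
#' @export
plot_migration_rose <- function(features) {
  .need_ggplot2()
  rose <- migration_rose(features)
  ggplot2::ggplot(rose, ggplot2::aes(x = dx_um, y = dy_um,
                                     group = track_id)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [um]", y = "y [um]", title = "Migration rose") +
    ggplot2::theme_minimal()
}

#' Per-period boxplots of circularity or density
#'
#' @param run a `pamp_run`.
#' @param what `"circularity_pct"` or `"density_pg_per_um2"`.
#' @return A ggplot object.
#' @export
plot_period_boxplots <- function(run, what = c("circularity_pct", "density_pg_per_um2")) {
  .need_ggplot2()
  what <- match.arg(what)
  dat <- do.call(rbind, lapply(names(run$summaries), function(cond) {
    cbind(condition = cond, run$summaries[[cond]]$pooled)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = condition, y = !!ggplot2::sym(what),
                                    fill = condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~period) +
    ggplot2::labs(y = what) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Displacement / directionality quadrant plot
#'
#' Euclidean displacement (x) against meandering index (y) per track, with
#' the invasive-phenotype thresholds drawn; invasive cells sit in the upper
#' right quadrant.
#'
#' @param features feature table.
#' @param eval_time evaluation time, h.
#' @param dist_threshold,mi_threshold quadrant thresholds (um, %).
#' @return A ggplot object.
#' @export
plot_invasive_quadrant <- function(features, eval_time = 20,
                                   dist_threshold = 100, mi_threshold = 25) {
  .need_ggplot2()
  iv <- invasive_fraction(features, eval_time, dist_threshold, mi_threshold)
  ggplot2::ggplot(iv$calls, ggplot2::aes(x = euclid_um,
                                         y = meandering_pct,
                                         colour = invasive)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = dist_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = mi_threshold, linetype = 2) +
    ggplot2::labs(x = "Euclidean distance [um]", y = "Meandering index [%]") +
    ggplot2::theme_minimal()
}

.need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}
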