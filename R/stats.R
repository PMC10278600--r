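#' Two-sample F-test for equality of variances
#'
#' `F = s_a^2 / s_b^2` with `(n_a - 1, n_b - 1)` degrees of freedom; the
#' two-tailed p-value is `2 * min(P(F' <= F), P(F' >= F))`, capped at 1.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return List `F`, `df1`, `df2`, `p`.
#' @export
f_test_variance <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- var(a); vb <- var(b)
  if (va == 0 || vb == 0) stop("f_test_variance: zero sample variance")
  F <- va / vb
  df1 <- length(a) - 1L; df2 <- length(b) - 1L
  p <- min(1, 2 * min(pf(F, df1, df2), pf(F, df1, df2, lower.tail = FALSE)))
  list(F = F, df1 = df1, df2 = df2, p = p)
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' `n.s.`.
#'
#' @param p p-value(s).
#' @return Character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' Variance-gated two-sample t-test
#'
#' Runs the two-sample F-test for variance first; if its two-tailed p-value
#' is below `gate_alpha` (0.05) the unequal-variance t-test with
#' Welch-Satterthwaite degrees of freedom is used, otherwise the
#' pooled-variance t-test. Returns the two-tailed p-value with significance
#' stars. When the two sample variances are exactly equal the gate always
#' selects the pooled test and both variants coincide.
#'
#' @param a,b numeric samples.
#' @param gate_alpha F-test significance level deciding the variant.
#' @return List `variant` ("pooled" or "welch"), `t`, `df`, `p`, `stars`,
#'   and the gating `f_test`.
#' @export
gated_t_test <- function(a, b, gate_alpha = 0.05) {
  ft <- f_test_variance(a, b)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (ft$p < gate_alpha) {
    variant <- "welch"
    se2 <- va / na + vb / nb
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    variant <- "pooled"
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(variant = variant, t = tstat, df = df, p = p, stars = p_stars(p),
       f_test = ft)
}

#' Percent speed change of a treated condition versus its control
#'
#' `100 * (mean_treated - mean_control) / mean_control`; negative values
#' mean the treatment slowed migration down (reported with a down arrow in
#' summary tables).
#'
#' @param mean_treated,mean_control period mean speeds, um/h
#'   (`mean_control > 0`).
#' @return Signed percentage.
#' @export
#' @examples
#' speed_change_pct(33.2, 24.4)  # +36.1
#' speed_change_pct(24.6, 34.9)  # -29.5
speed_change_pct <- function(mean_treated, mean_control) {
  if (any(mean_control <= 0)) stop("speed_change_pct: control mean must be positive")
  100 * (mean_treated - mean_control) / mean_control
}

#' Empirical type-I error of the variance-gated t-test
#'
#' Draws both groups from the same Gaussian `n_reps` times, applies
#' [gated_t_test()] and returns the fraction of rejections at `alpha`. The
#' arithmetic is vectorised over replicates so large `n_reps` stays cheap.
#'
#' @param n_per_group group size.
#' @param n_reps number of simulated experiments (>= 1000).
#' @param seed RNG seed.
#' @param alpha nominal level.
#' @return Rejection rate.
#' @export
typeI_error_simulation <- function(n_per_group = 30, n_reps = 5000,
                                   seed = 1, alpha = 0.05) {
  stopifnot(n_reps >= 1000)
  set.seed(seed)
  n <- n_per_group
  A <- matrix(rnorm(n * n_reps), n, n_reps)
  B <- matrix(rnorm(n * n_reps), n, n_reps)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums((A - matrix(ma, n, n_reps, byrow = TRUE))^2) / (n - 1)
  vb <- colSums((B - matrix(mb, n, n_reps, byrow = TRUE))^2) / (n - 1)
  fp <- pmin(1, 2 * pmin(pf(va / vb, n - 1, n - 1),
                         pf(va / vb, n - 1, n - 1, lower.tail = FALSE)))
  welch <- fp < 0.05
  se2 <- va / n + vb / n
  t_w <- (ma - mb) / sqrt(se2)
  df_w <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
  sp2 <- (va + vb) / 2
  t_p <- (ma - mb) / sqrt(sp2 * 2 / n)
  df_p <- 2 * n - 2
  p <- ifelse(welch,
              2 * pt(abs(t_w), df_w, lower.tail = FALSE),
              2 * pt(abs(t_p), df_p, lower.tail = FALSE))
  mean(p < alpha)
}

#' Compare treated and control per-cell mean speeds in one period
#'
#' Builds one comparison row: group sizes, mean +/- sd and median speeds,
#' percent change versus control, the gating F-test, the selected t-test
#' variant, the two-tailed p-value and its stars.
#'
#' @param speeds_treated,speeds_control per-cell period mean speeds, um/h
#'   (NAs dropped).
#' @param condition,period labels carried into the output row.
#' @return One-row `data.frame`.
#' @export
compare_speeds <- function(speeds_treated, speeds_control,
                           condition = "treated", period = "") {
  a <- speeds_treated[!is.na(speeds_treated)]
  b <- speeds_control[!is.na(speeds_control)]
  gt <- gated_t_test(a, b)
  data.frame(condition = condition, period = period,
             n_treated = length(a), n_control = length(b),
             mean_treated = mean(a), sd_treated = sd(a),
             median_treated = median(a),
             mean_control = mean(b), sd_control = sd(b),
             median_control = median(b),
             speed_change_pct = speed_change_pct(mean(a), mean(b)),
             F = gt$f_test$F, f_p = gt$f_test$p,
             variant = gt$variant, t = gt$t, t_p = gt$p, stars = gt$stars)
}
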