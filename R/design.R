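#' Configuration of a randomized biomarker-guided design
#'
#' Defines one of the three randomized design topologies together with its
#' monitoring thresholds:
#'
#' * `"pooled"`: patients are randomized 3:1 to experimental treatment or
#'   control; biomarker testing is done only on treated patients, so a
#'   single biomarker-unselected control arm (maximum `n_arm`) is shared by
#'   the three biomarker-specific treatment arms (`n_arm` each); maximum
#'   total `4 * n_arm` (200 in the case study).
#' * `"stratified"`: all patients are biomarker tested and randomized 1:1
#'   within subgroup, giving each subgroup its own control arm; maximum
#'   total `6 * n_arm` (300).
#' * `"enrichment"`: stage 1 is the pooled design; at its end the subgroup
#'   with the highest posterior predictive probability advances to stage 2
#'   (subject to a lower bound calibrated under the null and to not having
#'   stopped for futility), where `stage2_n` additional patients of that
#'   subgroup are randomized 1:1 and the stage-1 treatment data are carried
#'   forward; maximum total `4 * n_arm + stage2_n` (300).
#'
#' Interim futility looks occur after every `look_interval` patients per
#' arm of a comparison; enrollment in a comparison stops when the
#' two-sample predictive probability falls below `theta_star`, and a
#' completed comparison is positive when the posterior probability that the
#' treatment rate exceeds the control rate is above `theta`.
#'
#' @param design One of `"pooled"`, `"stratified"`, `"enrichment"`.
#' @param theta Posterior (efficacy) threshold in (0, 1).
#' @param theta_star Predictive (futility) threshold in (0, 1).
#' @param n_arm Maximum patients per arm and subgroup (50 in the case study).
#' @param look_interval Patients per arm between futility looks.
#' @param prior Shared [beta_prior()] for all arms.
#' @param stage2_n Total stage-2 enrollment of the enrichment design,
#'   randomized 1:1.
#' @param stage1_bound_quantile Quantile of the null distribution of the
#'   maximum stage-1 PPP used as the enrichment advancement bound.
#' @param n_sim Number of simulated replicates used by [simulate_design()]
#'   and [estimate_oc()].
#'
#' @return A `design_config` object.
#' @examples
#' design_config("pooled", theta = 0.9, theta_star = 0.1)
#' @export
design_config <- function(design = c("pooled", "stratified", "enrichment"),
                          theta, theta_star,
                          n_arm = 50, look_interval = 10,
                          prior = beta_prior(),
                          stage2_n = 100,
                          stage1_bound_quantile = 0.8,
                          n_sim = 1000) {
  design <- match.arg(design)
  stopifnot(theta > 0, theta < 1, theta_star > 0, theta_star < 1,
            n_arm >= 1, n_arm == round(n_arm),
            look_interval >= 1, look_interval == round(look_interval),
            look_interval <= n_arm,
            stage2_n >= 2, stage2_n %% 2 == 0,
            stage1_bound_quantile > 0, stage1_bound_quantile < 1,
            n_sim >= 1)
  structure(list(design = design, theta = theta, theta_star = theta_star,
                 n_arm = n_arm, look_interval = look_interval,
                 prior = as_beta_prior(prior), stage2_n = stage2_n,
                 stage1_bound_quantile = stage1_bound_quantile,
                 n_sim = n_sim),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  maxn <- switch(x$design,
                 pooled = 4 * x$n_arm,
                 stratified = 6 * x$n_arm,
                 enrichment = 4 * x$n_arm + x$stage2_n)
  cat(sprintf("%s (max %d patients)\n",
              switch(x$design,
                     pooled = "Pooled control arm design",
                     stratified = "Stratified control arm design",
                     enrichment = "Two-stage enrichment design"), maxn))
  cat(sprintf("  theta = %g, theta* = %g, looks every %d patients/arm\n",
              x$theta, x$theta_star, x$look_interval))
  print(x$prior)
  invisible(x)
}

# interim look schedule (per-arm n); the evaluation at n_arm is the final
# analysis, not a futility look
design_looks <- function(config, N = config$n_arm) {
  lk <- seq(config$look_interval, N, by = config$look_interval)
  lk[lk < N]
}

#' Grid of candidate monitoring thresholds
#'
#' The default grid is the 14 posterior x 4 predictive threshold
#' combinations over which operating characteristics are estimated before
#' selecting an optimal-efficiency design.
#'
#' @param theta Posterior thresholds.
#' @param theta_star Predictive thresholds.
#' @return A tibble with one row per `(theta, theta_star)` combination.
#' @export
threshold_grid <- function(theta = c(0.7, 0.74, 0.78, 0.82, 0.86, 0.9, 0.92,
                                     0.93, 0.94, 0.95, 0.96, 0.97, 0.98, 0.99),
                           theta_star = c(0.05, 0.1, 0.15, 0.2)) {
  stopifnot(all(theta > 0 & theta < 1), all(theta_star > 0 & theta_star < 1))
  th <- rep(theta, each = length(theta_star))
  ts <- rep(theta_star, times = length(theta))
  tibble::tibble(theta = th, theta_star = ts)
}
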