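# Trial simulation engine.
#
# Accrual follows the simulation protocol of the design: responses arrive
# in blocks of `look_interval` patients per arm, drawn from a binomial with
# the scenario's true rate, and every comparison is examined after each
# block (per-arm n = 10, 20, 30, 40 in the case study; the evaluation at
# the maximum is the final analysis).  The predictive probability of each
# open subgroup-vs-control comparison is computed at every look and the
# comparison stops for futility when it falls below theta_star.  In the
# pooled topology the shared control arm stops enrolling once all three
# subgroups have stopped.

.derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# cumulative response counts at the end of each accrual block:
# matrix n_sim x length(blocks)
.cum_counts <- function(n_sim, blocks, p) {
  nb <- length(blocks)
  x <- matrix(rbinom(n_sim * nb, rep(blocks, each = n_sim), p), n_sim, nb)
  if (nb > 1) x <- t(apply(x, 1, cumsum))
  x
}

# simulated response streams for one pooled-design (or enrichment stage-1)
# run: cumulative counts per treatment subgroup and for the shared control
.gen_pooled_paths <- function(n_sim, scenario, config, seed) {
  N <- config$n_arm
  blocks <- diff(c(0, design_looks(config), N))
  set.seed(seed)
  xc <- .cum_counts(n_sim, blocks, scenario$p_ctrl)
  xt <- lapply(scenario$p_trt, function(p) .cum_counts(n_sim, blocks, p))
  list(xt = xt, xc = xc, n_sim = n_sim)
}

# stratified design: an independent control stream per subgroup
.gen_stratified_paths <- function(n_sim, scenario, config, seed) {
  N <- config$n_arm
  blocks <- diff(c(0, design_looks(config), N))
  set.seed(seed)
  streams <- lapply(scenario$p_trt, function(p) {
    list(xt = .cum_counts(n_sim, blocks, p),
         xc = .cum_counts(n_sim, blocks, scenario$p_ctrl))
  })
  list(streams = streams, n_sim = n_sim)
}

# patient-level stage-2 uniforms, drawn for every replicate so that the
# same randomness is reused across threshold combinations (the subgroup
# selected in stage 1 determines which response rate they are compared to)
.gen_stage2_uniforms <- function(n_sim, config, seed) {
  half <- config$stage2_n / 2
  set.seed(seed)
  list(trt = matrix(runif(n_sim * half), n_sim, half),
       ctrl = matrix(runif(n_sim * half), n_sim, half))
}

# evaluate one two-arm comparison stream at thresholds (theta, theta_star):
# xt, xc are cumulative count matrices with one column per block (the last
# column is the final analysis).  Returns stop look (0 = none), positivity,
# per-arm enrollment, last computed PPP and final-state bookkeeping.
.eval_comparison <- function(xt, xc, config, theta, theta_star) {
  N <- config$n_arm
  looks <- design_looks(config)
  nlook <- length(looks)
  nb <- nlook + 1
  n_sim <- nrow(xt)
  prior <- config$prior
  M <- .pe_matrix(N, N, prior)
  traj <- matrix(NA_real_, n_sim, nlook)
  for (k in seq_len(nlook)) {
    P <- .ppp_state_matrix(looks[k], N, looks[k], N, prior, theta)
    traj[, k] <- P[cbind(xt[, k] + 1, xc[, k] + 1)]
  }
  stopm <- traj < theta_star
  stop_look <- integer(n_sim)
  open <- rep(TRUE, n_sim)
  for (k in seq_len(nlook)) {
    hit <- open & stopm[, k]
    stop_look[hit] <- k
    open <- open & !hit
  }
  pe_fin <- M[cbind(xt[, nb] + 1, xc[, nb] + 1)]
  final_pos <- pe_fin > theta
  positive <- stop_look == 0L & final_pos
  n_arm_used <- ifelse(stop_look > 0, looks[pmax(stop_look, 1L)], N)
  last_look <- ifelse(stop_look > 0, stop_look, nb)
  last_ppp <- ifelse(stop_look > 0,
                     traj[cbind(seq_len(n_sim), pmax(stop_look, 1L))],
                     as.numeric(final_pos))
  list(stop_look = stop_look, positive = positive, n = n_arm_used,
       last_ppp = last_ppp, pe_fin = pe_fin, final_pos = final_pos,
       x_last = xt[cbind(seq_len(n_sim), last_look)],
       xc_last = xc[cbind(seq_len(n_sim), last_look)],
       x_fin = xt[, nb])
}

.col_bind <- function(lst, field)
  matrix(unlist(lapply(lst, `[[`, field)), ncol = length(lst))

.eval_pooled <- function(paths, config, theta, theta_star) {
  cmp <- lapply(paths$xt, function(x)
    .eval_comparison(x, paths$xc, config, theta, theta_star))
  n_s <- .col_bind(cmp, "n")
  n_ctrl <- apply(n_s, 1, max)   # control enrolls while any subgroup is open
  list(cmp = cmp, n_s = n_s, n_ctrl = n_ctrl,
       n_trt_total = rowSums(n_s),
       n_total = rowSums(n_s) + n_ctrl)
}

.eval_stratified <- function(paths, config, theta, theta_star) {
  cmp <- lapply(paths$streams, function(s)
    .eval_comparison(s$xt, s$xc, config, theta, theta_star))
  n_s <- .col_bind(cmp, "n")      # both arms of a subgroup stop together
  list(cmp = cmp, n_s = n_s, n_ctrl = rowSums(n_s),
       n_trt_total = rowSums(n_s),
       n_total = 2 * rowSums(n_s))
}

# enrichment stage-1 selection: the subgroup with maximal last-computed PPP
# (ties broken by the final posterior probability) advances iff it did not
# stop for futility and its PPP exceeds the calibrated lower bound
.stage1_selection <- function(ev, bound) {
  n_sim <- length(ev$cmp[[1]]$positive)
  last_ppp <- .col_bind(ev$cmp, "last_ppp")
  pe_fin <- .col_bind(ev$cmp, "pe_fin")
  stopped <- .col_bind(ev$cmp, "stop_look") > 0
  sel <- max.col(last_ppp + 1e-9 * pe_fin, ties.method = "first")
  idx <- cbind(seq_len(n_sim), sel)
  advance <- !stopped[idx] & last_ppp[idx] > bound
  list(sel = sel, advance = advance, max_ppp = last_ppp[idx])
}

.eval_stage2 <- function(paths, u2, s1ev, s1sel, config, theta, theta_star,
                         scenario) {
  n_sim <- paths$n_sim
  N1 <- config$n_arm
  half <- config$stage2_n / 2
  prior <- config$prior
  N2t <- N1 + half
  N2c <- half
  iv <- config$look_interval
  looks2 <- seq(iv, half, by = iv)
  looks2 <- looks2[looks2 < half]
  Ind2 <- .pe_matrix(N2t, N2c, prior) > theta
  PP2 <- lapply(looks2, function(l)
    .ppp_state_matrix(N1 + l, N2t, l, N2c, prior, theta))
  n2t <- n2c <- numeric(n_sim)
  pos2 <- s2stopped <- logical(n_sim)
  for (i in which(s1sel$advance)) {
    s <- s1sel$sel[i]
    p_t <- scenario$p_trt[[s]]
    xt2 <- cumsum(vapply(seq_len(half / iv), function(b)
      sum(u2$trt[i, ((b - 1) * iv + 1):(b * iv)] < p_t), numeric(1)))
    xc2 <- cumsum(vapply(seq_len(half / iv), function(b)
      sum(u2$ctrl[i, ((b - 1) * iv + 1):(b * iv)] < scenario$p_ctrl), numeric(1)))
    x0 <- s1ev$cmp[[s]]$x_fin[i]
    stopj <- 0L
    for (j in seq_along(looks2)) {
      if (PP2[[j]][x0 + xt2[j] + 1, xc2[j] + 1] < theta_star) {
        stopj <- j
        break
      }
    }
    if (stopj > 0L) {
      n2t[i] <- n2c[i] <- looks2[stopj]
      s2stopped[i] <- TRUE
    } else {
      n2t[i] <- n2c[i] <- half
      pos2[i] <- Ind2[x0 + xt2[length(xt2)] + 1, xc2[length(xc2)] + 1]
    }
  }
  list(n2t = n2t, n2c = n2c, positive = pos2, stopped = s2stopped)
}

#' Calibrate the enrichment design's stage-1 advancement bound
#'
#' Simulates `config$n_sim` stage-1 (pooled-design) trials under the global
#' null and returns the `stage1_bound_quantile` quantile of the
#' per-replicate maximum, across subgroups, of the last computed posterior
#' predictive probability (the value at the stopping look for subgroups
#' stopped early, the end-of-trial value otherwise).  A subgroup advances
#' to stage 2 only if it holds the maximum PPP, exceeds this bound, and did
#' not stop for futility.
#'
#' @param config An enrichment [design_config()].
#' @param null_scenario The global-null [trial_scenario()].
#' @param seed Integer seed for the calibration replicates.
#' @return The lower bound (scalar in `[0, 1]`).
#' @export
calibrate_stage1_bound <- function(config, null_scenario = scenario_null(),
                                   seed = 1) {
  stopifnot(inherits(config, "design_config"), config$design == "enrichment")
  paths <- .gen_pooled_paths(config$n_sim, null_scenario, config,
                             .derive_seeds(seed, 1))
  ev <- .eval_pooled(paths, config, config$theta, config$theta_star)
  maxppp <- do.call(pmax, lapply(ev$cmp, `[[`, "last_ppp"))
  as.numeric(quantile(maxppp, config$stage1_bound_quantile))
}

#' Simulate a randomized biomarker-guided trial design
#'
#' Simulates `config$n_sim` complete trials of the configured design under
#' a true response-rate scenario, with interim futility monitoring and, for
#' the enrichment design, stage-1 subgroup selection and stage-2 enrollment.
#'
#' @param config A [design_config()].
#' @param scenario A [trial_scenario()] generating the data.
#' @param seed Master integer seed; every random stream (arm responses,
#'   stage-2 patients, bound calibration) is derived from it, so identical
#'   inputs reproduce identical results.
#' @param stage1_bound Advancement bound for the enrichment design; when
#'   `NULL` it is calibrated internally with [calibrate_stage1_bound()]
#'   under `null_scenario`.
#' @param null_scenario Scenario used for internal bound calibration.
#'
#' @return An object of class `ppd_sim`: a list with `subgroups` (a tibble
#'   with one row per replicate and subgroup: decision, stopping look,
#'   enrollment and response counts, last predictive probability),
#'   `trials` (one row per replicate: totals of patients enrolled, treated
#'   with the experimental agent, biomarker tested, and for the enrichment
#'   design the selected subgroup and stage reached), and the inputs.
#'
#' @examples
#' cfg <- design_config("pooled", theta = 0.9, theta_star = 0.1, n_sim = 20)
#' sim <- simulate_design(cfg, scenario_alternative(), seed = 7)
#' head(sim$subgroups)
#' @export
simulate_design <- function(config, scenario, seed = 1, stage1_bound = NULL,
                            null_scenario = scenario_null()) {
  stopifnot(inherits(config, "design_config"),
            inherits(scenario, "trial_scenario"))
  seeds <- .derive_seeds(seed, 3)
  n_sim <- config$n_sim
  subg <- names(scenario$p_trt)

  if (config$design == "pooled") {
    paths <- .gen_pooled_paths(n_sim, scenario, config, seeds[1])
    ev <- .eval_pooled(paths, config, config$theta, config$theta_star)
    out <- .assemble_sim(config, scenario, seed, ev, subg,
                         n_ctrl_trial = ev$n_ctrl,
                         n_tested = ev$n_trt_total)
  } else if (config$design == "stratified") {
    paths <- .gen_stratified_paths(n_sim, scenario, config, seeds[1])
    ev <- .eval_stratified(paths, config, config$theta, config$theta_star)
    out <- .assemble_sim(config, scenario, seed, ev, subg,
                         n_ctrl_trial = ev$n_ctrl,
                         n_tested = ev$n_total)
  } else {
    if (is.null(stage1_bound))
      stage1_bound <- calibrate_stage1_bound(config, null_scenario,
                                             seed = seeds[3])
    stopifnot(stage1_bound >= 0, stage1_bound <= 1)
    paths <- .gen_pooled_paths(n_sim, scenario, config, seeds[1])
    u2 <- .gen_stage2_uniforms(n_sim, config, seeds[2])
    ev <- .eval_pooled(paths, config, config$theta, config$theta_star)
    s1sel <- .stage1_selection(ev, stage1_bound)
    s2 <- .eval_stage2(paths, u2, ev, s1sel, config, config$theta,
                       config$theta_star, scenario)
    out <- .assemble_sim(config, scenario, seed, ev, subg,
                         n_ctrl_trial = ev$n_ctrl + s2$n2c,
                         n_tested = ev$n_trt_total +
                           .stage2_screened(s2, s1sel, scenario),
                         s1sel = s1sel, s2 = s2, stage1_bound = stage1_bound)
  }
  out
}

# analytic screening count for stage 2: enrolling n patients of a subgroup
# with prevalence w requires screening n / w patients on average
.stage2_screened <- function(s2, s1sel, scenario) {
  n2 <- s2$n2t + s2$n2c
  w <- scenario$prevalence[s1sel$sel]
  ifelse(n2 > 0, n2 / w, 0)
}

.assemble_sim <- function(config, scenario, seed, ev, subg, n_ctrl_trial,
                          n_tested, s1sel = NULL, s2 = NULL,
                          stage1_bound = NULL) {
  n_sim <- length(ev$n_ctrl)
  rows <- lapply(seq_along(subg), function(s) {
    c <- ev$cmp[[s]]
    tibble::tibble(
      replicate = seq_len(n_sim),
      subgroup = subg[s],
      decision = ifelse(c$stop_look > 0, "stopped_futility",
                        ifelse(c$positive, "positive", "negative")),
      stop_look = ifelse(c$stop_look > 0, c$stop_look, NA_integer_),
      n_trt = c$n, x_trt = c$x_last,
      n_ctrl = ifelse(c$stop_look > 0, c$n, config$n_arm),
      x_ctrl = c$xc_last,
      last_ppp = c$last_ppp
    )
  })
  subgroups <- dplyr::arrange(dplyr::bind_rows(rows), .data$replicate)

  trt_tot <- ev$n_trt_total
  if (!is.null(s2)) trt_tot <- trt_tot + s2$n2t
  trials <- tibble::tibble(
    replicate = seq_len(n_sim),
    n_ctrl = n_ctrl_trial,
    n_trt = trt_tot,
    n_total = n_ctrl_trial + trt_tot,
    n_tested = n_tested,
    n_positive = rowSums(.col_bind(ev$cmp, "positive"))
  )
  if (!is.null(s1sel)) {
    trials$advanced <- s1sel$advance
    trials$selected_subgroup <- ifelse(s1sel$advance, subg[s1sel$sel],
                                       NA_character_)
    trials$stage_reached <- ifelse(s1sel$advance, 2L, 1L)
    trials$stage2_n_trt <- s2$n2t
    trials$stage2_n_ctrl <- s2$n2c
    trials$decision <- ifelse(!s1sel$advance, "negative",
                              ifelse(s2$stopped, "stopped_futility",
                                     ifelse(s2$positive, "positive",
                                            "negative")))
    trials$n_positive <- as.integer(s2$positive)
  }
  structure(list(subgroups = subgroups, trials = trials, config = config,
                 scenario = scenario, seed = seed,
                 stage1_bound = stage1_bound),
            class = "ppd_sim")
}

#' @export
print.ppd_sim <- function(x, ...) {
  cat(sprintf("Simulated %s design: %d replicates\n",
              x$config$design, nrow(x$trials)))
  if (x$config$design != "enrichment") {
    pos <- tapply(x$subgroups$decision == "positive", x$subgroups$subgroup,
                  mean)
    cat("  positive rate by subgroup:",
        paste(sprintf("%s=%.3f", names(pos), pos), collapse = ", "), "\n")
  } else {
    cat(sprintf("  advanced to stage 2: %.3f; positive overall: %.3f\n",
                mean(x$trials$advanced), mean(x$trials$decision == "positive")))
  }
  cat(sprintf("  average total enrolled: %.1f\n", mean(x$trials$n_total)))
  invisible(x)
}
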