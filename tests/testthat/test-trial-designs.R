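# Small-replicate simulations exercising the three design topologies.
# Case-study-scale operating characteristics are checked in
# test-acceptance.R; here the focus is structural invariants.

n_small <- 150

test_that("futility threshold extremes behave as expected in the pooled design", {
  # near-zero predictive threshold: stopping is confined to the rare
  # states where success has become (all but) impossible, so enrollment
  # runs essentially to the maximum even under the null
  cfg <- design_config("pooled", theta = 0.9, theta_star = 1e-9,
                       n_sim = n_small)
  sim <- simulate_design(cfg, scenario_null(), seed = 3)
  expect_gt(mean(sim$trials$n_total), 190)
  stopped <- sim$subgroups[!is.na(sim$subgroups$stop_look), ]
  expect_lt(nrow(stopped) / nrow(sim$subgroups), 0.1)
  expect_true(all(stopped$last_ppp < 1e-9))

  # near-one predictive threshold: essentially every subgroup stops at the
  # first look
  cfg2 <- design_config("pooled", theta = 0.9, theta_star = 0.999,
                        n_sim = n_small)
  sim2 <- simulate_design(cfg2, scenario_null(), seed = 3)
  expect_lt(mean(sim2$trials$n_total), 60)
  expect_gt(mean(sim2$subgroups$decision == "stopped_futility"), 0.95)
})

test_that("enrollment maxima and bookkeeping identities hold", {
  for (design in c("pooled", "stratified", "enrichment")) {
    cfg <- design_config(design, theta = 0.9, theta_star = 0.15,
                         n_sim = n_small)
    sim <- simulate_design(cfg, scenario_alternative(), seed = 11)
    max_total <- switch(design, pooled = 200, stratified = 300,
                        enrichment = 300)
    expect_true(all(sim$trials$n_total <= max_total))
    expect_true(all(sim$trials$n_total ==
                      sim$trials$n_trt + sim$trials$n_ctrl))
    expect_true(all(sim$subgroups$n_trt <= 50))
    if (design == "enrichment")
      expect_true(all(sim$trials$n_trt <= 200))
  }
})

test_that("stratified arms stop together so control equals treatment enrollment", {
  cfg <- design_config("stratified", theta = 0.9, theta_star = 0.2,
                       n_sim = n_small)
  sim <- simulate_design(cfg, scenario_alternative(), seed = 5)
  expect_true(all(sim$trials$n_ctrl == sim$trials$n_trt))
})

test_that("pooled control arm stops when and only when all subgroups have stopped", {
  cfg <- design_config("pooled", theta = 0.9, theta_star = 0.2,
                       n_sim = n_small)
  sim <- simulate_design(cfg, scenario_null(), seed = 9)
  per_rep <- tapply(sim$subgroups$n_trt, sim$subgroups$replicate, max)
  expect_equal(as.numeric(per_rep[as.character(sim$trials$replicate)]),
               as.numeric(sim$trials$n_ctrl))
})

test_that("biomarker testing counts follow the design topology", {
  cfg_p <- design_config("pooled", theta = 0.9, theta_star = 0.1,
                         n_sim = n_small)
  sp <- simulate_design(cfg_p, scenario_null(), seed = 21)
  expect_equal(sp$trials$n_tested, sp$trials$n_trt)  # only treated are tested
  expect_true(all(sp$trials$n_tested <= 150))

  cfg_s <- design_config("stratified", theta = 0.9, theta_star = 0.1,
                         n_sim = n_small)
  ss <- simulate_design(cfg_s, scenario_null(), seed = 21)
  expect_equal(ss$trials$n_tested, ss$trials$n_total)  # everyone is tested

  cfg_e <- design_config("enrichment", theta = 0.9, theta_star = 0.1,
                         n_sim = n_small)
  se <- simulate_design(cfg_e, scenario_alternative(), seed = 21)
  s1_trt <- se$trials$n_trt - se$trials$stage2_n_trt
  screened <- 3 * (se$trials$stage2_n_trt + se$trials$stage2_n_ctrl)
  expect_equal(se$trials$n_tested, s1_trt + screened)
  expect_true(all(se$trials$n_tested <= 450))
})

test_that("raising theta never converts a negative decision to positive", {
  for (th in list(c(0.8, 0.9), c(0.9, 0.96))) {
    cfg_lo <- design_config("pooled", theta = th[1], theta_star = 0.1,
                            n_sim = n_small)
    cfg_hi <- design_config("pooled", theta = th[2], theta_star = 0.1,
                            n_sim = n_small)
    lo <- simulate_design(cfg_lo, scenario_alternative(), seed = 13)
    hi <- simulate_design(cfg_hi, scenario_alternative(), seed = 13)
    flipped <- lo$subgroups$decision != "positive" &
      hi$subgroups$decision == "positive"
    expect_false(any(flipped))
  }
})

test_that("early stopping is monotone in the predictive threshold", {
  stops <- sapply(c(0.05, 0.1, 0.2), function(ts) {
    cfg <- design_config("pooled", theta = 0.9, theta_star = ts,
                         n_sim = n_small)
    sim <- simulate_design(cfg, scenario_null(), seed = 17)
    mean(sim$subgroups$decision == "stopped_futility")
  })
  expect_true(all(diff(stops) >= 0))
})

test_that("identical seeds reproduce identical simulations", {
  cfg <- design_config("enrichment", theta = 0.92, theta_star = 0.15,
                       n_sim = 50)
  a <- simulate_design(cfg, scenario_alternative(), seed = 77)
  b <- simulate_design(cfg, scenario_alternative(), seed = 77)
  expect_identical(a$subgroups, b$subgroups)
  expect_identical(a$trials, b$trials)
  c <- simulate_design(cfg, scenario_alternative(), seed = 78)
  expect_false(identical(a$trials, c$trials))
})

test_that("enrichment advancement respects the bound and futility status", {
  cfg <- design_config("enrichment", theta = 0.9, theta_star = 0.15,
                       n_sim = n_small)
  # unattainable bound: nothing ever advances
  sim1 <- simulate_design(cfg, scenario_alternative(), seed = 31,
                          stage1_bound = 1)
  expect_false(any(sim1$trials$advanced))
  expect_true(all(sim1$trials$stage_reached == 1))
  expect_true(all(sim1$trials$decision == "negative"))

  # permissive bound: advancement happens, and only for replicates whose
  # best subgroup did not stop for futility
  sim2 <- simulate_design(cfg, scenario_alternative(), seed = 31,
                          stage1_bound = 0)
  expect_gt(mean(sim2$trials$advanced), 0.5)
  adv <- sim2$trials$replicate[sim2$trials$advanced]
  sel <- sim2$trials$selected_subgroup[sim2$trials$advanced]
  sel_rows <- sim2$subgroups[match(paste(adv, sel),
                                   paste(sim2$subgroups$replicate,
                                         sim2$subgroups$subgroup)), ]
  expect_false(any(sel_rows$decision == "stopped_futility"))

  # everything stopping at stage 1 ends the trial
  cfg3 <- design_config("enrichment", theta = 0.9, theta_star = 0.999,
                        n_sim = 50)
  sim3 <- simulate_design(cfg3, scenario_null(), seed = 31, stage1_bound = 0.5)
  expect_true(all(!sim3$trials$advanced))
})

test_that("stage-1 bound calibration returns a reproducible quantile", {
  cfg <- design_config("enrichment", theta = 0.96, theta_star = 0.15,
                       n_sim = 200)
  b1 <- calibrate_stage1_bound(cfg, seed = 4)
  b2 <- calibrate_stage1_bound(cfg, seed = 4)
  expect_identical(b1, b2)
  expect_gte(b1, 0)
  expect_lte(b1, 1)
  # with a four-fifths quantile at least 20% of null maxima sit at or above it
  paths_max <- local({
    ev <- ppdesigns:::.eval_pooled(
      ppdesigns:::.gen_pooled_paths(200, scenario_null(), cfg,
                                    ppdesigns:::.derive_seeds(4, 1)),
      cfg, cfg$theta, cfg$theta_star)
    do.call(pmax, lapply(ev$cmp, `[[`, "last_ppp"))
  })
  expect_gte(mean(paths_max >= b1), 0.2)
})
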