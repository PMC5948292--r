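test_that("data years loop with period n_base_years", {
  expect_equal(loop_base_year(0, 5), 0L)
  expect_equal(loop_base_year(4, 5), 4L)
  expect_equal(loop_base_year(5, 5), 0L)
  expect_equal(loop_base_year(24, 5), 4L)
  expect_equal(loop_base_year(0:24, 5), rep(0:4, 5))
})

test_that("yearly flows match a hand-enumerated oracle and partition everyone", {
  insured <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  beneficial <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  optout <- c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  res <- apply_flows(insured, beneficial, optout)
  # by hand: persons 3 and 5 (insured, not beneficial, drawn) opt out;
  # 1, 2, 4, 6 keep; 7, 8 opt back in; 9, 10 stay out
  expect_equal(res$flows,
               c(opt_out = 2L, keep = 4L, opt_in = 2L, stay_out = 2L))
  expect_equal(which(res$insured), c(1L, 2L, 4L, 6L, 7L, 8L))
  expect_equal(sum(res$flows), 10L)
})

test_that("no uninsured beneficial person stays out; draws only hit the exposed", {
  set.seed(33)
  for (i in 1:50) {
    n <- 30
    insured <- runif(n) < 0.6
    ben <- runif(n) < 0.5
    out <- runif(n) < 0.5
    res <- apply_flows(insured, ben, out)
    expect_true(all(res$insured[!insured & ben]))       # opt-in deterministic
    expect_true(all(res$insured[insured & ben]))        # beneficial keep
    expect_true(all(!res$insured[!insured & !ben]))     # stay out
    expect_equal(sum(res$flows), n)
    expect_equal(res$flows[["keep"]] + res$flows[["opt_in"]],
                 sum(res$insured))
  }
})

test_that("controls: p = 0 and unbounded risk premium pin uptake at 100%", {
  panel <- mid_panel()
  preds <- mid_predictors()
  r0 <- run_market(panel, simulation_config(horizon = 8, opt_out_prob = 0,
                                            seed = 3), predictors = preds)
  expect_true(all(r0$trajectories$uptake == 1))
  rInf <- run_market(panel,
                     simulation_config(horizon = 8, opt_out_prob = 0.3,
                                       operating_risk_premium = Inf,
                                       seed = 3),
                     predictors = preds)
  expect_true(all(rInf$trajectories$uptake == 1))
})

test_that("trajectories are seed-deterministic and flows are conserved", {
  panel <- mid_panel()
  preds <- mid_predictors()
  cfg <- simulation_config(horizon = 12, opt_out_prob = 0.1,
                           scheme = "community", seed = 9, n_replicates = 3)
  r1 <- suppressWarnings(run_market(panel, cfg, predictors = preds))
  r2 <- suppressWarnings(run_market(panel, cfg, predictors = preds))
  expect_identical(r1$trajectories, r2$trajectories)
  tr <- r1$trajectories[r1$trajectories$sim_year > 0, ]
  n <- n_individuals(panel)
  expect_true(all(tr$flow_opt_out + tr$flow_keep +
                    tr$flow_opt_in + tr$flow_stay_out == n))
  expect_true(all(tr$flow_keep + tr$flow_opt_in == tr$n_insured))
  # data years loop across cycle boundaries without crashing or leaking
  expect_equal(tr$data_year[tr$replicate == 1],
               loop_base_year(1:12, 5) + 1L)
})

test_that("a higher opt-out probability cannot raise uptake (paired seeds)", {
  panel <- mid_panel()
  preds <- mid_predictors()
  u25 <- function(p) {
    r <- suppressWarnings(run_market(
      panel, simulation_config(horizon = 15, opt_out_prob = p,
                               scheme = "community", seed = 4,
                               n_replicates = 2), predictors = preds))
    mean(r$trajectories$uptake[r$trajectories$sim_year == 15])
  }
  expect_gte(u25(0), u25(0.05))
  expect_gte(u25(0.05), u25(0.10))
})

test_that("community spiral: pool mean claims rise when exits are adverse", {
  panel <- mid_panel()
  preds <- mid_predictors()
  run <- suppressWarnings(run_market(
    panel, simulation_config(horizon = 10, opt_out_prob = 0.2,
                             scheme = "community", opt_in_prob = 0,
                             seed = 3), predictors = preds))
  tr <- run$trajectories
  # compare the same data year one cycle apart: the shrinking pool is sicker
  for (s in 1:5) {
    expect_gt(tr$pool_mean_claims[tr$sim_year == s + 5],
              tr$pool_mean_claims[tr$sim_year == s])
  }
  # uptake can only fall without opt-in
  expect_true(all(diff(tr$uptake) <= 0))
})

test_that("an emptied pool terminates the trajectory as a market collapse", {
  panel <- mid_panel()
  preds <- mid_predictors()
  run <- suppressWarnings(run_market(
    panel, simulation_config(horizon = 5, opt_out_prob = 1,
                             scheme = "community", loading = 100,
                             operating_risk_premium = 0, seed = 3),
    predictors = preds))
  expect_equal(run$status, "collapsed")
  expect_equal(max(run$trajectories$sim_year), 1)
  expect_equal(run$trajectories$n_insured[2], 0)
})

test_that("full risk rating: the not-beneficial set is the closed-form tail", {
  panel <- mid_panel()
  preds <- mid_predictors()
  cfg <- simulation_config(horizon = 10, opt_out_prob = 0.1,
                           scheme = "individual", seed = 6)
  run <- run_market(panel, cfg, predictors = preds,
                    keep_classification = TRUE)
  inputs <- shisim:::build_sim_inputs(panel, preds)
  threshold <- cfg$operating_risk_premium / cfg$loading
  for (s in 1:10) {
    d <- loop_base_year(s, 5) + 1L
    expect_identical(!run$classification[[s]],
                     inputs$pred[, d] > threshold)
  }
})
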