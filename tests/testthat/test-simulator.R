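test_that("the staggered ramp totals 303 centre-months over 24 months", {
  s <- recruitment_schedule()
  expect_identical(s$horizon, 24L)
  expect_equal(s$centre_months, 303)
})

test_that("recruitment is Poisson with the schedule's exposure", {
  expect_length(simulate_recruitment(recruitment_schedule(rate = 0,
                                                          cap = Inf),
                                     seed = 1), 0)
  # uncapped mean over many seeds matches rate x centre-months
  s <- recruitment_schedule(rate = 170 / 303, cap = Inf)
  set.seed(2)
  totals <- replicate(3000, length(simulate_recruitment(s)))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 170), 3 * se)
  # capped recruitment stops exactly at the cap, entries sorted
  e <- simulate_recruitment(recruitment_schedule(cap = 50), seed = 3)
  expect_length(e, 50)
  expect_true(all(diff(e) >= 0))
})

test_that("outcome generation recovers the generating moments", {
  m <- endpoint_model(c(18, 19, 20),
                      matrix(c(1, 0.3, 0.5, 0.3, 1, 0.6, 0.5, 0.6, 1), 3),
                      means_active = c(0, 0, 7))
  d <- simulate_outcomes(m, entries = rep(0, 1e5), seed = 4)
  X <- as.matrix(as.data.frame(d)[, c("outcome_3m", "outcome_6m",
                                      "outcome_12m")])
  cc <- cor(X[d$arm == 0, ])
  expect_lt(max(abs(cc - m$corr)), 0.015)
  expect_lt(max(abs(apply(X[d$arm == 0, ], 2, sd) - m$sigmas)), 0.2)
  # the treatment difference lands on the final endpoint only
  dd <- colMeans(X[d$arm == 1, ]) - colMeans(X[d$arm == 0, ])
  expect_lt(max(abs(dd[1:2])), 0.5)
  expect_equal(unname(dd[3]), 7, tolerance = 0.5)
  tr <- scenario_truth(start_model(0.5), 10)
  expect_equal(tr$means_active - tr$means_control, c(0, 0, 10))
  expect_error(endpoint_model(c(0, 1, 1), 0.5), "positive")
})

test_that("identical seeds give identical traces", {
  d <- trial_design(spending_plan(c(0.5, 0.975), c(0.001, 0.025)),
                    matrix(c(60, 45, 25), 1), 85, start_model(0.5))
  t1 <- run_simulated_trial(d, scenario_truth(d$assumed, 5), seed = 71)
  t2 <- run_simulated_trial(d, scenario_truth(d$assumed, 5), seed = 71)
  expect_identical(t1$looks, t2$looks)
  expect_identical(t1$reject, t2$reject)
  t3 <- run_simulated_trial(d, scenario_truth(d$assumed, 5), seed = 72)
  expect_false(identical(t1$looks$S, t3$looks$S))
})

test_that("infinite early boundaries always reach the final analysis", {
  plan <- spending_plan(c(0, 0, 0.975), c(0, 0, 0.025))
  d <- trial_design(plan, rbind(c(55, 40, 20), c(70, 55, 35)), 85,
                    start_model(0.5),
                    recruitment = recruitment_schedule(cap = 170))
  expect_true(all(is.infinite(d$bounds$upper[1:2])))
  for (seed in 1:5) {
    tr <- run_simulated_trial(d, scenario_truth(d$assumed, 0), seed = seed)
    expect_identical(tr$stopped, 0L)
    expect_false(is.null(tr$final))
    expect_identical(tr$n_randomised, 170L)
  }
})

test_that("operating characteristics aggregate traces coherently", {
  d <- trial_design(spending_plan(c(0.5, 0.975), c(0.001, 0.025)),
                    matrix(c(60, 45, 25), 1), 85, start_model(0.5))
  oc <- operating_characteristics(d, scenario_truth(d$assumed, 0),
                                  n_reps = 400, seed = 81)
  expect_true(all(oc$p_wF >= 0 & oc$p_wF <= 1))
  expect_true(all(diff(oc$p_wF) >= 0))
  expect_lte(oc$ess, 170 + 1e-9)
  expect_equal(oc$p_E + oc$p_12m, oc$power)
  ess <- expected_sample_size(oc)
  expect_lt(abs(ess$from_traces - ess$from_probabilities), 3 * ess$se)
  # futility stopping under the null tracks the spending (loose 3.5 SE here)
  expect_lt(abs(oc$p_wF[1] - 0.5), 3.5 * sqrt(0.25 / 400))
})

test_that("planned counts validation and design assembly", {
  expect_error(trial_design(wk_plan(), rbind(c(25, 20, 15), c(20, 15, 10)),
                            30, wk_model()),
               "nondecreasing")
  expect_error(trial_design(wk_plan(), rbind(c(20, 15, 10), c(25, 20, 15)),
                            20, wk_model()),
               "at least the largest")
  expect_error(look_counts(c(10, 15, 20)), "non-increasing")
  d <- trial_design(wk_plan(), rbind(c(20, 15, 10), c(25, 20, 15)), 30,
                    wk_model(), recruitment = recruitment_schedule(cap = 60))
  expect_equal(d$schedule$info[3], 30 / 648)
  expect_equal(round(d$bounds$lower[1], 3), -0.842)
  expect_true(d$pooled_scheduling)   # equal assumed SDs -> pooled scheduling
  d2 <- trial_design(wk_plan(), rbind(c(20, 15, 10), c(25, 20, 15)), 30,
                     endpoint_model(c(17, 18, 19), 0.5),
                     recruitment = recruitment_schedule(cap = 60))
  expect_false(d2$pooled_scheduling)
})

test_that("abandoning looks after recruitment completes is honoured", {
  # tiny trial recruited almost instantly: looks would all be post-recruitment
  rec <- recruitment_schedule(centres_by_month = rep(60, 4), rate = 1,
                              cap = 60)
  plan <- spending_plan(c(0.5, 0.975), c(0.001, 0.025))
  d_keep <- trial_design(plan, matrix(c(25, 20, 15), 1), 30, start_model(0.5),
                         recruitment = rec, looks_after_recruitment = TRUE)
  d_drop <- trial_design(plan, matrix(c(25, 20, 15), 1), 30, start_model(0.5),
                         recruitment = rec, looks_after_recruitment = FALSE)
  kept <- run_simulated_trial(d_keep, scenario_truth(d_keep$assumed, 0),
                              seed = 91)
  dropped <- run_simulated_trial(d_drop, scenario_truth(d_drop$assumed, 0),
                                 seed = 91)
  expect_true(kept$looks$reached[1])
  expect_false(dropped$looks$reached[1])
  expect_identical(dropped$stopped, 0L)
})
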