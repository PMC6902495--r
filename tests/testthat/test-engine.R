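test_that("interim verdicts follow the strictness rule (futility <, efficacy >=)", {
  m <- wk_model()
  fx <- generate_fixture(m, c(20, 15, 10), seed = 41)
  bounds <- compute_boundaries(wk_plan(), wk_schedule())
  dec <- run_interim_analysis(fx, 1, bounds, assumed = m)
  expect_true(dec$verdict %in% c("stop_futility", "stop_efficacy", "continue"))
  S <- dec$effect$S
  # doctored boundaries around the realised statistic pin down the tie rule
  tie <- bounds
  tie$lower[1] <- S; tie$upper[1] <- S + 1
  expect_identical(run_interim_analysis(fx, 1, tie, assumed = m)$verdict,
                   "continue")        # S == l -> not below -> continue
  tie$lower[1] <- S - 1; tie$upper[1] <- S
  expect_identical(run_interim_analysis(fx, 1, tie, assumed = m)$verdict,
                   "stop_efficacy")   # S == u -> crossing inclusive
  tie$lower[1] <- S + 0.5; tie$upper[1] <- S + 1
  expect_identical(run_interim_analysis(fx, 1, tie, assumed = m)$verdict,
                   "stop_futility")
  expect_error(run_interim_analysis(fx, 9, bounds), "no boundaries")
})

test_that("with all correlations zero the engine is the classical z-test", {
  m0 <- endpoint_model(rep(20, 3), 0)
  fx <- generate_fixture(start_model(0.5), c(30, 25, 18), seed = 42)
  nu <- estimate_nuisance(fx)
  nu0 <- nuisance_estimate(nu$sigma_hats, diag(3))
  eff <- treatment_effect(fx, nu0)
  y <- fx$outcome_12m
  n0 <- sum(!is.na(y) & fx$arm == 0); n1 <- sum(!is.na(y) & fx$arm == 1)
  z <- (mean(y[fx$arm == 1], na.rm = TRUE) - mean(y[fx$arm == 0], na.rm = TRUE)) /
    (nu$sigma_hats[3] * sqrt(1 / n0 + 1 / n1))
  expect_equal(eff$S, z, tolerance = 1e-12)
})

test_that("future outcomes cannot leak into a look", {
  m <- start_model(0.5)
  d <- simulate_outcomes(m, entries = sort(runif(60, 0, 18)), seed = 43)
  dec <- run_interim_analysis(d, 1,
                              compute_boundaries(wk_plan(), wk_schedule()),
                              time = 16, assumed = m)
  # poison everything not yet observable at month 16 with absurd sentinels
  poisoned <- as.data.frame(d)
  lags <- c(3, 6, 12)
  cols <- c("outcome_3m", "outcome_6m", "outcome_12m")
  for (k in 1:3) {
    mask <- poisoned$entry_month + lags[k] > 16
    poisoned[[cols[k]]][mask] <- 1e6
  }
  dec2 <- run_interim_analysis(trial_dataset(poisoned), 1,
                               compute_boundaries(wk_plan(), wk_schedule()),
                               time = 16, assumed = m)
  expect_identical(dec$verdict, dec2$verdict)
  expect_equal(dec$effect$B, dec2$effect$B, tolerance = 1e-12)
})

test_that("information monitoring locates planned-information crossings", {
  m <- start_model(0.5)
  set.seed(44)
  d <- simulate_outcomes(m, entries = sort(runif(120, 0, 14)), seed = 44)
  sched <- information_schedule(c(
    expected_information(look_counts(c(45, 35, 20)), m),
    final_information(60, 20)))
  mon <- monitor_information(d, sched, assumed = m)
  expect_false(is.na(mon$looks$time[1]))
  # the trigger is the first eligible event at or past the planned level
  path <- mon$path
  hit <- which(path$info_trigger >= sched$info[1] & path$final_arrival &
                 path$n_final_control >= 10 & path$n_final_active >= 10)[1]
  expect_equal(mon$looks$time[1], path$time[hit])
  # information only accrues through final outcomes when rho = 0
  m0 <- endpoint_model(rep(20, 3), 0)
  p0 <- augseq:::information_path(d, assumed = m0)
  # between final arrivals the rho = 0 *expected* information is flat; the
  # estimated path may wiggle, but plugging assumed values in directly it is
  # a step function of the final count
  nfin <- p0$n_final_control + p0$n_final_active
  expect_true(all(diff(nfin) >= 0))
})

test_that("unreached looks are reported as NA, not errors", {
  m <- start_model(0.5)
  d <- simulate_outcomes(m, entries = sort(runif(30, 0, 10)), seed = 45)
  sched <- information_schedule(c(0.2, 0.3))   # unattainably high
  mon <- monitor_information(d, sched, assumed = m)
  expect_true(is.na(mon$looks$time[1]))
})

test_that("overrunning analysis: closed-form p, plain-difference reduction", {
  m <- start_model(0.5)
  d <- complete_dataset(40, m, seed = 46)
  ov <- overrun_analysis(d)
  plain <- mean(d$outcome_12m[d$arm == 1]) - mean(d$outcome_12m[d$arm == 0])
  expect_equal(ov$B, plain, tolerance = 1e-12)
  expect_equal(ov$p_value, 2 * pnorm(-abs(ov$B) / sqrt(ov$varB)),
               tolerance = 1e-12)
  expect_equal(unname(ov$n_per_arm), c(40, 40))
  # a null effect gives p = 1 exactly
  dz <- as.data.frame(d)
  dz$outcome_12m[dz$arm == 1] <- dz$outcome_12m[dz$arm == 0]
  ovz <- overrun_analysis(trial_dataset(dz))
  expect_equal(ovz$B, 0, tolerance = 1e-12)
  expect_equal(ovz$p_value, 1, tolerance = 1e-12)
  # incomplete final data: warn and analyse completers
  di <- as.data.frame(d); di$outcome_12m[1:5] <- NA
  expect_warning(ovi <- overrun_analysis(trial_dataset(di)), "completers")
  expect_true(ovi$p_value >= 0 && ovi$p_value <= 1)
})
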