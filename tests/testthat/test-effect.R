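test_that("zero early-final correlation reduces B to the plain mean difference", {
  m <- endpoint_model(rep(18, 3), matrix(c(1, 0.4, 0, 0.4, 1, 0, 0, 0, 1), 3))
  fx <- generate_fixture(m, c(20, 15, 10), seed = 101)
  eff <- treatment_effect(fx, m)
  final <- fx$outcome_12m
  plain <- mean(final[fx$arm == 1], na.rm = TRUE) -
    mean(final[fx$arm == 0], na.rm = TRUE)
  expect_equal(eff$B, plain, tolerance = 1e-12)
})

test_that("fully observed data give the plain mean difference (empty corrections)", {
  d <- complete_dataset(25, start_model(0.5), seed = 7)
  nu <- estimate_nuisance(d)
  eff <- treatment_effect(d, nu)
  plain <- mean(d$outcome_12m[d$arm == 1]) - mean(d$outcome_12m[d$arm == 0])
  expect_equal(eff$B, plain, tolerance = 1e-12)
  expect_equal(eff$S, eff$B / sqrt(eff$varB))
  expect_equal(eff$info, 1 / eff$varB)
})

test_that("estimator matches a naive loop transcription on seeded fixtures", {
  for (seed in c(11, 12, 13)) {
    m <- wk_model()
    fx <- generate_fixture(m, c(20, 15, 10), seed = seed)
    nu <- estimate_nuisance(fx)
    eff <- treatment_effect(fx, nu)
    expect_equal(eff$B, naive_eq1(fx, nu), tolerance = 1e-10)
  }
  # and with a non-trivial rho12 and unequal layer sizes
  m2 <- endpoint_model(c(15, 18, 21), matrix(c(1, 0.3, 0.45,
                                               0.3, 1, 0.6,
                                               0.45, 0.6, 1), 3))
  fx2 <- generate_fixture(m2, c(30, 18, 9), seed = 99)
  nu2 <- estimate_nuisance(fx2)
  expect_equal(treatment_effect(fx2, nu2)$B, naive_eq1(fx2, nu2),
               tolerance = 1e-10)
})

test_that("variance formula reproduces the printed closed form and examples", {
  m <- wk_model()
  # first worked-example look: information ~ 0.019
  expect_equal(expected_information(look_counts(c(20, 15, 10)), m),
               1 / eq2_variance(20, 15, 10, 0.5, 0.5, 0, 18))
  expect_equal(round(expected_information(look_counts(c(20, 15, 10)), m), 3),
               0.019)
  # uncorrelated case collapses to 2 sigma^2 / N3
  m0 <- endpoint_model(rep(18, 3), 0)
  expect_equal(treatment_effect_variance(look_counts(c(20, 15, 10)), m0),
               2 * 18^2 / 10, tolerance = 1e-12)
  # accrual example: information fraction 21.4% under uniform rho = 0.5
  frac <- information_fraction(
    expected_information(look_counts(c(50, 35, 15)), start_model(0.5)),
    85 / 800)
  expect_equal(round(frac, 1), 21.4)
  expect_equal(round(100 * (15 / 800) / (85 / 800), 1), 17.6)
})

test_that("variance errors: non-PSD correlations and empty final endpoint", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  nu_bad <- list(K = 3, sigma_hats = rep(20, 3), corr_hat = bad)
  class(nu_bad) <- "nuisance_estimate"   # bypass constructor repair
  expect_error(treatment_effect_variance(look_counts(c(20, 15, 10)), nu_bad),
               "positive semi-definite")
  expect_error(treatment_effect_variance(look_counts(c(20, 15, 0)),
                                         start_model(0.5)),
               "no information")
  d <- complete_dataset(5, start_model(0.5), seed = 3)
  d$outcome_12m[d$arm == 1] <- NA
  d2 <- trial_dataset(as.data.frame(d))
  expect_error(treatment_effect(d2, start_model(0.5)), "insufficient data")
})

test_that("augmentation never loses information and is monotone in rho", {
  set.seed(42)
  for (i in 1:40) {
    C <- crossprod(matrix(stats::rnorm(9), 3))
    d <- sqrt(diag(C))
    cand <- C / (d %o% d)
    cand <- (cand + t(cand)) / 2; diag(cand) <- 1
    N3 <- sample(5:30, 1)
    N2 <- N3 + sample(0:20, 1)
    N1 <- N2 + sample(0:20, 1)
    m <- endpoint_model(runif(3, 5, 30), cand)
    v <- treatment_effect_variance(look_counts(c(N1, N2, N3)), m)
    expect_lte(v, 2 * m$sigmas[3]^2 / N3 + 1e-9)
    expect_gt(v, 0)
  }
  # with rho12 = 0, variance is non-increasing in rho13 and rho23
  # (rho13^2 + rho23^2 <= 1 keeps the matrix PSD)
  vs <- sapply(seq(0, 0.7, by = 0.1), function(r) {
    m <- endpoint_model(rep(20, 3), matrix(c(1, 0, r, 0, 1, r, r, r, 1), 3))
    treatment_effect_variance(look_counts(c(60, 45, 25)), m)
  })
  expect_true(all(diff(vs) <= 1e-12))
})

test_that("general-K machinery specialises exactly to the printed K = 3 form", {
  set.seed(77)
  for (i in 1:20) {
    r13 <- runif(1, -0.7, 0.7); r23 <- runif(1, -0.7, 0.7)
    r12 <- runif(1, -0.4, 0.4)
    R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) next
    s3 <- runif(1, 5, 30)
    N3 <- sample(4:20, 1); N2 <- N3 + sample(0:15, 1); N1 <- N2 + sample(0:15, 1)
    m <- endpoint_model(c(runif(2, 5, 30), s3), R)
    expect_equal(treatment_effect_variance(look_counts(c(N1, N2, N3)), m),
                 eq2_variance(N1, N2, N3, r13, r23, r12, s3),
                 tolerance = 1e-12)
  }
})

test_that("K = 2 with complete follow-up is the plain two-sample difference", {
  m <- endpoint_model(rep(10, 2), 0.6)
  d <- simulate_outcomes(m, entries = rep(0, 40), arms = rep(c(0L, 1L), 20),
                         lags = c(3, 12), seed = 5)
  eff <- generalized_effect(d, m)
  plain <- mean(d$outcome_12m[d$arm == 1]) - mean(d$outcome_12m[d$arm == 0])
  expect_equal(eff$B, plain, tolerance = 1e-12)
  expect_equal(eff$varB, 2 * 100 / 20, tolerance = 1e-12)
})

test_that("K = 4 generalisation: unbiased and variance matches Monte Carlo", {
  R <- 0.5 + diag(4) * 0.5
  m <- endpoint_model(rep(20, 4), R,
                      means_active = c(3, -2, 1, 8))   # early effects too
  N <- c(40, 30, 20, 10)
  draws <- mc_estimator_draws(N, m, reps = 4e4, seed = 31)
  v_form <- treatment_effect_variance(look_counts(N), m)
  expect_equal(mean(draws), 8, tolerance = 4 * sd(draws) / sqrt(length(draws)))
  expect_equal(var(draws), v_form, tolerance = 0.05 * v_form)
})

test_that("information fraction arithmetic and overshoot warning", {
  expect_equal(information_fraction(0.046, 0.046), 100)
  expect_equal(information_fraction(0.023, 0.046, percent = FALSE), 0.5)
  expect_warning(information_fraction(0.05, 0.046), "overshoot")
  expect_error(information_fraction(0.02, 0), "final_info")
  # fractions are nondecreasing as counts accrue
  m <- start_model(0.5)
  counts <- rbind(c(50, 35, 15), c(55, 40, 20), c(60, 45, 25), c(65, 50, 30))
  infos <- apply(counts, 1, function(x)
    expected_information(look_counts(x), m))
  expect_true(all(diff(infos) > 0))
})

test_that("fixed-design sample size: printed value, scaling law, grid oracle", {
  ss <- fixed_design_sample_size(10, 20, 0.9, 0.05)
  expect_identical(ss$n_per_group, 85L)
  expect_identical(ss$n_total, 170L)
  # doubling delta quarters the raw (pre-ceiling) requirement
  raw <- function(delta) 2 * 20^2 *
    (qnorm(0.975) + qnorm(0.9))^2 / delta^2
  expect_equal(raw(20), raw(10) / 4)
  # smallest n with analytic power >= 0.9 (brute force over n)
  an_power <- function(n) pnorm(10 / (20 * sqrt(2 / n)) - qnorm(0.975))
  n_grid <- which(sapply(1:200, an_power) >= 0.9)[1]
  expect_identical(ss$n_per_group, as.integer(n_grid))
  expect_error(fixed_design_sample_size(0, 20), "delta")
  expect_error(fixed_design_sample_size(10, -1), "sigma")
})
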