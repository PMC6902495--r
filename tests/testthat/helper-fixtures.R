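# shared models, datasets and independent oracles used across the suite

# worked-example design assumptions: sigma 18, rho13 = rho23 = 0.5, rho12 = 0
wk_model <- function() {
  endpoint_model(rep(18, 3),
                 matrix(c(1, 0, 0.5,
                          0, 1, 0.5,
                          0.5, 0.5, 1), 3))
}

# motivating-trial assumptions: sigma 20, uniform correlation
start_model <- function(rho = 0.5) endpoint_model(rep(20, 3), rho)

wk_plan <- function() spending_plan(c(0.200, 0.600, 0.975),
                                    c(0.000, 0.001, 0.025))

wk_schedule <- function() {
  m <- wk_model()
  information_schedule(c(expected_information(look_counts(c(20, 15, 10)), m),
                         expected_information(look_counts(c(25, 20, 15)), m),
                         final_information(30, 18)))
}

# complete dataset (everyone fully observed), equal arms, entries at 0
complete_dataset <- function(n_per_arm, model, seed) {
  simulate_outcomes(model, entries = rep(0, 2 * n_per_arm),
                    arms = rep(c(0L, 1L), n_per_arm), seed = seed)
}

# Literal loop transcription of the two-early-endpoint estimator for equal
# arms: B = (1/N3)[ sum_{i<=N3} (x_i13 - x_i03)
#   + rho_k3 (s3/sk) sum_{i=N3+1..Nk} (d_ik - mean_{m<=Nk} d_mk) ], with
# participants in each arm ordered completers-first and paired by position.
# Independent of the package's arm-mean formulation.
naive_eq1 <- function(data, nu) {
  cols <- attr(data, "outcome_cols")
  arm_block <- function(a) {
    d <- data[data$arm == a, cols]
    d[order(rowSums(is.na(d))), , drop = FALSE]   # completers first
  }
  d0 <- arm_block(0); d1 <- arm_block(1)
  N <- sapply(seq_along(cols), function(k)
    min(sum(!is.na(d0[[k]])), sum(!is.na(d1[[k]]))))
  K <- length(cols)
  tot <- 0
  for (i in seq_len(N[K])) tot <- tot + (d1[i, K] - d0[i, K])
  for (k in seq_len(K - 1)) {
    if (N[k] == N[K]) next
    dbar <- mean(sapply(seq_len(N[k]), function(m) d1[m, k] - d0[m, k]))
    s <- 0
    for (i in (N[K] + 1):N[k]) s <- s + (d1[i, k] - d0[i, k] - dbar)
    tot <- tot + nu$corr_hat[k, K] * nu$sigma_hats[K] / nu$sigma_hats[k] * s
  }
  tot / N[K]
}

# closed-form printed variance for K = 3, equal arms
eq2_variance <- function(N1, N2, N3, r13, r23, r12, s3) {
  (2 * s3^2 / N3) * (1 - r13^2 * (N1 - N3) / N1 - r23^2 * (N2 - N3) / N2 +
                       2 * r13 * r23 * r12 * (1 - N3 / N2))
}

# Vectorised Monte-Carlo oracle for the estimator's variance at fixed
# monotone equal-arm counts, drawing paired differences directly from the
# outcome model and applying the estimator with *true* nuisance values.
mc_estimator_draws <- function(N, model, reps, seed) {
  set.seed(seed)
  K <- length(N)
  Sd <- 2 * model_covariance(model)      # covariance of paired differences
  ch <- chol(Sd)
  D <- matrix(stats::rnorm(reps * K * N[1]), ncol = K) %*% ch
  dim(D) <- c(N[1], reps, K)
  a <- model$corr[seq_len(K - 1), K] * model$sigmas[K] /
    model$sigmas[seq_len(K - 1)]
  cm <- function(idx, k) colMeans(matrix(D[idx, , k], nrow = length(idx)))
  delta <- model$means_active - model$means_control
  B <- cm(seq_len(N[K]), K) + delta[K]
  for (k in seq_len(K - 1)) {
    if (N[k] == N[K]) next
    B <- B + a[k] * (N[k] - N[K]) / N[K] *
      (cm((N[K] + 1):N[k], k) - cm(seq_len(N[k]), k))
  }
  B
}

# Monte-Carlo crossing probabilities for boundaries on the canonical joint
# distribution (independent score increments), independent of the quadrature
mc_crossing <- function(lower, upper, info, theta, reps, seed) {
  set.seed(seed)
  W <- length(info)
  dI <- diff(c(0, info))
  Tm <- matrix(0, reps, W)
  acc <- 0
  for (w in seq_len(W)) {
    acc <- acc + stats::rnorm(reps, theta * dI[w], sqrt(dI[w]))
    Tm[, w] <- acc
  }
  S <- sweep(Tm, 2, sqrt(info), "/")
  alive <- rep(TRUE, reps)
  pL <- pU <- numeric(W)
  for (w in seq_len(W)) {
    lo <- alive & S[, w] < lower[w]
    up <- alive & S[, w] >= upper[w]
    if (w == W) lo <- alive & S[, w] < upper[w]   # final partition at u_W
    pL[w] <- mean(lo); pU[w] <- mean(up)
    alive <- alive & !lo & !up
  }
  list(lower = pL, upper = pU)
}
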