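# Event-driven information accrual.
#
# Observation times are entry + lag, with common lags across participants, so
# at any calendar time the set of participants with endpoint k observed is a
# prefix of the arm's entry-ordered participants. Every running quantity the
# nuisance estimates need (arm sums, sums of squares, cross-products) is then
# a prefix sum, and the observed information can be evaluated at every
# outcome-arrival event with vectorised arithmetic. This is the fast path the
# simulator uses; it reproduces estimate_nuisance()/generalized_effect() on
# the restricted dataset exactly (see tests).

# Build prefix-sum structures for one trial's complete outcome data.
# entry: numeric entry times; arm: 0/1; X: n x K outcomes; lags: increasing.
info_engine_build <- function(entry, arm, X, lags, assumed) {
  K <- length(lags)
  fb <- as_nuisance(assumed)
  if (fb$K != K) stop("assumed model has wrong number of endpoints")
  arms <- list()
  for (a in 0:1) {
    sel <- which(arm == a)
    sel <- sel[order(entry[sel])]
    Xa <- X[sel, , drop = FALSE]
    n <- length(sel)
    cs1 <- apply(Xa, 2, cumsum)
    cs2 <- apply(Xa^2, 2, cumsum)
    if (n == 1) { cs1 <- matrix(cs1, 1); cs2 <- matrix(cs2, 1) }
    pair_idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
    cp <- matrix(0, n, nrow(pair_idx))
    for (p in seq_len(nrow(pair_idx)))
      cp[, p] <- cumsum(Xa[, pair_idx[p, 1]] * Xa[, pair_idx[p, 2]])
    arms[[a + 1]] <- list(entry = entry[sel],
                          cs1 = rbind(0, cs1), cs2 = rbind(0, cs2),
                          cp = rbind(0, cp), n = n)
  }
  pair_idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  events <- sort(unique(as.vector(outer(entry, lags, "+"))))
  final_arrival <- events %in% (entry + lags[K])
  list(arms = arms, K = K, lags = lags, fb = fb, pair_idx = pair_idx,
       events = events, final_arrival = final_arrival)
}

# Observed counts, SD and correlation estimates at each time in `tt`.
# Returns list of matrices indexed by time.
info_engine_nuisance <- function(eng, tt) {
  K <- eng$K
  nt <- length(tt)
  idx <- lapply(eng$arms, function(a) {
    m <- vapply(seq_len(K),
                function(k) findInterval(tt - eng$lags[k], a$entry),
                numeric(nt))
    matrix(m, nrow = nt)
  })
  # pooled arm-centred SDs
  sig <- matrix(NA_real_, nt, K)
  ntot <- matrix(0, nt, K)
  sxx_k <- matrix(0, nt, K)            # pooled centred SS over all observed
  for (k in seq_len(K)) {
    sxx <- numeric(nt)
    for (a in 1:2) {
      n <- idx[[a]][, k]
      s1 <- eng$arms[[a]]$cs1[n + 1, k]
      s2 <- eng$arms[[a]]$cs2[n + 1, k]
      sxx <- sxx + ifelse(n > 0, s2 - s1^2 / pmax(n, 1), 0)
      ntot[, k] <- ntot[, k] + n
    }
    sxx_k[, k] <- sxx
    df <- ntot[, k] - 2
    sig[, k] <- ifelse(ntot[, k] >= 3 & df > 0 & sxx > 0,
                       sqrt(sxx / pmax(df, 1)), eng$fb$sigma_hats[k])
  }
  # pooled arm-centred pairwise correlations; the pairwise-complete set for
  # (k, j), k < j, is the prefix observed for the later endpoint j
  np <- nrow(eng$pair_idx)
  rho <- matrix(NA_real_, nt, np)
  for (p in seq_len(np)) {
    k <- eng$pair_idx[p, 1]; j <- eng$pair_idx[p, 2]
    sxy <- sxx <- syy <- numeric(nt)
    mtot <- numeric(nt)
    for (a in 1:2) {
      A <- eng$arms[[a]]
      nk <- idx[[a]][, k]
      m <- idx[[a]][, j]
      xbar <- ifelse(nk > 0, A$cs1[nk + 1, k] / pmax(nk, 1), 0)
      ybar <- ifelse(m > 0, A$cs1[m + 1, j] / pmax(m, 1), 0)
      s1x <- A$cs1[m + 1, k]; s2x <- A$cs2[m + 1, k]
      s1y <- A$cs1[m + 1, j]; s2y <- A$cs2[m + 1, j]
      cpm <- A$cp[m + 1, p]
      sxy <- sxy + cpm - xbar * s1y - ybar * s1x + m * xbar * ybar
      sxx <- sxx + s2x - 2 * xbar * s1x + m * xbar^2
      syy <- syy + s2y - 2 * ybar * s1y + m * ybar^2
      mtot <- mtot + m
    }
    r <- ifelse(mtot >= 3 & sxx > 0 & syy > 0,
                sxy / sqrt(pmax(sxx * syy, .Machine$double.eps)),
                eng$fb$corr_hat[eng$pair_idx[p, 1], eng$pair_idx[p, 2]])
    rho[, p] <- pmin(pmax(r, -0.99), 0.99)
  }
  list(idx = idx, sig = sig, rho = rho, ntot = ntot, sxx_k = sxx_k)
}

# harmonic-mean effective per-arm counts, nt x K
effective_counts <- function(eng, nu) {
  K <- eng$K
  n0 <- nu$idx[[1]]; n1 <- nu$idx[[2]]
  tot <- n0 + n1
  ifelse(tot > 0 & n0 > 0 & n1 > 0, 2 * n0 * n1 / pmax(tot, 1), 0)
}

# observed information at each time; K = 3 uses the vectorised closed form,
# general K loops over times through the exact covariance algebra
info_engine_information <- function(eng, nu) {
  K <- eng$K
  Ne <- effective_counts(eng, nu)
  nt <- nrow(Ne)
  info <- numeric(nt)
  ok <- Ne[, K] >= 1
  if (K == 3L) {
    # pair order from upper.tri: (1,2), (1,3), (2,3)
    r12 <- nu$rho[, 1]; r13 <- nu$rho[, 2]; r23 <- nu$rho[, 3]
    # 3x3 correlation matrix is PSD iff this determinant is nonnegative;
    # near-singular estimates (tiny determinant) go through the repair path
    # so monitoring matches the estimate_nuisance() treatment
    det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
    bracket <- 1 - r13^2 * (Ne[, 1] - Ne[, 3]) / pmax(Ne[, 1], 1) -
      r23^2 * (Ne[, 2] - Ne[, 3]) / pmax(Ne[, 2], 1) +
      2 * r13 * r23 * r12 * (1 - Ne[, 3] / pmax(Ne[, 2], 1))
    v <- 2 * nu$sig[, 3]^2 / pmax(Ne[, 3], 1) * bracket
    suspect <- bracket <= 0 | det3 < 1e-4
    info[ok & !suspect] <- 1 / v[ok & !suspect]
    bad <- which(ok & suspect)
  } else {
    bad <- which(ok)          # general K: always check/repair per time
  }
  # non-PSD or near-singular estimates: PSD-repair and re-evaluate
  for (i in bad) {
    R <- diag(K)
    R[eng$pair_idx] <- nu$rho[i, ]
    R[eng$pair_idx[, c(2, 1), drop = FALSE]] <- nu$rho[i, ]
    R <- repair_psd(clamp_corr(R))
    v <- varB_general(Ne[i, ], nu$sig[i, ], R)
    info[i] <- if (v > 0) 1 / v else 0
  }
  info
}

# Look-scheduling (trigger) information.
#
# Two differences from the plug-in analysis information 1/var_hat(B):
# (1) when the design assumes a common outcome SD across the repeated
#     measurements, the scheduling SD pools the arm-centred residuals of all
#     K endpoints (df = sum n_k - 2K), the efficient estimate under that
#     assumption -- scheduling should not chase the sampling noise of the
#     final-endpoint-only SD, whose first-passage selection would distort
#     stopping probabilities;
# (2) the reciprocal-variance bias correction (df - 2)/df, since
#     E[1/sigma_hat^2] = df/((df - 2) sigma^2): uncorrected, looks trigger
#     systematically before the planned counts are reached.
# The analysis statistic S_w always keeps the plug-in per-endpoint variance.
trigger_information <- function(eng, nu, pool) {
  K <- eng$K
  if (pool) {
    df <- rowSums(nu$ntot) - 2 * K
    sp <- sqrt(rowSums(nu$sxx_k) / pmax(df, 1))
    nu2 <- nu
    use <- df >= 1 & is.finite(sp) & sp > 0
    for (k in seq_len(K)) nu2$sig[use, k] <- sp[use]
    info_engine_information(eng, nu2) * ifelse(df > 2, (df - 2) / df, 0)
  } else {
    df <- nu$ntot[, K] - 2
    info_engine_information(eng, nu) * ifelse(df > 2, (df - 2) / df, 0)
  }
}

# pooled scheduling is the default whenever the assumed model treats the
# endpoint SDs as equal (as the motivating trial does)
resolve_scheduling_sd <- function(scheduling_sd, assumed) {
  scheduling_sd <- match.arg(scheduling_sd,
                             c("auto", "pooled", "per_endpoint"))
  if (scheduling_sd != "auto") return(scheduling_sd == "pooled")
  !is.null(assumed) &&
    diff(range(as_nuisance(assumed)$sigma_hats)) < 1e-9
}

# augmented effect estimate at time index i of the nuisance evaluation
info_engine_effect <- function(eng, nu, i) {
  K <- eng$K
  n0 <- nu$idx[[1]][i, ]; n1 <- nu$idx[[2]][i, ]
  if (n0[K] < 1 || n1[K] < 1)
    stop("insufficient data: no final-endpoint observation in an arm")
  A0 <- eng$arms[[1]]; A1 <- eng$arms[[2]]
  mean_at <- function(A, n, k) A$cs1[n + 1, k] / n
  D_K <- mean_at(A1, n1[K], K) - mean_at(A0, n0[K], K)
  N_K <- 2 * n0[K] * n1[K] / (n0[K] + n1[K])
  B <- D_K
  pair_col <- function(k, j) which(eng$pair_idx[, 1] == min(k, j) &
                                   eng$pair_idx[, 2] == max(k, j))
  for (k in seq_len(K - 1)) {
    m0 <- n0[k] - n0[K]; m1 <- n1[k] - n1[K]
    if (m0 < 1 || m1 < 1) next
    D_k <- mean_at(A1, n1[k], k) - mean_at(A0, n0[k], k)
    s0 <- (A0$cs1[n0[k] + 1, k] - A0$cs1[n0[K] + 1, k]) / m0
    s1 <- (A1$cs1[n1[k] + 1, k] - A1$cs1[n1[K] + 1, k]) / m1
    N_kS <- 2 * m0 * m1 / (m0 + m1)
    r <- nu$rho[i, pair_col(k, K)]
    B <- B + r * (nu$sig[i, K] / nu$sig[i, k]) * (N_kS / N_K) *
      ((s1 - s0) - D_k)
  }
  B
}

# information at all outcome-arrival events of a trial_dataset (slow path
# falls back to restricting the dataset when outcomes are missing for
# reasons other than follow-up lag)
information_path <- function(data, assumed = NULL, scheduling_sd = "auto") {
  stopifnot(inherits(data, "trial_dataset"))
  cols <- dataset_outcols(data)
  lags <- dataset_lags(data)
  pool <- resolve_scheduling_sd(scheduling_sd, assumed)
  X <- as.matrix(data[, cols, drop = FALSE])
  if (!anyNA(X)) {
    eng <- info_engine_build(data$entry_month, data$arm, X, lags, assumed)
    nu <- info_engine_nuisance(eng, eng$events)
    info <- info_engine_information(eng, nu)
    K <- length(lags)
    return(data.frame(time = eng$events, info = info,
                      info_trigger = trigger_information(eng, nu, pool),
                      n_final_control = nu$idx[[1]][, K],
                      n_final_active = nu$idx[[2]][, K],
                      final_arrival = eng$final_arrival))
  }
  # arbitrary missingness: evaluate by restriction at each event time
  obs_time <- sweep(ifelse(is.na(X), NA, 0), 1, data$entry_month, "+")
  obs_time <- sweep(obs_time, 2, lags, "+")
  events <- sort(unique(obs_time[!is.na(obs_time)]))
  K <- length(cols)
  stats <- vapply(events, function(t) {
    d <- observe_at(data, t)
    cts <- look_counts(monotone_counts(observed_counts(d)))
    nuis <- tryCatch(estimate_nuisance(d, fallback = assumed, warn = FALSE),
                     error = function(e) NULL)
    if (is.null(nuis) || any(cts$n[K, ] < 1))
      return(c(0, 0, cts$n[K, 1], cts$n[K, 2]))
    info <- 1 / treatment_effect_variance(cts, nuis)
    if (pool) {
      ss <- 0; ntot <- 0
      for (k in seq_len(K)) {
        v <- d[[cols[k]]]
        for (a in 0:1) {
          sel <- d$arm == a & !is.na(v)
          if (any(sel)) ss <- ss + sum((v[sel] - mean(v[sel]))^2)
        }
        ntot <- ntot + sum(!is.na(v))
      }
      df <- ntot - 2 * K
      info_t <- if (df > 2 && ss > 0) {
        nu_t <- nuisance_estimate(rep(sqrt(ss / df), K), nuis$corr_hat)
        (1 / treatment_effect_variance(cts, nu_t)) * (df - 2) / df
      } else 0
    } else {
      df <- sum(cts$n[K, ]) - 2
      info_t <- if (df > 2) info * (df - 2) / df else 0
    }
    c(info, info_t, cts$n[K, 1], cts$n[K, 2])
  }, numeric(4))
  data.frame(time = events, info = stats[1, ], info_trigger = stats[2, ],
             n_final_control = stats[3, ], n_final_active = stats[4, ],
             final_arrival = events %in% obs_time[, K])
}
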