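#' Augmented treatment-effect estimate at an interim analysis
#'
#' Estimates the treatment difference B on the long-term endpoint using all
#' available data: the plain difference of arm means among participants with
#' the final endpoint observed, plus for each early endpoint k a correction
#' term. The correction is the early-endpoint arm-mean difference among
#' participants with endpoint k observed but the final endpoint still pending,
#' centred by the arm-mean difference over everyone with endpoint k, scaled by
#' \eqn{\rho_{kK}\,\sigma_K/\sigma_k} and weighted by effective sample sizes.
#' Because the correction terms are mean-centred they have expectation zero
#' whatever the early-endpoint treatment effects, so B is unbiased for the
#' long-term difference.
#'
#' With equal per-arm counts this is exactly the printed two-early-endpoint
#' estimator; with unequal arms, per-arm harmonic-mean effective sample sizes
#' replace the common N in each term (see the methods vignette). With all
#' early-final correlations zero, B reduces to the plain difference of final
#' outcome means.
#'
#' @param data A [trial_dataset()], already restricted to a calendar time
#'   (see [observe_at()]).
#' @param nuisance A [nuisance_estimate()] (or an [endpoint_model()] whose
#'   sigmas/correlations are taken as known).
#' @return An object of class `effect_summary`: list with `B`, `varB`,
#'   `S = B/sqrt(varB)`, `info = 1/varB`, and `counts` (the [look_counts()]
#'   used).
#' @seealso [treatment_effect_variance()], [generalized_effect()]
#' @export
treatment_effect <- function(data, nuisance) {
  generalized_effect(data, nuisance)
}

#' Augmented effect estimate for any number of early endpoints
#'
#' The general-K form of [treatment_effect()]: one mean-centred correction
#' term per early endpoint. For K = 3 this is identical to the two-early-
#' endpoint estimator.
#'
#' @inheritParams treatment_effect
#' @return An `effect_summary`; see [treatment_effect()].
#' @export
generalized_effect <- function(data, nuisance) {
  stopifnot(inherits(data, "trial_dataset"))
  nu <- as_nuisance(nuisance)
  cols <- dataset_outcols(data)
  K <- length(cols)
  if (K < 2L) stop("need at least one early endpoint (K >= 2)")
  if (nu$K != K) stop("nuisance estimate is for K = ", nu$K,
                      " endpoints but data has K = ", K)

  final <- data[[cols[K]]]
  n_fin <- c(sum(!is.na(final) & data$arm == 0),
             sum(!is.na(final) & data$arm == 1))
  if (any(n_fin < 1))
    stop("insufficient data: no final-endpoint observation in the ",
         c("control", "active")[which(n_fin < 1)[1]], " arm")

  mean_diff <- function(values, sel) {
    m0 <- sel & data$arm == 0 & !is.na(values)
    m1 <- sel & data$arm == 1 & !is.na(values)
    c(d = mean(values[m1]) - mean(values[m0]), n0 = sum(m0), n1 = sum(m1))
  }
  harm <- function(n0, n1) if (n0 > 0 && n1 > 0) 2 * n0 * n1 / (n0 + n1) else 0

  all_rows <- rep(TRUE, nrow(data))
  fin <- mean_diff(final, all_rows)
  N_K <- harm(fin["n0"], fin["n1"])
  B <- unname(fin["d"])

  sK <- nu$sigma_hats[K]
  for (k in seq_len(K - 1L)) {
    vals <- data[[cols[k]]]
    pending <- is.na(final)                     # final endpoint not yet seen
    m0 <- sum(pending & data$arm == 0 & !is.na(vals))
    m1 <- sum(pending & data$arm == 1 & !is.na(vals))
    N_kS <- harm(m0, m1)
    if (N_kS == 0) next                         # no usable correction
    sub <- mean_diff(vals, pending)
    full <- mean_diff(vals, all_rows)
    B <- B + nu$corr_hat[k, K] * (sK / nu$sigma_hats[k]) *
      (N_kS / N_K) * unname(sub["d"] - full["d"])
  }

  # under non-monotone missingness the variance uses the monotone envelope
  # of the observed counts (the nested-set structure Eq-style variance needs)
  counts <- look_counts(monotone_counts(observed_counts(data)))
  varB <- treatment_effect_variance(counts, nu)
  new_effect_summary(unname(B), varB, counts)
}

# smallest nonincreasing-by-endpoint envelope of an observed count matrix
monotone_counts <- function(m) {
  for (k in (nrow(m) - 1):1) m[k, ] <- pmax(m[k, ], m[k + 1, ])
  m
}

new_effect_summary <- function(B, varB, counts) {
  structure(list(B = B, varB = varB, S = B / sqrt(varB), info = 1 / varB,
                 counts = counts),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("Augmented effect estimate: B = %.4g, var(B) = %.4g\n",
              x$B, x$varB))
  cat(sprintf("  z-statistic S = %.4g, information = %.4g\n", x$S, x$info))
  invisible(x)
}

#' Variance of the augmented effect estimate
#'
#' For K = 3 (two early endpoints) this evaluates the closed form
#' \deqn{\mathrm{var}(B) = \frac{2\sigma_3^2}{N_3}\Big[1
#'   - \rho_{13}^2\frac{N_1-N_3}{N_1}
#'   - \rho_{23}^2\frac{N_2-N_3}{N_2}
#'   + 2\rho_{13}\rho_{23}\rho_{12}\big(1-\tfrac{N_3}{N_2}\big)\Big],}
#' and for general K the exact covariance algebra over the multivariate
#' normal outcome model (which reproduces the K = 3 closed form). Unequal
#' per-arm counts enter through harmonic-mean effective sample sizes. The
#' variance never exceeds the unaugmented \eqn{2\sigma_K^2/N_K}: with a valid
#' correlation matrix the early endpoints cannot lose information.
#'
#' @param counts A [look_counts()] (or a length-K vector / K x 2 matrix).
#' @param model An [endpoint_model()] or [nuisance_estimate()] supplying
#'   sigmas and correlations.
#' @return var(B), a positive scalar.
#' @export
treatment_effect_variance <- function(counts, model) {
  if (!inherits(counts, "look_counts")) counts <- look_counts(counts)
  nu <- as_nuisance(model)
  K <- counts$K
  if (nu$K != K) stop("model has K = ", nu$K, " endpoints, counts have K = ", K)
  check_corr(nu$corr_hat, K)
  N <- effective_n(counts)
  if (N[K] <= 0)
    stop("no information: no participants with the final endpoint in both arms")
  sig <- nu$sigma_hats
  R <- nu$corr_hat
  base <- 2 * sig[K]^2 / N[K]
  if (K == 3L) {
    bracket <- 1 - R[1, 3]^2 * (N[1] - N[3]) / N[1] -
      R[2, 3]^2 * (N[2] - N[3]) / N[2] +
      2 * R[1, 3] * R[2, 3] * R[1, 2] * (1 - N[3] / N[2])
    if (bracket <= 0) {
      warning("variance bracket non-positive after clamping; flooring")
      bracket <- 1e-8
    }
    return(base * bracket)
  }
  v <- varB_general(N, sig, R)
  if (v <= 0) {
    warning("variance non-positive after clamping; flooring")
    v <- 1e-8 * base
  }
  v
}

# exact variance of the augmented estimator for monotone counts N (per arm,
# effective), via the per-participant weight decomposition:
#   B = dbar_K(completers) + sum_k a_k f_k (dbar_k(pending) - dbar_k(completers))
varB_general <- function(N, sig, R) {
  K <- length(N)
  Sd <- 2 * (sig %o% sig) * R            # covariance of paired differences
  a <- R[seq_len(K - 1), K] * sig[K] / sig[seq_len(K - 1)]
  f <- (N[seq_len(K - 1)] - N[K]) / N[seq_len(K - 1)]
  wC <- c(-a * f, 1) / N[K]              # completers' weight vector
  v <- N[K] * drop(t(wC) %*% Sd %*% wC)
  for (m in seq_len(K - 1)) {            # layer observed up to endpoint m only
    cm <- N[m] - N[m + 1]
    if (cm <= 0) next
    wm <- numeric(K)
    wm[1:m] <- a[1:m] * f[1:m] / (N[1:m] - N[K])
    v <- v + cm * drop(t(wm) %*% Sd %*% wm)
  }
  v
}

#' Expected information at a planned look
#'
#' Information is inverse variance: `1 / var(B)` evaluated with the design's
#' assumed (not estimated) nuisance parameters at the planned counts. At the
#' final analysis every participant has the long-term outcome and the
#' information is \eqn{N / (2\sigma_K^2)} for N per arm.
#'
#' @inheritParams treatment_effect_variance
#' @return Expected information (inverse-variance units).
#' @export
expected_information <- function(counts, model) {
  1 / treatment_effect_variance(counts, model)
}

#' Information at the final analysis
#' @param n_per_arm Participants per arm analysed at the final look.
#' @param sigma Standard deviation of the long-term outcome.
#' @return \eqn{n / (2\sigma^2)}.
#' @export
final_information <- function(n_per_arm, sigma) {
  stopifnot(n_per_arm > 0, sigma > 0)
  n_per_arm / (2 * sigma^2)
}

#' Information fraction of a look
#'
#' @param look_info Information at the look.
#' @param final_info Information at the final analysis (> 0).
#' @param percent Report as a percentage (default TRUE, as printed in design
#'   summaries).
#' @return `look_info / final_info` (x100 if `percent`). A fraction above 1
#'   (information overshoot) triggers a warning, not an error.
#' @export
information_fraction <- function(look_info, final_info, percent = TRUE) {
  if (any(final_info <= 0)) stop("'final_info' must be > 0")
  fr <- look_info / final_info
  if (any(fr > 1 + 1e-12))
    warning("look information exceeds final information (overshoot)")
  if (percent) 100 * fr else fr
}

#' Fixed-design sample size for a two-arm normal comparison
#'
#' Normal-approximation two-sample formula
#' \eqn{n = 2\sigma^2 (z_{1-\alpha/2} + z_{power})^2 / \delta^2}, rounded up
#' per group. With the 10-point minimum clinically important difference and
#' SD 20 at 90% power, 5% two-sided, this gives 85 per group (170 total).
#'
#' @param delta Target treatment difference (non-zero).
#' @param sigma Outcome standard deviation (> 0).
#' @param power Desired power, in (0, 1). Default 0.9.
#' @param alpha_two_sided Two-sided type I error rate. Default 0.05.
#' @return List with `n_per_group` and `n_total`.
#' @export
fixed_design_sample_size <- function(delta, sigma, power = 0.9,
                                     alpha_two_sided = 0.05) {
  if (delta == 0) stop("'delta' must be non-zero")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  if (alpha_two_sided <= 0 || alpha_two_sided >= 1)
    stop("'alpha_two_sided' must be in (0, 1)")
  z <- stats::qnorm(1 - alpha_two_sided / 2) + stats::qnorm(power)
  n <- as.integer(ceiling(2 * sigma^2 * z^2 / delta^2))
  list(n_per_group = n, n_total = 2L * n)
}
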