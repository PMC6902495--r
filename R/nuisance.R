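#' Nuisance-parameter estimate
#'
#' Container for estimated per-endpoint standard deviations and the endpoint
#' correlation matrix, as used by the augmented effect estimator. Usually
#' produced by [estimate_nuisance()]; construct directly to inject known
#' values.
#'
#' @param sigma_hats Length-K vector of positive SDs.
#' @param corr_hat K x K correlation matrix (entries clamped to
#'   \[-0.99, 0.99\] off the diagonal and PSD-repaired if needed).
#' @param n_pairs Optional K x K matrix of pairwise-complete sample sizes.
#' @return Object of class `nuisance_estimate`.
#' @export
nuisance_estimate <- function(sigma_hats, corr_hat, n_pairs = NULL) {
  sigma_hats <- as.numeric(sigma_hats)
  K <- length(sigma_hats)
  if (any(!is.finite(sigma_hats)) || any(sigma_hats <= 0))
    stop("'sigma_hats' must be finite and > 0")
  corr_hat <- clamp_corr(unname(corr_hat), 0.99)
  corr_hat <- repair_psd(corr_hat)
  check_corr(corr_hat, K)
  structure(list(K = K, sigma_hats = sigma_hats, corr_hat = corr_hat,
                 n_pairs = n_pairs),
            class = "nuisance_estimate")
}

# accept either a nuisance_estimate or an endpoint_model wherever sigmas +
# correlations are needed
as_nuisance <- function(x) {
  if (inherits(x, "nuisance_estimate")) return(x)
  if (inherits(x, "endpoint_model"))
    return(structure(list(K = x$K, sigma_hats = x$sigmas, corr_hat = x$corr,
                          n_pairs = NULL),
                     class = "nuisance_estimate"))
  stop("expected a nuisance_estimate or endpoint_model")
}

clamp_corr <- function(R, limit = 0.99) {
  off <- row(R) != col(R)
  R[off] <- pmin(pmax(R[off], -limit), limit)
  R
}

# nearest-PSD repair by eigenvalue clipping; rescale back to unit diagonal
repair_psd <- function(R, floor = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return((R + t(R)) / 2)
  v <- pmax(e$values, floor)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / (d %o% d)
  diag(M) <- 1
  (M + t(M)) / 2
}

#' Estimate nuisance parameters from observed trial data
#'
#' Per-endpoint SDs are pooled across arms from arm-mean-centred residuals
#' (denominator `n - 2`, two arm means estimated); correlations are Pearson
#' correlations of arm-centred residuals over pairwise-complete observations,
#' pooled across arms. Estimates are clamped to \[-0.99, 0.99\] and the matrix
#' PSD-repaired so the variance formula stays positive and finite. Arm-centring
#' removes any treatment effect, so arms with different means but a common
#' residual structure give the same estimates as pooled single-group data.
#'
#' @param data A [trial_dataset()] (restricted to a calendar time if interim).
#' @param fallback Optional [endpoint_model()] supplying design-assumed values
#'   for quantities that cannot be estimated (an SD with fewer than 3
#'   observations, a correlation with fewer than `min_pairs` complete pairs).
#'   Without a fallback these are errors.
#' @param min_pairs Minimum pairwise-complete observations to estimate a
#'   correlation (default 3).
#' @param warn Warn when a fallback value is used (default TRUE; the
#'   simulator silences this).
#' @return A [nuisance_estimate()].
#' @export
estimate_nuisance <- function(data, fallback = NULL, min_pairs = 3,
                              warn = TRUE) {
  stopifnot(inherits(data, "trial_dataset"))
  cols <- dataset_outcols(data)
  K <- length(cols)
  if (!is.null(fallback)) {
    fb <- as_nuisance(fallback)
    if (fb$K != K) stop("fallback model has wrong number of endpoints")
  }
  arm <- data$arm

  centred <- matrix(NA_real_, nrow(data), K)
  sigma_hats <- numeric(K)
  for (k in seq_len(K)) {
    v <- data[[cols[k]]]
    for (a in 0:1) {
      sel <- arm == a & !is.na(v)
      if (any(sel)) centred[sel, k] <- v[sel] - mean(v[sel])
    }
    n_k <- sum(!is.na(v))
    if (n_k >= 3) {
      sigma_hats[k] <- sqrt(sum(centred[, k]^2, na.rm = TRUE) / (n_k - 2))
    } else if (!is.null(fallback)) {
      if (warn) warning("fewer than 3 observations for endpoint ", k,
                        "; using design-assumed SD")
      sigma_hats[k] <- fb$sigma_hats[k]
    } else {
      stop("cannot estimate SD of endpoint ", k, ": fewer than 3 observations")
    }
    if (sigma_hats[k] <= 0) {
      if (is.null(fallback))
        stop("degenerate (zero) SD estimate for endpoint ", k)
      if (warn) warning("degenerate SD for endpoint ", k,
                        "; using design-assumed SD")
      sigma_hats[k] <- fb$sigma_hats[k]
    }
  }

  corr_hat <- diag(K)
  n_pairs <- matrix(nrow(data), K, K)
  for (k in seq_len(K - 1)) {
    for (j in (k + 1):K) {
      ok <- !is.na(centred[, k]) & !is.na(centred[, j])
      n_pairs[k, j] <- n_pairs[j, k] <- sum(ok)
      if (sum(ok) >= min_pairs) {
        sxx <- sum(centred[ok, k]^2)
        syy <- sum(centred[ok, j]^2)
        sxy <- sum(centred[ok, k] * centred[ok, j])
        r <- if (sxx > 0 && syy > 0) sxy / sqrt(sxx * syy) else NA_real_
      } else {
        r <- NA_real_
      }
      if (is.na(r)) {
        if (is.null(fallback))
          stop("cannot estimate correlation between endpoints ", k, " and ", j,
               ": fewer than ", min_pairs, " complete pairs")
        if (warn) warning("correlation (", k, ",", j,
                          ") inestimable; using design-assumed value")
        r <- fb$corr_hat[k, j]
      }
      corr_hat[k, j] <- corr_hat[j, k] <- r
    }
  }
  nuisance_estimate(sigma_hats, corr_hat, n_pairs)
}

#' @export
print.nuisance_estimate <- function(x, ...) {
  cat("Nuisance estimate for", x$K, "endpoints\n")
  cat("  sigma_hats:", paste(format(x$sigma_hats, digits = 4), collapse = ", "), "\n")
  cat("  correlations (upper triangle):",
      paste(format(x$corr_hat[upper.tri(x$corr_hat)], digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}
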