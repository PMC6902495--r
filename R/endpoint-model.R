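#' Multivariate-normal endpoint model
#'
#' Describes the joint distribution of the K repeated measurements of the
#' primary outcome (K-1 early endpoints plus the definitive long-term
#' endpoint, which always has index K). Outcomes for a participant are
#' multivariate normal with arm-specific means, common standard deviations
#' `sigmas` and correlation matrix `corr`.
#'
#' @param sigmas Numeric vector of per-endpoint standard deviations
#'   (outcome-score units), length K; all strictly positive.
#' @param corr K x K correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite). A scalar is expanded to a uniform (exchangeable)
#'   correlation matrix.
#' @param means_control,means_active Per-endpoint mean vectors (length K).
#'   Defaults are zero vectors.
#'
#' @return An object of class `endpoint_model` with elements `K`, `sigmas`,
#'   `corr`, `means_control`, `means_active`.
#' @examples
#' # the design assumptions used for the shoulder-score exemplar:
#' endpoint_model(sigmas = rep(20, 3), corr = 0.5)
#' @export
endpoint_model <- function(sigmas, corr,
                           means_control = numeric(length(sigmas)),
                           means_active = numeric(length(sigmas))) {
  sigmas <- as.numeric(sigmas)
  K <- length(sigmas)
  if (K < 2L) stop("an endpoint model needs at least 2 endpoints (K >= 2)")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("'sigmas' must be finite and strictly positive")
  if (is.matrix(corr)) {
    corr <- unname(corr)
  } else if (length(corr) == 1L) {
    corr <- uniform_corr(K, corr)
  } else {
    stop("'corr' must be a K x K matrix or a single uniform correlation")
  }
  check_corr(corr, K)
  means_control <- as.numeric(means_control)
  means_active <- as.numeric(means_active)
  if (length(means_control) != K || length(means_active) != K)
    stop("mean vectors must have length K = ", K)
  if (any(!is.finite(c(means_control, means_active))))
    stop("mean vectors must be finite")
  structure(
    list(K = K, sigmas = sigmas, corr = corr,
         means_control = means_control, means_active = means_active),
    class = "endpoint_model"
  )
}

#' Exchangeable correlation matrix
#'
#' @param K Number of endpoints.
#' @param rho Common pairwise correlation.
#' @return A K x K correlation matrix with `rho` off the diagonal.
#' @export
uniform_corr <- function(K, rho) {
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  m <- matrix(rho, K, K)
  diag(m) <- 1
  m
}

check_corr <- function(corr, K, tol = 1e-8) {
  if (!is.numeric(corr) || !identical(dim(corr), c(K, K)))
    stop("correlation matrix must be numeric and ", K, " x ", K)
  if (any(!is.finite(corr))) stop("correlation matrix has non-finite entries")
  if (max(abs(corr - t(corr))) > tol) stop("correlation matrix is not symmetric")
  if (max(abs(diag(corr) - 1)) > tol) stop("correlation matrix diagonal must be 1")
  if (max(abs(corr)) > 1 + tol) stop("correlations must satisfy |rho| <= 1")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, abs(ev[1])))
    stop("correlation matrix is not positive semi-definite")
  invisible(corr)
}

#' Covariance matrix implied by an endpoint model
#' @param model An [endpoint_model()].
#' @return K x K covariance matrix.
#' @export
model_covariance <- function(model) {
  stopifnot(inherits(model, "endpoint_model"))
  (model$sigmas %o% model$sigmas) * model$corr
}

#' @export
print.endpoint_model <- function(x, ...) {
  cat("Endpoint model:", x$K, "endpoints\n")
  cat("  sigmas:", paste(format(x$sigmas), collapse = ", "), "\n")
  cat("  correlations (upper triangle):",
      paste(format(x$corr[upper.tri(x$corr)], digits = 3), collapse = ", "), "\n")
  cat("  mean difference (active - control):",
      paste(format(x$means_active - x$means_control), collapse = ", "), "\n")
  invisible(x)
}

#' Per-arm observed counts at a look
#'
#' Numbers of participants with each endpoint observed, per arm, at some
#' calendar time. Because follow-up is ordered, earlier endpoints are always
#' observed on at least as many participants: `n[k, arm] >= n[k + 1, arm]`.
#'
#' @param n Either a length-K vector (equal per-arm counts) or a K x 2 matrix
#'   with columns (control, active).
#' @param randomised Optional total randomised per arm (length 2), at least
#'   the column maxima of `n`.
#' @return Object of class `look_counts`: list with `n` (K x 2 integer-valued
#'   matrix), `K` and `randomised`.
#' @examples
#' look_counts(c(20, 15, 10))       # worked-example first look, per arm
#' @export
look_counts <- function(n, randomised = NULL) {
  if (is.matrix(n)) {
    if (ncol(n) != 2L) stop("'n' matrix must have 2 columns (control, active)")
  } else {
    n <- cbind(n, n)
  }
  n <- unname(n) * 1.0
  if (any(!is.finite(n)) || any(n < 0)) stop("counts must be finite and >= 0")
  K <- nrow(n)
  if (K < 2L) stop("need counts for at least 2 endpoints")
  if (any(diff(n[, 1]) > 0) || any(diff(n[, 2]) > 0))
    stop("counts must be non-increasing across endpoints (N_1 >= ... >= N_K)")
  if (!is.null(randomised)) {
    randomised <- as.numeric(randomised)
    if (length(randomised) != 2L || any(randomised < n[1, ]))
      stop("'randomised' must be length 2 and at least the endpoint-1 counts")
  }
  structure(list(n = n, K = K, randomised = randomised), class = "look_counts")
}

# harmonic-mean effective per-arm sample size for each endpoint;
# 0 whenever either arm contributes nothing
effective_n <- function(counts) {
  n <- counts$n
  tot <- n[, 1] + n[, 2]
  ifelse(tot > 0, 2 * n[, 1] * n[, 2] / pmax(tot, 1), 0)
}

#' @export
print.look_counts <- function(x, ...) {
  m <- x$n
  dimnames(m) <- list(paste0("endpoint_", seq_len(x$K)), c("control", "active"))
  cat("Observed per-arm counts at look:\n")
  print(m)
  invisible(x)
}
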