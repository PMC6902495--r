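#' Error-spending plan
#'
#' Cumulative type I error spending across the W analyses of a one-sided
#' group-sequential test with futility stopping: `alphaU_cum[w]` is the
#' cumulative probability (under H0, binding rules) of stopping and rejecting
#' by analysis w (efficacy), `alphaL_cum[w]` of stopping without rejecting
#' (futility). At the final analysis these must reach `alpha` and `1 - alpha`
#' so the decision partition is exhaustive.
#'
#' @param alphaL,alphaU Lower (futility) and upper (efficacy) spending
#'   vectors, length W. Cumulative by default.
#' @param alpha Overall one-sided level (default 0.025).
#' @param cumulative If FALSE, the vectors are per-look increments and are
#'   cumulated here.
#' @return Object of class `spending_plan`: `W`, `alphaL_cum`, `alphaU_cum`,
#'   `alpha`.
#' @examples
#' spending_plan(c(0.200, 0.600, 0.975), c(0.000, 0.001, 0.025))
#' @export
spending_plan <- function(alphaL, alphaU, alpha = 0.025, cumulative = TRUE) {
  alphaL <- as.numeric(alphaL)
  alphaU <- as.numeric(alphaU)
  if (length(alphaL) != length(alphaU))
    stop("spending vectors must have equal length")
  if (!cumulative) {
    if (any(alphaL < 0) || any(alphaU < 0))
      stop("spending increments must be >= 0")
    if (sum(alphaL) > 1 || sum(alphaU) > 1)
      stop("spending increments must not sum above 1")
    alphaL <- cumsum(alphaL)
    alphaU <- cumsum(alphaU)
  }
  plan <- structure(list(W = length(alphaL), alphaL_cum = alphaL,
                         alphaU_cum = alphaU, alpha = alpha),
                    class = "spending_plan")
  validate_spending(plan)
}

#' Validate a spending plan
#'
#' Checks monotonicity, range and the final-analysis endpoints
#' (`alphaU_cum[W] = alpha`, `alphaL_cum[W] = 1 - alpha`); violations are
#' reported with the offending index.
#'
#' @param plan A [spending_plan()] (or a bare list with the same fields).
#' @return The validated plan, invisibly usable downstream.
#' @export
validate_spending <- function(plan) {
  need <- c("W", "alphaL_cum", "alphaU_cum", "alpha")
  if (!all(need %in% names(plan))) stop("not a spending plan")
  W <- plan$W
  aL <- plan$alphaL_cum
  aU <- plan$alphaU_cum
  a <- plan$alpha
  if (W < 1) stop("need at least one analysis")
  if (a <= 0 || a >= 0.5) stop("'alpha' must be in (0, 0.5)")
  for (v in list(L = aL, U = aU)) {
    if (any(v < 0 | v > 1)) stop("spending values must lie in [0, 1]; index ",
                                 which(v < 0 | v > 1)[1])
  }
  if (any(diff(aL) < 0))
    stop("lower spending must be nondecreasing; index ", which(diff(aL) < 0)[1] + 1)
  if (any(diff(aU) < 0))
    stop("upper spending must be nondecreasing; index ", which(diff(aU) < 0)[1] + 1)
  tol <- 1e-9
  if (abs(aU[W] - a) > tol)
    stop("upper spending must end at alpha = ", a, " (got ", aU[W], ")")
  if (abs(aL[W] - (1 - a)) > tol)
    stop("lower spending must end at 1 - alpha = ", 1 - a, " (got ", aL[W], ")")
  if (!inherits(plan, "spending_plan")) class(plan) <- "spending_plan"
  plan
}

spending_increments <- function(plan) {
  list(lower = diff(c(0, plan$alphaL_cum)), upper = diff(c(0, plan$alphaU_cum)))
}

#' Planned information schedule
#'
#' @param info Strictly increasing, positive information levels (inverse
#'   variance of the effect estimate) at each of the W analyses, the last
#'   being the final analysis. May also be given as fractions of
#'   `final_info`.
#' @param final_info Optional final-analysis information by which fractional
#'   `info` is scaled.
#' @return Object of class `information_schedule` with element `info`.
#' @export
information_schedule <- function(info, final_info = NULL) {
  info <- as.numeric(info)
  if (!is.null(final_info)) info <- info * final_info
  if (any(!is.finite(info)) || any(info <= 0))
    stop("information levels must be finite and > 0")
  if (any(diff(info) <= 0))
    stop("information must be strictly increasing across analyses")
  structure(list(info = info, W = length(info)), class = "information_schedule")
}

#' Group-sequential stopping boundaries from error spending
#'
#' Computes the lower (futility) and upper (efficacy) z-scale boundaries
#' l_w, u_w at each analysis so that, under H0, the probability of first
#' crossing at analysis w equals the corresponding spending increment. The
#' sequential z-statistics follow the canonical joint distribution
#' \eqn{\mathrm{Cov}(S_v, S_w) = \sqrt{I_v / I_w}}; probabilities are
#' evaluated by the standard stagewise recursion, propagating the sub-density
#' of the non-stopped score statistic on a Simpson grid, with boundary values
#' found by root bracketing. A zero spending increment yields an infinite
#' boundary; at the final analysis the two boundaries coincide
#' (`l_W = u_W`, solved from the remaining upper spending).
#'
#' With `binding = TRUE` (default) the futility boundaries are binding: the
#' recursion conditions on not having crossed either boundary, and type I
#' error control relies on stopping whenever the futility boundary is
#' crossed. With `binding = FALSE` the upper boundaries are computed ignoring
#' the lower ones (error control holds even if futility stops are
#' overridden); lower boundaries then spend the futility probability given
#' those upper boundaries.
#'
#' @param plan A [spending_plan()].
#' @param schedule An [information_schedule()] with the same W.
#' @param binding Binding futility rule (default TRUE).
#' @param n_grid Simpson nodes per stage (odd, >= 301; default 501).
#' @return Object of class `boundary_set`: `lower`, `upper` (z-scale, with
#'   +/-Inf sentinels), `info`, `plan`, `binding`, and `diagnostics` (implied
#'   final lower spending mismatch).
#' @examples
#' plan <- spending_plan(c(0.200, 0.600, 0.975), c(0.000, 0.001, 0.025))
#' sched <- information_schedule(c(0.019, 0.028, 0.046))
#' compute_boundaries(plan, sched)
#' @export
compute_boundaries <- function(plan, schedule, binding = TRUE, n_grid = 501) {
  plan <- validate_spending(plan)
  if (!inherits(schedule, "information_schedule"))
    schedule <- information_schedule(schedule)
  if (schedule$W != plan$W)
    stop("plan has ", plan$W, " analyses but schedule has ", schedule$W)
  info <- schedule$info
  W <- plan$W
  inc <- spending_increments(plan)

  if (binding) {
    sol <- gs_solve(inc$lower, inc$upper, info, n_grid)
    lower <- sol$lower
    upper <- sol$upper
    diag_mismatch <- sol$final_lower_mismatch
  } else {
    # upper boundaries ignore futility stopping entirely
    up <- gs_solve(rep(0, W), inc$upper, info, n_grid)
    # futility boundaries spend alphaL given those upper boundaries
    lo <- gs_solve(inc$lower, inc$upper, info, n_grid,
                   fixed_upper = up$upper)
    lower <- lo$lower
    upper <- up$upper
    lower[W] <- upper[W]
    diag_mismatch <- lo$final_lower_mismatch
  }
  if (abs(diag_mismatch) > 1e-4)
    warning(sprintf(paste0("implied lower spending at the final analysis ",
                           "misses 1 - alpha by %.2g"), diag_mismatch))
  structure(list(lower = lower, upper = upper, info = info, plan = plan,
                 binding = binding,
                 diagnostics = list(final_lower_mismatch = diag_mismatch,
                                    n_grid = n_grid)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  W <- length(x$lower)
  df <- data.frame(analysis = seq_len(W), info = x$info,
                   lower = round(x$lower, 4), upper = round(x$upper, 4))
  cat("Group-sequential boundaries (",
      if (x$binding) "binding" else "non-binding", " futility):\n", sep = "")
  print(df, row.names = FALSE)
  invisible(x)
}

# Simpson quadrature weights for an odd-length uniform grid
simpson_weights <- function(n, h) {
  if (n %% 2 == 0) stop("Simpson rule needs an odd number of nodes")
  w <- rep(c(4, 2), length.out = n - 2)
  h / 3 * c(1, w, 1)
}

# Stagewise boundary solver on the score scale T_w = S_w * sqrt(I_w)
# (independent increments under H0: T_w - T_{w-1} ~ N(0, dI)).
# piL/piU: spending increments; fixed_upper: use these upper z-boundaries
# instead of solving for them (non-binding lower pass).
gs_solve <- function(piL, piU, info, n_grid = 501, fixed_upper = NULL) {
  W <- length(info)
  span <- 8
  lower <- upper <- numeric(W)
  lower[1] <- if (piL[1] > 0) stats::qnorm(piL[1]) else -Inf
  upper[1] <- if (!is.null(fixed_upper)) fixed_upper[1]
              else if (piU[1] > 0) stats::qnorm(1 - piU[1]) else Inf
  if (W == 1) {
    u <- if (!is.null(fixed_upper)) fixed_upper[1] else stats::qnorm(1 - piU[1])
    return(list(lower = u, upper = u,
                final_lower_mismatch = stats::pnorm(u) - piL[1]))
  }

  grid_state <- function(lz, uz, w) {
    sI <- sqrt(info[w])
    lo <- max(lz * sI, -span * sI)
    hi <- min(uz * sI, span * sI)
    if (hi <= lo) stop("empty continuation region at analysis ", w,
                       " (lower >= upper)")
    t <- seq(lo, hi, length.out = n_grid)
    list(t = t, wts = simpson_weights(n_grid, t[2] - t[1]))
  }

  g <- grid_state(lower[1], upper[1], 1)
  h <- stats::dnorm(g$t, 0, sqrt(info[1])) * g$wts
  t <- g$t

  mismatch <- NA_real_
  for (w in 2:W) {
    dI <- info[w] - info[w - 1]
    sD <- sqrt(dI)
    sI <- sqrt(info[w])
    p_low <- function(Lz) sum(h * stats::pnorm((Lz * sI - t) / sD))
    p_up <- function(Uz) sum(h * stats::pnorm((Uz * sI - t) / sD,
                                              lower.tail = FALSE))
    solve_bound <- function(fn, target, increasing) {
      f <- function(z) fn(z) - target
      lo <- -span; hi <- span
      flo <- f(lo); fhi <- f(hi)
      if (flo * fhi > 0)
        stop("boundary root not bracketed at analysis ", w,
             " (target ", signif(target, 6), ", f(", lo, ") = ",
             signif(flo, 6), ", f(", hi, ") = ", signif(fhi, 6), ")")
      stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    }
    if (w < W) {
      lower[w] <- if (piL[w] > 0) solve_bound(p_low, piL[w]) else -Inf
      upper[w] <- if (!is.null(fixed_upper)) fixed_upper[w]
                  else if (piU[w] > 0) solve_bound(p_up, piU[w]) else Inf
      g <- grid_state(lower[w], upper[w], w)
      h <- as.vector(stats::dnorm(outer(g$t, t, "-"), 0, sD) %*% h) * g$wts
      t <- g$t
    } else {
      u <- if (!is.null(fixed_upper)) fixed_upper[w] else solve_bound(p_up, piU[w])
      upper[w] <- u
      lower[w] <- u
      mismatch <- p_low(u) - piL[w]
    }
  }
  list(lower = lower, upper = upper, final_lower_mismatch = mismatch)
}

#' Crossing probabilities of a boundary set
#'
#' Evaluates, for a given drift, the probability of first crossing the lower
#' and upper boundaries at each analysis, by the same stagewise recursion
#' used to construct the boundaries. The drift model is the canonical one:
#' `E[S_w] = theta * sqrt(I_w)` where `theta` is the raw treatment
#' difference. At `theta = 0` the probabilities reproduce the spending
#' increments the boundaries were built from; the probabilities over all
#' analyses and both sides always sum to 1 (the final analysis partitions
#' whatever mass remains).
#'
#' @param bounds A [boundary_set()] from [compute_boundaries()], or a list
#'   with `lower`, `upper` and (if `schedule` is missing) `info`.
#' @param schedule Optional [information_schedule()]; defaults to the one
#'   stored in `bounds`.
#' @param theta Drift (treatment difference), scalar.
#' @param n_grid Simpson nodes per stage (default 501).
#' @return List with `lower`, `upper` (first-crossing probabilities per
#'   analysis), `total_upper` (= power at this drift) and `theta`.
#' @export
crossing_probabilities <- function(bounds, schedule = NULL, theta = 0,
                                   n_grid = 501) {
  info <- if (!is.null(schedule)) {
    if (!inherits(schedule, "information_schedule"))
      schedule <- information_schedule(schedule)
    schedule$info
  } else bounds$info
  if (is.null(info)) stop("no information schedule available")
  lower <- bounds$lower
  upper <- bounds$upper
  W <- length(info)
  if (length(lower) != W || length(upper) != W)
    stop("boundary vectors must match the schedule length")
  if (any(lower[-W] >= upper[-W]))
    stop("lower boundary must be below upper boundary before the final analysis")
  span <- 8
  pL <- pU <- numeric(W)

  sI1 <- sqrt(info[1])
  mu1 <- theta * info[1]                # score-scale mean at analysis 1
  pL[1] <- stats::pnorm(lower[1] * sI1, mu1, sI1)
  pU[1] <- stats::pnorm(upper[1] * sI1, mu1, sI1, lower.tail = FALSE)
  if (W == 1) {
    return(list(lower = pL, upper = pU, total_upper = sum(pU), theta = theta))
  }
  lo <- max(lower[1] * sI1, mu1 - span * sI1)
  hi <- min(upper[1] * sI1, mu1 + span * sI1)
  t <- seq(lo, hi, length.out = n_grid)
  h <- stats::dnorm(t, mu1, sI1) * simpson_weights(n_grid, t[2] - t[1])

  for (w in 2:W) {
    dI <- info[w] - info[w - 1]
    sD <- sqrt(dI)
    sI <- sqrt(info[w])
    muD <- theta * dI
    pL[w] <- sum(h * stats::pnorm((lower[w] * sI - t - muD) / sD))
    pU[w] <- sum(h * stats::pnorm((upper[w] * sI - t - muD) / sD,
                                  lower.tail = FALSE))
    if (w < W) {
      mu_w <- theta * info[w]
      lo <- max(lower[w] * sI, mu_w - span * sI)
      hi <- min(upper[w] * sI, mu_w + span * sI)
      t2 <- seq(lo, hi, length.out = n_grid)
      h <- as.vector(stats::dnorm(outer(t2, t, "-"), muD, sD) %*% h) *
        simpson_weights(n_grid, t2[2] - t2[1])
      t <- t2
    }
  }
  list(lower = pL, upper = pU, total_upper = sum(pU), theta = theta)
}
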