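#' Multicentre recruitment schedule
#'
#' Staggered-opening multicentre recruitment: `centres_by_month[m]` centres
#' are open in month m, each recruiting at a constant Poisson rate. The
#' default is the motivating shoulder-surgery trial's ramp: 1, 2, 3, 6, 9,
#' 12 then 15 centres from month 7 of a 24-month recruitment window, giving
#' 303 centre-months; at 0.56 participants/centre/month this averages the
#' 170-participant fixed-design target. Recruitment continues at the plateau
#' beyond the window if the cap has not been reached.
#'
#' @param centres_by_month Open centres per month (nonnegative, nondecreasing
#'   to a plateau).
#' @param rate Recruitment rate per centre per month (>= 0).
#' @param cap Total participants recruited (recruitment stops at the cap).
#'   May be `Inf` for uncapped simulation.
#' @return Object of class `recruitment_schedule` with fields
#'   `centres_by_month`, `rate`, `cap`, `horizon`, `centre_months`.
#' @export
recruitment_schedule <- function(centres_by_month = c(1, 2, 3, 6, 9, 12,
                                                      rep(15, 18)),
                                 rate = 0.56, cap = 170) {
  centres_by_month <- as.numeric(centres_by_month)
  if (any(centres_by_month < 0)) stop("centre counts must be nonnegative")
  plateau <- which.max(centres_by_month)
  if (any(diff(centres_by_month[seq_len(plateau)]) < 0))
    stop("centre counts must be nondecreasing up to the plateau")
  if (rate < 0) stop("'rate' must be >= 0")
  if (!is.infinite(cap) && (cap < 1 || cap != round(cap)))
    stop("'cap' must be a positive whole number (or Inf)")
  structure(list(centres_by_month = centres_by_month, rate = rate, cap = cap,
                 horizon = length(centres_by_month),
                 centre_months = sum(centres_by_month)),
            class = "recruitment_schedule")
}

#' @export
print.recruitment_schedule <- function(x, ...) {
  cat("Recruitment schedule:", x$horizon, "months,",
      x$centre_months, "centre-months,",
      "rate", x$rate, "per centre-month, cap", x$cap, "\n")
  invisible(x)
}

#' Simulate participant entry times
#'
#' Monthly recruitment counts are independent Poisson with mean
#' `rate x open centres`; entry times are uniform within the month.
#' Recruitment stops at the cap, continuing at the plateau centre count past
#' the scheduled horizon if needed; uncapped (`cap = Inf`) recruitment stops
#' at the horizon.
#'
#' @param schedule A [recruitment_schedule()].
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of entry times (months).
#' @export
simulate_recruitment <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "recruitment_schedule"))
  if (!is.null(seed)) set.seed(seed)
  cap <- schedule$cap
  plateau <- schedule$centres_by_month[schedule$horizon]
  entries <- numeric(0)
  m <- 0L
  repeat {
    m <- m + 1L
    centres <- if (m <= schedule$horizon) schedule$centres_by_month[m] else plateau
    if (m > schedule$horizon && (is.infinite(cap) || schedule$rate * plateau == 0))
      break
    k <- stats::rpois(1, schedule$rate * centres)
    if (k > 0) entries <- c(entries, m - 1 + sort(stats::runif(k)))
    if (length(entries) >= cap) {
      entries <- entries[seq_len(cap)]
      break
    }
    if (m > 10000L) stop("recruitment cap never reached (rate too low?)")
  }
  entries
}

# 1:1 permuted-block allocation with block size 2, keeping per-arm counts
# balanced at every moment to within one participant
permuted_block_allocation <- function(n) {
  blocks <- ceiling(n / 2)
  arm <- as.vector(vapply(seq_len(blocks), function(b) sample(c(0L, 1L)),
                          integer(2)))
  arm[seq_len(n)]
}

#' Scenario truth for simulation
#'
#' Wraps an [endpoint_model()] with a treatment difference. By default the
#' difference `delta` is applied to the final endpoint only (early-endpoint
#' means equal across arms); a length-K vector applies per-endpoint
#' differences. Because the estimator's early-endpoint terms are
#' mean-centred, operating characteristics are insensitive to early effects.
#'
#' @param model An [endpoint_model()] (means taken as the control arm's).
#' @param delta Scalar treatment difference on the final endpoint, or a
#'   length-K vector of per-endpoint differences.
#' @return An [endpoint_model()] with shifted active-arm means.
#' @export
scenario_truth <- function(model, delta = 0) {
  stopifnot(inherits(model, "endpoint_model"))
  K <- model$K
  if (length(delta) == 1L) {
    d <- numeric(K)
    d[K] <- delta
  } else if (length(delta) == K) {
    d <- as.numeric(delta)
  } else stop("'delta' must be scalar or length K = ", K)
  endpoint_model(model$sigmas, model$corr,
                 means_control = model$means_control,
                 means_active = model$means_control + d)
}

#' Simulate correlated outcomes for recruited participants
#'
#' One multivariate-normal draw per participant with arm-specific means and
#' the model's shared covariance; endpoint k becomes observable `lags[k]`
#' months after entry.
#'
#' @param truth An [endpoint_model()] (e.g. from [scenario_truth()]).
#' @param entries Entry times (months), e.g. from [simulate_recruitment()].
#' @param arms Optional 0/1 allocation; default permuted-block 1:1.
#' @param lags Observation lags (months), default `c(3, 6, 12)`.
#' @param seed Optional integer seed.
#' @return A [trial_dataset()] containing all eventual outcomes (restrict
#'   with [observe_at()] for interim views).
#' @export
simulate_outcomes <- function(truth, entries, arms = NULL,
                              lags = c(3, 6, 12), seed = NULL) {
  stopifnot(inherits(truth, "endpoint_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(entries)
  if (n < 1) stop("no participants recruited")
  if (truth$K != length(lags)) stop("'lags' must have length K = ", truth$K)
  if (is.null(arms)) arms <- permuted_block_allocation(n)
  ch <- chol(model_covariance(truth))
  X <- matrix(stats::rnorm(n * truth$K), n) %*% ch
  X <- X + rep(1, n) %o% truth$means_control +
    arms %o% (truth$means_active - truth$means_control)
  df <- data.frame(participant_id = seq_len(n), arm = arms,
                   entry_month = entries)
  cols <- paste0("outcome_", format_lag(lags))
  for (k in seq_len(truth$K)) df[[cols[k]]] <- X[, k]
  trial_dataset(df, lags = lags, outcome_cols = cols)
}

#' Group-sequential trial design
#'
#' Bundles everything fixed before the trial starts: the error-spending plan,
#' the planned per-arm counts at each early look, the final per-arm sample
#' size, the assumed endpoint model, the recruitment model and policy flags.
#' Planned information levels are computed from the assumed model at the
#' planned counts (final-analysis information \eqn{N/(2\sigma_K^2)}) and the
#' stopping boundaries are derived immediately.
#'
#' @param plan A [spending_plan()] with W = number of early looks + 1.
#' @param planned_counts Per-arm counts with each endpoint observed at each
#'   early look: a (W-1) x K matrix (rows = looks), a list of length-K
#'   vectors, or for a single look one length-K vector.
#' @param n_per_arm Final per-arm sample size N.
#' @param assumed [endpoint_model()] of design assumptions.
#' @param recruitment A [recruitment_schedule()]; default is the motivating
#'   trial's ramp with `cap = 2 * n_per_arm`.
#' @param lags Observation lags (months).
#' @param binding Binding futility boundaries (default TRUE).
#' @param looks_after_recruitment If TRUE (default, as in the design
#'   simulations) looks still happen when their information level is reached
#'   after recruitment has completed; if FALSE such looks are abandoned, as
#'   they would be in a real trial.
#' @param min_final_per_arm Minimum long-term outcomes per arm before a look
#'   can trigger (default 10). Interim looks are only contemplated once some
#'   long-term data exist: below this, the variance estimate entering the
#'   observed information has so few degrees of freedom that spurious
#'   information crossings would schedule meaningless analyses.
#' @param trigger_cadence When trigger crossings are checked: `"final"`
#'   (default) at each new long-term outcome arrival, the moments at which
#'   information moves materially and a monitoring committee would check;
#'   `"any"` at every outcome arrival of any endpoint. The information path
#'   itself is recomputed at every outcome arrival in both modes.
#' @param scheduling_sd SD estimate used in the *monitored* (look-scheduling)
#'   information: `"pooled"` pools arm-centred residuals of all K endpoints
#'   into one common SD (the efficient choice when the design assumes equal
#'   SDs, and the default under `"auto"` whenever it does); `"per_endpoint"`
#'   uses the final endpoint's own SD. The analysis statistic S always uses
#'   the per-endpoint estimates. See the methods vignette for why scheduling
#'   must not chase the sampling noise of a low-df variance estimate.
#' @param n_grid Simpson nodes for the boundary recursion.
#' @return Object of class `trial_design` with the derived
#'   `information_schedule` and `boundary_set`.
#' @export
trial_design <- function(plan, planned_counts, n_per_arm, assumed,
                         recruitment = NULL, lags = c(3, 6, 12),
                         binding = TRUE, looks_after_recruitment = TRUE,
                         min_final_per_arm = 10,
                         trigger_cadence = c("final", "any"),
                         scheduling_sd = "auto", n_grid = 501) {
  trigger_cadence <- match.arg(trigger_cadence)
  plan <- validate_spending(plan)
  stopifnot(inherits(assumed, "endpoint_model"))
  K <- assumed$K
  if (length(lags) != K) stop("'lags' must have length K = ", K)
  if (is.list(planned_counts)) planned_counts <- do.call(rbind, planned_counts)
  if (!is.matrix(planned_counts)) planned_counts <- matrix(planned_counts, 1)
  W <- plan$W
  if (nrow(planned_counts) != W - 1L)
    stop("planned_counts has ", nrow(planned_counts), " looks; plan implies ",
         W - 1L)
  if (ncol(planned_counts) != K)
    stop("planned_counts must have one column per endpoint")
  if (W > 2L && any(apply(planned_counts, 2, diff) < 0))
    stop("planned counts must be nondecreasing across looks")
  if (n_per_arm < max(planned_counts))
    stop("'n_per_arm' must be at least the largest planned count")
  if (is.null(recruitment))
    recruitment <- recruitment_schedule(cap = 2 * n_per_arm)
  # counts are stored earliest endpoint first; look_counts checks N1 >= ... >= NK
  look_info <- vapply(seq_len(W - 1L), function(w)
    expected_information(look_counts(planned_counts[w, ]), assumed),
    numeric(1))
  final_info <- final_information(n_per_arm, assumed$sigmas[K])
  schedule <- information_schedule(c(look_info, final_info))
  bounds <- compute_boundaries(plan, schedule, binding = binding,
                               n_grid = n_grid)
  structure(list(plan = plan, planned_counts = planned_counts,
                 n_per_arm = n_per_arm, assumed = assumed,
                 recruitment = recruitment, lags = lags, binding = binding,
                 looks_after_recruitment = looks_after_recruitment,
                 min_final_per_arm = min_final_per_arm,
                 trigger_cadence = trigger_cadence,
                 pooled_scheduling = resolve_scheduling_sd(scheduling_sd,
                                                           assumed),
                 schedule = schedule, bounds = bounds),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  W <- x$plan$W
  cat("Group-sequential design:", W - 1, "early look(s) + final,",
      "N =", x$n_per_arm, "per arm\n")
  cat("  planned information:",
      paste(signif(x$schedule$info, 3), collapse = ", "), "\n")
  print(x$bounds)
  invisible(x)
}

#' Simulate one trial under a design
#'
#' Emulates the trial as it would unfold: Poisson recruitment, permuted-block
#' allocation, multivariate-normal outcomes arriving at their lags, nuisance
#' parameters re-estimated at every outcome arrival, looks triggered the
#' first time observed information reaches each planned level, decisions
#' against the pre-computed boundaries, and (absent an early stop) the final
#' analysis once all long-term outcomes are in.
#'
#' @param design A [trial_design()].
#' @param truth An [endpoint_model()] (e.g. [scenario_truth()]).
#' @param seed Optional integer seed; the same seed reproduces the trace
#'   exactly.
#' @return Object of class `trial_trace`: data.frame `looks` (per-look time,
#'   observed information, statistic, verdict, counts, randomised),
#'   `stopped` (look index, 0 = reached final analysis), `stop_reason`,
#'   `final` (final-analysis statistic and rejection), `reject` (overall),
#'   `n_randomised` (at stop or cap), and
#'   `recruit_complete_before_last_look`.
#' @export
run_simulated_trial <- function(design, truth, seed = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "endpoint_model"))
  if (!is.null(seed)) set.seed(seed)
  entries <- simulate_recruitment(design$recruitment)
  n <- length(entries)
  arms <- permuted_block_allocation(n)
  ch <- chol(model_covariance(truth))
  K <- truth$K
  X <- matrix(stats::rnorm(n * K), n) %*% ch
  X <- X + rep(1, n) %o% truth$means_control +
    arms %o% (truth$means_active - truth$means_control)

  eng <- info_engine_build(entries, arms, X, design$lags, design$assumed)
  nu <- info_engine_nuisance(eng, eng$events)
  info <- info_engine_information(eng, nu)
  info_trig <- trigger_information(eng, nu, design$pooled_scheduling)
  recruit_complete <- max(entries)

  W <- design$plan$W
  bounds <- design$bounds
  looks <- data.frame(look = seq_len(W - 1L), time = NA_real_,
                      info = NA_real_, S = NA_real_,
                      lower = bounds$lower[seq_len(W - 1L)],
                      upper = bounds$upper[seq_len(W - 1L)],
                      verdict = NA_character_, n3_control = NA_real_,
                      n3_active = NA_real_, randomised = NA_real_,
                      reached = FALSE)
  stopped <- 0L
  stop_reason <- NA_character_
  prev_idx <- 0L
  last_look_time <- NA_real_
  # looks are only contemplated once both arms have some long-term data
  eligible <- nu$idx[[1]][, K] >= design$min_final_per_arm &
    nu$idx[[2]][, K] >= design$min_final_per_arm
  if (identical(design$trigger_cadence, "final"))
    eligible <- eligible & eng$final_arrival
  for (w in seq_len(W - 1L)) {
    idx <- which(info_trig >= design$schedule$info[w] & eligible)
    idx <- idx[idx > prev_idx]
    if (!length(idx)) break                   # information never reached
    i <- idx[1]
    t_w <- eng$events[i]
    if (!design$looks_after_recruitment && t_w > recruit_complete) break
    prev_idx <- i
    last_look_time <- t_w
    S <- info_engine_effect(eng, nu, i) * sqrt(info[i])
    verdict <- decide_verdict(S, bounds$lower[w], bounds$upper[w])
    looks$time[w] <- t_w
    looks$info[w] <- info[i]
    looks$S[w] <- S
    looks$verdict[w] <- verdict
    looks$n3_control[w] <- nu$idx[[1]][i, K]
    looks$n3_active[w] <- nu$idx[[2]][i, K]
    looks$randomised[w] <- sum(entries <= t_w)
    looks$reached[w] <- TRUE
    if (verdict != "continue") {
      stopped <- w
      stop_reason <- if (verdict == "stop_futility") "futility" else "efficacy"
      break
    }
  }

  final <- NULL
  reject <- FALSE
  if (stopped == 0L) {
    i <- length(eng$events)                   # all outcomes observed
    sig3 <- nu$sig[i, K]
    n0 <- nu$idx[[1]][i, K]; n1 <- nu$idx[[2]][i, K]
    B <- eng$arms[[2]]$cs1[n1 + 1, K] / n1 - eng$arms[[1]]$cs1[n0 + 1, K] / n0
    S_fin <- B / (sig3 * sqrt(1 / n0 + 1 / n1))
    reject <- S_fin >= bounds$upper[W]
    final <- list(S = S_fin, B = B, reject = reject)
  } else if (stop_reason == "efficacy") {
    reject <- TRUE
  }

  structure(list(
    looks = looks, stopped = stopped, stop_reason = stop_reason,
    final = final, reject = reject,
    n_randomised = if (stopped > 0L) looks$randomised[stopped] else n,
    recruit_complete_before_last_look =
      !is.na(last_look_time) && recruit_complete < last_look_time,
    n_recruited = n), class = "trial_trace")
}

#' @export
print.trial_trace <- function(x, ...) {
  cat("Simulated trial trace:\n")
  print(x$looks[, c("look", "time", "info", "S", "lower", "upper", "verdict")],
        row.names = FALSE)
  if (x$stopped > 0L) {
    cat("  stopped at look", x$stopped, "for", x$stop_reason,
        "with", x$n_randomised, "randomised\n")
  } else {
    cat(sprintf("  final analysis: S = %.3f, %s\n", x$final$S,
                if (x$reject) "reject H0" else "accept H0"))
  }
  invisible(x)
}

#' Operating characteristics by simulation
#'
#' Replicates [run_simulated_trial()] and summarises: cumulative futility
#' stopping probability per look, early-efficacy probability, final-analysis
#' rejection probability, overall power (any rejection), expected sample
#' size, and the fraction of replicates in which recruitment completed
#' before the last early look. A master seed spawns one independent
#' substream seed per replicate, recorded for exact replay.
#'
#' @param design A [trial_design()].
#' @param truth An [endpoint_model()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Optional master seed.
#' @param keep_traces Keep the individual `trial_trace` objects (default
#'   FALSE).
#' @return Object of class `operating_characteristics`.
#' @export
operating_characteristics <- function(design, truth, n_reps, seed = NULL,
                                      keep_traces = FALSE) {
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps))
    stop("'n_reps' must be a positive whole number")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  W <- design$plan$W
  stop_look <- integer(n_reps)
  stop_futility <- logical(n_reps)
  stop_efficacy <- logical(n_reps)
  reject_final <- logical(n_reps)
  n_rand <- numeric(n_reps)
  rc_before <- logical(n_reps)
  look_rand <- matrix(NA_real_, n_reps, W - 1L)   # randomised at each look
  look_n3 <- matrix(NA_real_, n_reps, W - 1L)
  traces <- if (keep_traces) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    tr <- run_simulated_trial(design, truth, seed = rep_seeds[r])
    stop_look[r] <- tr$stopped
    stop_futility[r] <- tr$stopped > 0L && tr$stop_reason == "futility"
    stop_efficacy[r] <- tr$stopped > 0L && tr$stop_reason == "efficacy"
    reject_final[r] <- tr$stopped == 0L && tr$reject
    n_rand[r] <- tr$n_randomised
    rc_before[r] <- tr$recruit_complete_before_last_look
    look_rand[r, ] <- tr$looks$randomised
    look_n3[r, ] <- (tr$looks$n3_control + tr$looks$n3_active) / 2
    if (keep_traces) traces[[r]] <- tr
  }
  p_wF <- vapply(seq_len(W - 1L), function(w)
    mean(stop_futility & stop_look <= w), numeric(1))
  p_E <- mean(stop_efficacy)
  p_12m <- mean(reject_final)
  power <- p_E + p_12m
  ess <- mean(n_rand)
  se <- function(p) sqrt(p * (1 - p) / n_reps)
  structure(list(
    p_wF = p_wF, p_E = p_E, p_12m = p_12m, power = power,
    ess = ess, ess_se = stats::sd(n_rand) / sqrt(n_reps),
    se_p_wF = se(p_wF), se_p_E = se(p_E), se_p_12m = se(p_12m),
    se_power = se(power),
    mean_randomised_by_look = colMeans(look_rand, na.rm = TRUE),
    mean_n3_by_look = colMeans(look_n3, na.rm = TRUE),
    p_stop_at_look = vapply(seq_len(W - 1L), function(w)
      mean(stop_look == w), numeric(1)),
    frac_recruit_complete_before_last_look = mean(rc_before),
    n_reps = n_reps, seed = seed, n_randomised = n_rand,
    stop_look = stop_look, traces = traces,
    design_W = W, cap = design$recruitment$cap),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("Operating characteristics (", x$n_reps, " replicates):\n", sep = "")
  cat("  cumulative futility stopping:",
      paste(sprintf("%.3f", x$p_wF), collapse = ", "), "\n")
  cat(sprintf("  early efficacy p_E = %.3f, final rejection p_12m = %.3f\n",
              x$p_E, x$p_12m))
  cat(sprintf("  overall power = %.3f (MC SE %.4f)\n", x$power, x$se_power))
  cat(sprintf("  expected sample size = %.1f (MC SE %.2f)\n", x$ess, x$ess_se))
  cat(sprintf("  recruitment complete before last look: %.1f%%\n",
              100 * x$frac_recruit_complete_before_last_look))
  invisible(x)
}

#' Expected sample size
#'
#' Two estimates from the same simulations: directly as the mean number
#' randomised per trace, and via the decomposition
#' \eqn{\mathrm{ESS} = \sum_w P(\mathrm{stop\ at\ } w)\, E[\mathrm{randomised
#' \ at\ look\ } w] + P(\mathrm{no\ stop}) \cdot 2N}. The two agree within
#' Monte-Carlo error; the decomposition is the form used when combining
#' stopping probabilities with an accrual model.
#'
#' @param oc An [operating_characteristics()] result.
#' @return List with `from_traces`, `from_probabilities` and `se`.
#' @export
expected_sample_size <- function(oc) {
  stopifnot(inherits(oc, "operating_characteristics"))
  p_stop <- oc$p_stop_at_look
  ess_formula <- sum(p_stop * oc$mean_randomised_by_look, na.rm = TRUE) +
    (1 - sum(p_stop)) * oc$cap
  list(from_traces = oc$ess, from_probabilities = ess_formula, se = oc$ess_se)
}
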