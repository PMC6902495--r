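#' Run an interim analysis on observed data
#'
#' Computes the augmented test statistic S_w = B / sd(B) from the data (with
#' nuisance parameters estimated from the same data) and compares it to the
#' pre-defined boundaries for look `w`. The decision rule is: stop for
#' futility iff `S_w < l_w`; stop for efficacy iff `S_w >= u_w`; otherwise
#' continue. Ties therefore go to efficacy at the upper boundary and to
#' continuation at the lower one, matching "less than the lower boundary" as
#' the futility trigger, and the three verdicts partition the real line.
#' Boundaries are the pre-defined ones: they are not recomputed at the
#' observed (generally slightly overshot) information.
#'
#' @param data A [trial_dataset()]; if `time` is given it is first restricted
#'   with [observe_at()].
#' @param look Look index w (1-based; must be below the final analysis).
#' @param bounds A [boundary_set()].
#' @param time Optional calendar time at which the look happens.
#' @param assumed Optional [endpoint_model()] used as fallback for
#'   inestimable nuisance parameters (see [estimate_nuisance()]).
#' @param nuisance Optional [nuisance_estimate()] to use instead of
#'   estimating from `data`.
#' @return Object of class `interim_decision`: `look`, `effect` (an
#'   `effect_summary`), `lower`, `upper`, `verdict` (one of `stop_futility`,
#'   `stop_efficacy`, `continue`) and `nuisance`.
#' @export
run_interim_analysis <- function(data, look, bounds, time = NULL,
                                 assumed = NULL, nuisance = NULL) {
  W <- length(bounds$lower)
  if (!is.numeric(look) || look < 1 || look > W)
    stop("no boundaries for look ", look, " (design has ", W, " analyses)")
  if (!is.null(time)) data <- observe_at(data, time)
  nu <- if (is.null(nuisance)) estimate_nuisance(data, fallback = assumed)
        else as_nuisance(nuisance)
  eff <- generalized_effect(data, nu)
  lw <- bounds$lower[look]
  uw <- bounds$upper[look]
  verdict <- decide_verdict(eff$S, lw, uw, final = look == W)
  structure(list(look = look, effect = eff, lower = lw, upper = uw,
                 verdict = verdict, nuisance = nu, time = time),
            class = "interim_decision")
}

# futility strictly below l; efficacy at or above u (exhaustive partition).
# At the final analysis l = u, so the verdict is reject (>= u) or accept.
decide_verdict <- function(S, l, u, final = FALSE) {
  if (S >= u) "stop_efficacy"
  else if (final || S < l) if (final) "accept_null" else "stop_futility"
  else "continue"
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("Interim analysis, look %d%s\n", x$look,
              if (!is.null(x$time)) sprintf(" (month %.2f)", x$time) else ""))
  cat(sprintf("  S = %.4f vs boundaries (l = %.4g, u = %.4g)\n",
              x$effect$S, x$lower, x$upper))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Monitor information accrual and locate look trigger times
#'
#' Recomputes the observed information 1/var(B) at every calendar event at
#' which a new outcome value becomes available (entry + lag for each
#' participant and endpoint), using nuisance parameters estimated from the
#' data observable at that moment, and returns for each planned look the
#' first event time at which the observed information reaches the planned
#' level. Looks the information never reaches are reported as `NA`
#' ("not reached"); the downstream policy (abandon or force) is the
#' caller's.
#'
#' @param data A full [trial_dataset()] (the event stream).
#' @param schedule An [information_schedule()]; only looks before the final
#'   analysis are matched unless `include_final = TRUE`.
#' @param assumed [endpoint_model()] fallback for early, data-poor estimates.
#' @param include_final Also locate the final-analysis information time.
#' @param min_final_per_arm Minimum long-term outcomes per arm before a look
#'   can trigger (default 10); see [trial_design()].
#' @param trigger_cadence `"final"` (default) checks crossings when new
#'   long-term outcomes arrive; `"any"` at every outcome arrival. See
#'   [trial_design()].
#' @param scheduling_sd SD estimate for the monitored information:
#'   `"auto"` (pooled across endpoints when the assumed model has equal SDs),
#'   `"pooled"`, or `"per_endpoint"`. See [trial_design()].
#' @return Object of class `information_monitor`: data.frame `looks` with
#'   columns `look`, `planned_info`, `time`, `observed_info`, plus the full
#'   event-level `path` (time, info, final-endpoint counts).
#' @export
monitor_information <- function(data, schedule, assumed = NULL,
                                include_final = FALSE,
                                min_final_per_arm = 10,
                                trigger_cadence = c("final", "any"),
                                scheduling_sd = "auto") {
  trigger_cadence <- match.arg(trigger_cadence)
  stopifnot(inherits(data, "trial_dataset"))
  if (!inherits(schedule, "information_schedule"))
    schedule <- information_schedule(schedule)
  path <- information_path(data, assumed, scheduling_sd = scheduling_sd)
  eligible <- path$n_final_control >= min_final_per_arm &
    path$n_final_active >= min_final_per_arm
  if (trigger_cadence == "final") eligible <- eligible & path$final_arrival
  W <- schedule$W
  n_look <- if (include_final) W else W - 1L
  res <- data.frame(look = seq_len(n_look),
                    planned_info = schedule$info[seq_len(n_look)],
                    time = NA_real_, observed_info = NA_real_)
  prev_idx <- 0L
  for (w in seq_len(n_look)) {
    idx <- which(path$info_trigger >= schedule$info[w] & eligible)
    idx <- idx[idx > prev_idx]
    if (length(idx)) {
      res$time[w] <- path$time[idx[1]]
      res$observed_info[w] <- path$info[idx[1]]
      prev_idx <- idx[1]
    }
  }
  structure(list(looks = res, path = path), class = "information_monitor")
}

#' @export
print.information_monitor <- function(x, ...) {
  cat("Information monitoring:\n")
  print(x$looks, row.names = FALSE)
  invisible(x)
}

#' Overrunning (definitive) analysis after a stop
#'
#' After an early stop, follow-up continues and the definitive analysis uses
#' all recruited participants' long-term outcomes. B and var(B) are computed
#' as at any analysis; when everyone has the final endpoint the correction
#' terms are empty and B is the plain difference of final-outcome means. The
#' two-sided p-value uses the normal reference:
#' \eqn{p = 2\Phi(-|B|/\mathrm{sd}(B))}.
#'
#' @param data A [trial_dataset()] with complete (or as complete as
#'   available) final-endpoint follow-up. Incomplete final data are analysed
#'   as available, with a warning.
#' @param assumed Optional [endpoint_model()] nuisance fallback.
#' @param nuisance Optional fixed [nuisance_estimate()].
#' @return Object of class `overrun_result`: `B`, `varB`, `p_value`,
#'   `n_per_arm`.
#' @export
overrun_analysis <- function(data, assumed = NULL, nuisance = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  cols <- dataset_outcols(data)
  final <- data[[cols[length(cols)]]]
  if (anyNA(final))
    warning("final endpoint missing for ", sum(is.na(final)),
            " participant(s); analysing available completers")
  nu <- if (is.null(nuisance)) estimate_nuisance(data, fallback = assumed)
        else as_nuisance(nuisance)
  eff <- generalized_effect(data, nu)
  p <- 2 * stats::pnorm(-abs(eff$S))
  structure(list(B = eff$B, varB = eff$varB, p_value = p,
                 n_per_arm = eff$counts$n[length(cols), ]),
            class = "overrun_result")
}

#' @export
print.overrun_result <- function(x, ...) {
  cat(sprintf("Overrunning analysis: B = %.4g, var(B) = %.4g, p = %.3f\n",
              x$B, x$varB, x$p_value))
  cat("  n per arm (control, active):", paste(x$n_per_arm, collapse = ", "), "\n")
  invisible(x)
}
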