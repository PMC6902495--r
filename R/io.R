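#' Read a trial dataset from CSV
#'
#' Comma-separated, UTF-8, header required, '.' decimal. Columns:
#' `participant_id`, `arm` (0/1), `entry_month`, then one outcome column per
#' endpoint (default `outcome_3m`, `outcome_6m`, `outcome_12m`). Empty cells
#' are missing values, never zeros. Malformed rows are reported with their
#' (data) row number.
#'
#' @param path CSV file path.
#' @param lags Observation lags matching the outcome columns.
#' @return A [trial_dataset()].
#' @export
read_dataset <- function(path, lags = c(3, 6, 12)) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, na.strings = "",
                        fileEncoding = "UTF-8")
  for (cc in grep("^outcome", names(df), value = TRUE)) {
    if (is.character(df[[cc]])) {
      bad <- which(!is.na(df[[cc]]) & is.na(suppressWarnings(as.numeric(df[[cc]]))))
      if (length(bad))
        stop("non-numeric outcome value in '", cc, "' at row ", bad[1])
      df[[cc]] <- as.numeric(df[[cc]])
    }
  }
  tryCatch(trial_dataset(df, lags = lags),
           error = function(e) stop("invalid dataset '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_dataset()]: missing outcomes become empty cells and the
#' write/read round trip reproduces the records exactly.
#'
#' @param data A [trial_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a synthetic fixture dataset
#'
#' Stands in for an interim snapshot of a real trial: exactly the requested
#' number of participants per arm with each endpoint observed, entry times
#' spaced so that a single calendar reference time reproduces those counts
#' through the observation lags, and outcomes drawn from the endpoint model.
#' Deterministic given `seed`.
#'
#' @param model An [endpoint_model()] (means give the two arms' outcome
#'   distributions).
#' @param counts Per-arm observed counts: length-K vector (equal arms) or
#'   K x 2 matrix, nonincreasing across endpoints, earliest endpoint first.
#' @param lags Observation lags (months).
#' @param seed Integer seed (required: fixtures must be reproducible).
#' @param reference_time Calendar time the snapshot represents; default
#'   `max(lags) + 1`.
#' @return A [trial_dataset()] whose observed pattern at `reference_time`
#'   matches `counts` exactly (later outcomes are NA).
#' @export
generate_fixture <- function(model, counts, lags = c(3, 6, 12), seed,
                             reference_time = max(lags) + 1) {
  stopifnot(inherits(model, "endpoint_model"))
  if (missing(seed)) stop("'seed' is required for a reproducible fixture")
  cts <- look_counts(counts)   # validates N_1 >= ... >= N_K
  if (model$K != cts$K) stop("'counts' must have one entry per endpoint")
  set.seed(seed)
  K <- model$K
  n_arm <- cts$n[1, ]          # endpoint-1 count = total per arm
  n <- sum(n_arm)
  arm <- rep(c(0L, 1L), n_arm)
  # participant p in an arm has endpoints 1..m(p) observed at reference time:
  # entry within (reference - lags[m+1], reference - lags[m]]
  entry <- numeric(n)
  pos <- 0L
  for (a in 1:2) {
    for (m in seq_len(K)) {
      n_m <- cts$n[m, a] - if (m < K) cts$n[m + 1, a] else 0
      if (n_m <= 0) next
      hi <- reference_time - lags[m]
      lo <- if (m < K) reference_time - lags[m + 1] else 0
      entry[pos + seq_len(n_m)] <- seq(lo + (hi - lo) / (n_m + 1), hi,
                                       length.out = n_m)
      pos <- pos + n_m
    }
  }
  ch <- chol(model_covariance(model))
  X <- matrix(stats::rnorm(n * K), n) %*% ch
  X <- X + rep(1, n) %o% model$means_control +
    arm %o% (model$means_active - model$means_control)
  # mask what the snapshot has not yet observed
  for (k in seq_len(K)) X[entry + lags[k] > reference_time, k] <- NA_real_
  df <- data.frame(participant_id = seq_len(n), arm = arm,
                   entry_month = round(entry, 6))
  cols <- paste0("outcome_", format_lag(lags))
  for (k in seq_len(K)) df[[cols[k]]] <- round(X[, k], 6)
  trial_dataset(df, lags = lags, outcome_cols = cols)
}

# ---- design / scenario configuration (JSON) --------------------------------

config_keys <- list(
  top = c("alpha", "spending", "looks", "n_per_arm", "model", "lags",
          "recruitment", "policy", "scenario"),
  spending = c("lower_cumulative", "upper_cumulative"),
  looks = c("counts"),
  model = c("sigmas", "correlations", "uniform_correlation", "means_control",
            "means_active"),
  recruitment = c("centres_by_month", "rate", "cap"),
  policy = c("binding", "looks_after_recruitment"),
  scenario = c("delta", "reps", "seed")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         " (unknown keys are errors, not ignored)")
  invisible(x)
}

#' Read a design (or scenario) configuration
#'
#' JSON, schema-validated; unknown keys are errors so misspelt options cannot
#' be silently ignored. See the packaged example under
#' `system.file("extdata", "worked_design.json", package = "augseq")`.
#'
#' @param path JSON file path.
#' @return List with `design` (a [trial_design()]) and, if present,
#'   `scenario` (delta, reps, seed).
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(cfg, config_keys$top, "config")
  for (part in c("spending", "looks", "model", "recruitment", "policy",
                 "scenario"))
    if (!is.null(cfg[[part]]))
      check_keys(cfg[[part]], config_keys[[part]], part)
  need <- c("spending", "looks", "n_per_arm", "model")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))

  alpha <- if (is.null(cfg$alpha)) 0.025 else cfg$alpha
  plan <- spending_plan(cfg$spending$lower_cumulative,
                        cfg$spending$upper_cumulative, alpha = alpha)
  m <- cfg$model
  corr <- if (!is.null(m$uniform_correlation)) m$uniform_correlation
          else as.matrix(m$correlations)
  K <- length(m$sigmas)
  model <- endpoint_model(
    m$sigmas, corr,
    means_control = if (is.null(m$means_control)) numeric(K) else m$means_control,
    means_active = if (is.null(m$means_active)) numeric(K) else m$means_active)
  lags <- if (is.null(cfg$lags)) c(3, 6, 12) else cfg$lags
  counts <- cfg$looks$counts
  if (is.list(counts)) counts <- do.call(rbind, counts)
  counts <- matrix(as.numeric(counts), ncol = K)
  rec <- if (is.null(cfg$recruitment)) {
    recruitment_schedule(cap = 2 * cfg$n_per_arm)
  } else {
    r <- cfg$recruitment
    recruitment_schedule(
      centres_by_month = if (is.null(r$centres_by_month))
        c(1, 2, 3, 6, 9, 12, rep(15, 18)) else r$centres_by_month,
      rate = if (is.null(r$rate)) 0.56 else r$rate,
      cap = if (is.null(r$cap)) 2 * cfg$n_per_arm else r$cap)
  }
  pol <- cfg$policy
  design <- trial_design(
    plan, counts, cfg$n_per_arm, model, recruitment = rec, lags = lags,
    binding = if (is.null(pol$binding)) TRUE else isTRUE(pol$binding),
    looks_after_recruitment = if (is.null(pol$looks_after_recruitment)) TRUE
                              else isTRUE(pol$looks_after_recruitment))
  list(design = design, scenario = cfg$scenario)
}

#' Write a boundary report as JSON
#'
#' Serialises a [boundary_set()] with its spending, increments, information
#' fractions and diagnostics. Infinite boundaries become the strings
#' `"inf"` / `"-inf"`.
#'
#' @param bounds A [boundary_set()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_boundary_report <- function(bounds, path) {
  inc <- spending_increments(bounds$plan)
  ser <- function(x) ifelse(is.finite(x), x,
                            ifelse(x > 0, "inf", "-inf"))
  report <- list(
    analyses = length(bounds$lower),
    binding = bounds$binding,
    information = bounds$info,
    information_fraction_pct =
      information_fraction(bounds$info, bounds$info[length(bounds$info)]),
    lower = as.list(ser(bounds$lower)),
    upper = as.list(ser(bounds$upper)),
    spending_lower_cumulative = bounds$plan$alphaL_cum,
    spending_upper_cumulative = bounds$plan$alphaU_cum,
    spending_lower_increments = inc$lower,
    spending_upper_increments = inc$upper,
    alpha_one_sided = bounds$plan$alpha,
    diagnostics = bounds$diagnostics)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
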