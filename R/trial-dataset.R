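#' Long-format trial dataset
#'
#' A two-arm trial dataset: one row per participant with entry time, arm and
#' the K repeated outcome measurements (NA = not observed). Endpoint k becomes
#' observable `lags[k]` months after entry, so restricting the dataset to a
#' calendar time masks outcomes whose observation time lies in the future.
#'
#' @param df data.frame with columns `participant_id`, `arm` (0 = control,
#'   1 = active), `entry_month`, and one outcome column per endpoint.
#' @param lags Observation lag in months for each endpoint, increasing
#'   (default `c(3, 6, 12)`, matching 3-, 6- and 12-month follow-up).
#' @param outcome_cols Names of the outcome columns, earliest first. Default
#'   `outcome_<lag>m` (e.g. `outcome_3m`), falling back to any columns whose
#'   name starts with "outcome".
#' @return Object of class `trial_dataset` (a data.frame with attributes
#'   `lags` and `outcome_cols`).
#' @export
trial_dataset <- function(df, lags = c(3, 6, 12), outcome_cols = NULL) {
  df <- as.data.frame(df)
  need <- c("participant_id", "arm", "entry_month")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset is missing columns: ", paste(miss, collapse = ", "))
  lags <- as.numeric(lags)
  if (any(diff(lags) <= 0)) stop("'lags' must be strictly increasing")
  if (is.null(outcome_cols)) {
    outcome_cols <- paste0("outcome_", format_lag(lags))
    if (!all(outcome_cols %in% names(df)))
      outcome_cols <- grep("^outcome", names(df), value = TRUE)
  }
  if (length(outcome_cols) != length(lags))
    stop("need one outcome column per endpoint (", length(lags), "), found ",
         length(outcome_cols))
  if (!all(outcome_cols %in% names(df)))
    stop("outcome columns not found: ",
         paste(setdiff(outcome_cols, names(df)), collapse = ", "))
  if (anyDuplicated(df$participant_id)) {
    bad <- which(duplicated(df$participant_id))[1]
    stop("duplicate participant_id at row ", bad)
  }
  bad_arm <- which(!(df$arm %in% c(0, 1)))
  if (length(bad_arm))
    stop("'arm' must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_arm, 5), collapse = ", "))
  if (any(!is.finite(df$entry_month)))
    stop("'entry_month' must be finite")
  for (cc in outcome_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) stop("outcome column '", cc, "' must be numeric")
    if (any(!is.na(v) & !is.finite(v)))
      stop("outcome column '", cc, "' has non-finite values")
  }
  structure(df, lags = lags, outcome_cols = outcome_cols,
            class = c("trial_dataset", "data.frame"))
}

format_lag <- function(lags) {
  ifelse(lags == round(lags), paste0(round(lags), "m"), paste0(lags, "m"))
}

dataset_lags <- function(data) attr(data, "lags")
dataset_outcols <- function(data) attr(data, "outcome_cols")

#' Restrict a dataset to what is observable at a calendar time
#'
#' Masks (sets to NA) every outcome whose observation time `entry_month +
#' lags[k]` exceeds `time`, and drops participants not yet recruited. This is
#' the only route by which interim analyses see data, so future values can
#' never leak into a look.
#'
#' @param data A [trial_dataset()].
#' @param time Calendar time in months.
#' @return A [trial_dataset()] with unobservable values set to NA.
#' @export
observe_at <- function(data, time) {
  stopifnot(inherits(data, "trial_dataset"))
  lags <- dataset_lags(data)
  cols <- dataset_outcols(data)
  keep <- data$entry_month <= time
  out <- data[keep, , drop = FALSE]
  for (k in seq_along(cols)) {
    mask <- out$entry_month + lags[k] > time
    out[[cols[k]]][mask] <- NA_real_
  }
  trial_dataset(out, lags = lags, outcome_cols = cols)
}

# K x 2 matrix of observed counts per endpoint and arm
observed_counts <- function(data) {
  cols <- dataset_outcols(data)
  K <- length(cols)
  m <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    obs <- !is.na(data[[cols[k]]])
    m[k, 1] <- sum(obs & data$arm == 0)
    m[k, 2] <- sum(obs & data$arm == 1)
  }
  m
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Trial dataset:", nrow(x), "participants (",
      sum(x$arm == 0), "control /", sum(x$arm == 1), "active ),",
      length(dataset_outcols(x)), "endpoints at lags",
      paste(dataset_lags(x), collapse = "/"), "months\n")
  m <- observed_counts(x)
  cat("  observed per endpoint (control/active):",
      paste(paste0(m[, 1], "/", m[, 2]), collapse = ", "), "\n")
  invisible(x)
}
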