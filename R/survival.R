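#' Build a validated survival table
#'
#' Companion clinical data for survival comparison of sample clusters:
#' one row per sample with a follow-up time (months) and an event
#' indicator (1 = death observed, 0 = censored).
#'
#' @param sample_ids Unique sample identifiers.
#' @param time Nonnegative finite follow-up times.
#' @param event Event indicators, each 0 or 1.
#' @return A `data.frame` of class `"survival_table"` with columns
#'   `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  .check_ids(sample_ids, "sample")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample_ids) ||
      length(event) != length(sample_ids))
    stop("`time` and `event` must match `sample_ids` in length",
         call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("`time` must be finite and nonnegative", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  structure(data.frame(sample_id = sample_ids, time = time, event = event,
                       stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

# optional truncation: follow-up beyond `horizon` months is censored at
# the horizon (turns overall survival into e.g. 5-year survival)
.apply_horizon <- function(tab, horizon) {
  if (is.null(horizon)) return(tab)
  .check_scalar(horizon, "horizon", positive = TRUE)
  over <- tab$time > horizon
  tab$event[over] <- 0
  tab$time[over] <- horizon
  tab
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function for one group of
#' subjects.  Returns a right-continuous nonincreasing step function
#' starting at 1, evaluable at any time.
#'
#' @param table A `"survival_table"` (see [survival_table()]).
#' @param horizon Optional truncation time in months: events after the
#'   horizon are treated as censored at the horizon.
#' @return A function `S(t)` (class `"km_estimate"`) with the fitted
#'   `survival::survfit` object in attribute `"fit"` and the step
#'   coordinates in attribute `"table"` (columns `time`, `surv`).
#' @export
km_estimate <- function(table, horizon = NULL) {
  table <- .validate_survival(table)
  table <- .apply_horizon(table, horizon)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  times <- fit$time
  surv <- fit$surv
  f <- if (length(times) == 0L) {
    function(t) rep(1, length(t))
  } else {
    stats::stepfun(times, c(1, surv), right = FALSE)
  }
  structure(f, class = c("km_estimate", class(f)),
            fit = fit,
            table = data.frame(time = times, surv = surv))
}

#' Two-group log-rank test
#'
#' Compares the survival experience of two sample groups: at each
#' distinct event time the observed number of events in group 1 is
#' compared with its hypergeometric expectation given the risk sets,
#' and the statistic `(sum(O - E))^2 / sum(V)` is referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param table A `"survival_table"`.
#' @param group_labels Group membership with exactly two levels, one
#'   entry per subject.
#' @param horizon Optional truncation time (see [km_estimate()]).
#' @return List of class `"logrank"` with `statistic` (chi-square) and
#'   `p_value`.  If no events are observed at all the test is
#'   undefined; a warning is raised and `statistic = 0`, `p_value = 1`
#'   is returned.
#' @export
logrank_test <- function(table, group_labels, horizon = NULL) {
  table <- .validate_survival(table)
  table <- .apply_horizon(table, horizon)
  g <- as.factor(group_labels)
  if (length(g) != nrow(table))
    stop("`group_labels` must have one entry per subject", call. = FALSE)
  if (nlevels(g) != 2L)
    stop("`group_labels` must define exactly two groups", call. = FALSE)
  if (sum(table$event) == 0) {
    warning("no events observed; log-rank test undefined, returning p = 1",
            call. = FALSE)
    return(structure(list(statistic = 0, p_value = 1), class = "logrank"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(table, g = g))
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE)),
            class = "logrank")
}

#' @export
print.logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

.validate_survival <- function(table) {
  if (inherits(table, "survival_table")) return(table)
  if (is.data.frame(table) &&
      all(c("sample_id", "time", "event") %in% names(table)))
    return(survival_table(table$sample_id, table$time, table$event))
  stop("`table` must be a survival_table or a data frame with columns ",
       "sample_id, time, event", call. = FALSE)
}
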