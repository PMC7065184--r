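# Kaplan-Meier estimation, log-rank comparison, reverse-KM follow-up.
#
# Thin, validated wrappers over the survival package. Times are months;
# "5-year" means 60.0 months. Ties of events and censorings at the same time
# follow the standard convention (events first), as implemented by survfit.

check_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop_mcec("negative follow-up times")
  if (nrow(records) == 0) stop_mcec("no survival records")
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records data frame with columns \code{time} (months) and
#'   \code{event} (logical or 0/1; TRUE = event observed).
#' @return object of class \code{km_fit}: list with \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event}, \code{n}, and the
#'   underlying \code{survfit} object as \code{fit}.
#' @export
km_estimate <- function(records) {
  check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = data.frame(time = records$time,
                                             event = as.integer(records$event)))
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = sum(fit$n), fit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n=%d, %d events, last follow-up %.1f months\n",
              x$n, sum(x$n_event), max(x$time)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation; \code{t = 60} gives the
#' 5-year estimate. Evaluation beyond the last follow-up returns the last
#' value with a warning.
#'
#' @param km \code{km_fit} from \code{\link{km_estimate}}.
#' @param t_months time in months, >= 0.
#' @return survival probability.
#' @export
survival_at <- function(km, t_months) {
  if (t_months < 0) stop_mcec("t_months must be >= 0")
  if (t_months > max(km$time)) {
    warning(sprintf("t = %g months exceeds last follow-up (%g); extrapolating last value",
                    t_months, max(km$time)))
  }
  s <- summary(km$fit, times = min(t_months, max(km$time)), extend = TRUE)
  unname(s$surv)
}

#' Log-rank test between survival groups
#'
#' @param records data frame with \code{time}, \code{event}, \code{group}.
#' @return list with \code{statistic} (chi-squared), \code{df}
#'   (groups - 1), \code{p_value}, \code{n_per_group}.
#' @export
logrank_test <- function(records) {
  check_records(records)
  if (is.null(records$group)) stop_mcec("a group column is required")
  counts <- table(records$group)
  if (length(counts) < 2) stop_mcec("at least two groups are required")
  if (any(counts == 0)) stop_mcec("empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data.frame(time = records$time,
                                             event = as.integer(records$event),
                                             group = records$group))
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_per_group = as.integer(counts))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' KM with the censoring indicator inverted: events are censored and
#' censorings are counted as events, so the curve estimates the follow-up
#' distribution of the cohort.
#'
#' @param records data frame with \code{time} and \code{event}.
#' @return list with \code{median} (months; NA when not reached) and
#'   \code{reached} (logical).
#' @export
reverse_km_followup <- function(records) {
  check_records(records)
  fit <- survival::survfit(survival::Surv(time, cens) ~ 1,
                           data = data.frame(time = records$time,
                                             cens = 1L - as.integer(records$event)))
  med <- unname(summary(fit)$table["median"])
  list(median = med, reached = !is.na(med))
}

#' Five-year survival summary per group, with pairwise log-rank tests
#'
#' @param records data frame with \code{time}, \code{event}, \code{group},
#'   optionally \code{stage}.
#' @param horizon months at which to read the curves (default 60).
#' @param subset_stage optional character vector of stage strings to keep
#'   (exact match, e.g. \code{c("I", "IA", "IB")}).
#' @param reference_group if given, pairwise log-rank of every other group
#'   against this one.
#' @return list with \code{by_group} data frame (group, n, events,
#'   survival at horizon), \code{logrank} (overall test), and
#'   \code{pairwise} (data frame, if a reference group was given).
#' @export
survival_summary <- function(records, horizon = 60, subset_stage = NULL,
                             reference_group = NULL) {
  check_records(records)
  if (!is.null(subset_stage)) {
    records <- records[records$stage %in% subset_stage, , drop = FALSE]
    if (nrow(records) == 0) stop_mcec("no records left after stage subsetting")
  }
  groups <- sort(unique(records$group))
  by_group <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, , drop = FALSE]
    km <- km_estimate(r)
    data.frame(group = g, n = nrow(r), events = sum(as.integer(r$event)),
               survival = survival_at(km, horizon), stringsAsFactors = FALSE)
  }))
  overall <- if (length(groups) > 1) logrank_test(records) else NULL
  pairwise <- NULL
  if (!is.null(reference_group) && reference_group %in% groups) {
    others <- setdiff(groups, reference_group)
    pairwise <- do.call(rbind, lapply(others, function(g) {
      lr <- logrank_test(records[records$group %in% c(g, reference_group), , drop = FALSE])
      data.frame(group = g, vs = reference_group, statistic = lr$statistic,
                 p_value = lr$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(horizon = horizon, by_group = by_group, logrank = overall, pairwise = pairwise)
}
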