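#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' plain data.frame. Censored observations leave the risk set after their
#' time (standard convention: a censoring tied with an event keeps the
#' subject at risk for that event).
#'
#' @param time positive follow-up times (days).
#' @param event 1 = death observed, 0 = censored.
#' @return An object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (rows at every distinct observed time).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("no records")
  if (length(time) != length(event)) stop("'time' and 'event' lengths differ")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at every distinct event time the observed
#' minus expected events in one group are accumulated under the
#' hypergeometric variance; the statistic is chi-squared with 1 df. Wraps
#' [survival::survdiff()] (rho = 0).
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level factor/vector assigning each record to a group.
#' @return list with `chisq`, `df`, `p`, and per-group `n`, `observed`,
#'   `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly two groups")
  if (length(unique(c(length(time), length(event), length(group)))) != 1L)
    stop("input lengths differ")
  if (sum(event) == 0) stop("no events observed")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(fit$n) - 1L
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n = as.vector(fit$n), observed = fit$obs, expected = fit$exp)
}

#' Compare survival between in-area and out-of-area samples
#'
#' Joins region membership with the clinical table and runs Kaplan-Meier
#' estimation per group plus the two-group log-rank test. Rows missing
#' survival data are dropped (and counted).
#'
#' @param membership data.frame from [classify_membership()].
#' @param samples data.frame with `sample_id`, `os_days`, `event`.
#' @param subset optional character vector of sample ids to restrict to
#'   (e.g. a [vasari_filter()] result).
#' @return list with `curves` (named list of [km_estimate()] results for
#'   `in_area` and `out_area`), `test` (the [logrank_test()] result or NULL
#'   if a group is empty), `n_used`, `n_dropped`.
#' @export
compare_survival <- function(membership, samples, subset = NULL) {
  d <- merge(membership[, c("sample_id", "in_area")],
             samples[, c("sample_id", "os_days", "event")],
             by = "sample_id")
  if (!is.null(subset)) d <- d[d$sample_id %in% subset, , drop = FALSE]
  ok <- !is.na(d$os_days) & !is.na(d$event) & d$os_days > 0
  n_dropped <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  curves <- list(
    in_area = if (any(d$in_area))
      km_estimate(d$os_days[d$in_area], d$event[d$in_area]) else NULL,
    out_area = if (any(!d$in_area))
      km_estimate(d$os_days[!d$in_area], d$event[!d$in_area]) else NULL)
  test <- if (any(d$in_area) && any(!d$in_area) && sum(d$event) > 0)
    logrank_test(d$os_days, d$event,
                 ifelse(d$in_area, "in_area", "out_area")) else NULL
  list(curves = curves, test = test, n_used = nrow(d), n_dropped = n_dropped)
}
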