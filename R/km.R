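#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric estimate of the survival function for right-censored data.
#' The curve steps only at event times; censored-only times reduce the risk
#' set but leave the estimate unchanged. The median is the earliest time at
#' which the estimated survival drops to 0.5 or below, or \code{NA}
#' ("not reached") if it never does.
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicator (1 = event, 0 = censored).
#' @return object of class \code{"kmcurve"}: \code{time} (ascending unique
#'   event times), \code{nRisk}, \code{nEvent}, \code{survival},
#'   \code{median}, \code{n}.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
#' km$survival   # 2/3 at t = 1, 0 at t = 3
#' km$median     # 3
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  if (anyNA(time) || anyNA(event)) stop("missing values in time/event")
  if (any(time <= 0)) stop("times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  eventTimes <- sort(unique(time[event == 1]))
  nRisk <- vapply(eventTimes, function(t) sum(time >= t), numeric(1))
  nEvent <- vapply(eventTimes, function(t) sum(time == t & event == 1),
                   numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  med <- if (length(surv) && any(surv <= 0.5))
    eventTimes[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(time = eventTimes, nRisk = nRisk, nEvent = nEvent,
                 survival = surv, median = med, n = length(time),
                 totalEvents = sum(event)),
            class = "kmcurve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km a \code{"kmcurve"}.
#' @param t times at which to evaluate (right-continuous step function;
#'   survival is 1 before the first event time).
#' @return numeric vector of survival probabilities.
#' @export
kmSurvivalAt <- function(km, t) {
  if (!length(km$time)) return(rep(1, length(t)))
  stats::stepfun(km$time, c(1, km$survival), right = FALSE)(t)
}

# left limit S(t-): survival just before t
.kmLeftLimit <- function(km, t) {
  if (!length(km$time)) return(rep(1, length(t)))
  vapply(t, function(tt) {
    idx <- which(km$time < tt)
    if (length(idx)) km$survival[max(idx)] else 1
  }, numeric(1))
}

#' @export
print.kmcurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, x$totalEvents,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a flat table
#'
#' @param km a \code{"kmcurve"}.
#' @return \code{data.frame} with one row per event time.
#' @export
kmTable <- function(km) {
  data.frame(time = km$time, n_risk = km$nRisk, n_event = km$nEvent,
             survival = km$survival)
}
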