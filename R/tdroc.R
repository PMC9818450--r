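# Shared case/control/IPCW preparation for a (time, event, horizon) triple:
# cases = died by the horizon, controls = survived beyond it; weights are
# inverse probabilities of remaining uncensored, from the Kaplan-Meier
# estimate of the censoring distribution (event flags flipped). Marker
# independent, so the screen computes it once per cohort.
.tdPrep <- function(time, event, horizon) {
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (horizon <= 0 || horizon > max(time))
    stop("horizon must lie within the observed follow-up range")
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (!length(cases)) stop("no cases: nobody died by the horizon")
  if (!length(controls)) stop("no controls: nobody under observation beyond the horizon")
  cens <- kmEstimate(time, 1 - event)
  wCases <- 1 / .kmLeftLimit(cens, time[cases])
  ok <- is.finite(wCases)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " case(s) with zero censoring-survival weight")
    cases <- cases[ok]; wCases <- wCases[ok]
    if (!length(cases)) stop("no cases with positive weight")
  }
  gHorizon <- kmSurvivalAt(cens, horizon)
  wControls <- rep(1 / max(gHorizon, .Machine$double.eps), length(controls))
  list(cases = cases, controls = controls,
       wCases = wCases, wControls = wControls, horizon = horizon)
}

.tdAuc <- function(marker, prep) {
  mC <- marker[prep$cases]; mK <- marker[prep$controls]
  conc <- outer(mC, mK, ">") + 0.5 * outer(mC, mK, "==")
  ww <- tcrossprod(prep$wCases, prep$wControls)
  sum(ww * conc) / sum(ww)
}

#' Time-dependent ROC curve for a censored survival outcome
#'
#' Cumulative-cases / dynamic-controls ROC of a continuous marker at a fixed
#' horizon: cases are subjects who died by the horizon, controls are those
#' still under observation beyond it, and censoring is handled by inverse-
#' probability-of-censoring weights (IPCW) from the Kaplan-Meier estimate of
#' the censoring distribution. A subject is called marker-positive when the
#' marker strictly exceeds the threshold, matching the dichotomization
#' convention of \code{\link{dichotomize}}. The AUC is the IPCW-weighted
#' pairwise concordance between cases and controls; with no censoring it
#' reduces to the Mann-Whitney concordance of marker vs died-by-horizon
#' status.
#'
#' @param marker continuous marker values (e.g. log expression).
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicator.
#' @param horizon evaluation time in months; must lie within follow-up.
#' @return object of class \code{"tdroc"}: \code{horizon},
#'   \code{thresholds} (ascending unique marker values),
#'   \code{sensitivity}, \code{specificity}, \code{auc}, \code{nCases},
#'   \code{nControls}.
#' @examples
#' set.seed(7)
#' t <- rexp(60, 0.03); m <- -log(t) + rnorm(60)
#' roc <- tdRoc(m, t, rep(1, 60), horizon = 24)
#' roc$auc
#' @export
tdRoc <- function(marker, time, event, horizon) {
  stopifnot(length(marker) == length(time))
  if (anyNA(marker)) stop("missing marker values")
  prep <- .tdPrep(time, event, horizon)
  thr <- sort(unique(marker))
  mC <- marker[prep$cases]; mK <- marker[prep$controls]
  sens <- drop(crossprod(prep$wCases, outer(mC, thr, ">"))) / sum(prep$wCases)
  spec <- drop(crossprod(prep$wControls, outer(mK, thr, "<="))) / sum(prep$wControls)
  structure(list(horizon = horizon, thresholds = thr,
                 sensitivity = sens, specificity = spec,
                 auc = .tdAuc(marker, prep),
                 nCases = length(prep$cases),
                 nControls = length(prep$controls)),
            class = "tdroc")
}

#' @export
print.tdroc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at %.4g months: AUC = %.4f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$nCases, x$nControls))
  invisible(x)
}

#' AUC trajectory over a grid of horizons
#'
#' Applies \code{\link{tdRoc}} at each horizon; horizons at which the ROC is
#' undefined (no cases or no controls, or beyond follow-up) are skipped with
#' a warning.
#'
#' @inheritParams tdRoc
#' @param horizons ascending evaluation times (months).
#' @return \code{data.frame} with columns \code{horizon}, \code{auc},
#'   \code{n_cases}, \code{n_controls}; one row per valid horizon.
#' @export
aucTrajectory <- function(marker, time, event, horizons) {
  stopifnot(length(horizons) >= 1L)
  if (is.unsorted(horizons, strictly = TRUE))
    stop("horizons must be strictly ascending")
  rows <- lapply(horizons, function(h) {
    roc <- tryCatch(tdRoc(marker, time, event, h), error = function(e) {
      warning(sprintf("horizon %.4g skipped: %s", h, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(roc)) NULL
    else data.frame(horizon = h, auc = roc$auc, n_cases = roc$nCases,
                    n_controls = roc$nControls)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no valid horizon in the requested grid")
  do.call(rbind, rows)
}
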