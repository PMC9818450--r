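# Core cutpoint search against a precomputed case/control preparation,
# so a transcriptome-wide screen pays for the censoring-KM only once.
.cutpointFast <- function(marker, prep, band = c(0.1, 0.9),
                          geneId = NA_character_) {
  qs <- stats::quantile(marker, band, names = FALSE, type = 7)
  thr <- sort(unique(marker))
  cand <- thr[thr >= qs[1L] & thr <= qs[2L] & thr < max(marker)]
  if (!length(cand))
    stop("no admissible candidate threshold inside the percentile band")
  mC <- marker[prep$cases]; mK <- marker[prep$controls]
  sens <- drop(crossprod(prep$wCases, outer(mC, cand, ">"))) / sum(prep$wCases)
  spec <- drop(crossprod(prep$wControls, outer(mK, cand, "<="))) / sum(prep$wControls)
  J <- sens + spec - 1
  best <- which(J > max(J) - 1e-12)
  if (length(best) > 1L) {  # ties: prefer the more balanced split, then the smaller cutpoint
    nHigh <- vapply(cand[best], function(c) sum(marker > c), numeric(1))
    imbalance <- abs(2 * nHigh - length(marker))
    best <- best[imbalance == min(imbalance)]
    best <- best[1L]
  }
  cut <- cand[best]
  structure(list(geneId = geneId, cutpoint = cut,
                 auc = .tdAuc(marker, prep),
                 sensitivity = sens[best], specificity = spec[best],
                 youdenJ = J[best], horizon = prep$horizon,
                 nHigh = sum(marker > cut), nLow = sum(marker <= cut)),
            class = "cutpointResult")
}

#' Optimal marker cutpoint for a censored survival outcome
#'
#' Chooses the dichotomization threshold maximizing the Youden index
#' J = sensitivity + specificity - 1 of the IPCW time-dependent ROC
#' (\code{\link{tdRoc}}) at the given horizon. Candidate thresholds are the
#' observed marker values restricted to a central percentile band (default
#' 10th-90th) so neither group becomes degenerately small. Ties in J are
#' broken toward the more balanced high/low split, then toward the smaller
#' cutpoint, making the choice deterministic. Because only marker ranks
#' enter, the induced sample partition is invariant under strictly
#' increasing marker transforms.
#'
#' @inheritParams tdRoc
#' @param band lower and upper percentile bounds for candidate thresholds.
#' @param geneId optional marker identifier carried in the result.
#' @return object of class \code{"cutpointResult"}: \code{cutpoint},
#'   \code{auc} (of the full ROC), \code{sensitivity}, \code{specificity}
#'   and \code{youdenJ} at the chosen threshold, \code{horizon},
#'   \code{nHigh}, \code{nLow}.
#' @examples
#' set.seed(11)
#' t <- rexp(80, 0.03); m <- -0.5 * log(t) + rnorm(80, sd = 0.5)
#' optimalCutpoint(m, t, rep(1, 80), horizon = 24)
#' @export
optimalCutpoint <- function(marker, time, event, horizon = 36,
                            band = c(0.1, 0.9), geneId = NA_character_) {
  stopifnot(length(marker) == length(time), length(band) == 2L,
            band[1L] < band[2L], band[1L] >= 0, band[2L] <= 1)
  if (anyNA(marker)) stop("missing marker values")
  .cutpointFast(marker, .tdPrep(time, event, horizon), band, geneId)
}

#' @export
print.cutpointResult <- function(x, ...) {
  cat(sprintf(
    "Optimal cutpoint%s at horizon %.4g: %.4g (AUC %.3f, sens %.3f, spec %.3f; %d high / %d low)\n",
    if (is.na(x$geneId)) "" else paste0(" [", x$geneId, "]"),
    x$horizon, x$cutpoint, x$auc, x$sensitivity, x$specificity,
    x$nHigh, x$nLow))
  invisible(x)
}
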