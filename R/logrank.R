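#' Log-rank test for equality of survival curves
#'
#' Classical observed-vs-expected chi-square over the pooled event times,
#' with the hypergeometric variance-covariance of the per-group event
#' counts. Handles k >= 2 groups (dof = k - 1) and is invariant to group
#' relabelling.
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicator.
#' @param group group membership (factor/character/numeric); every group
#'   must be non-empty.
#' @return object of class \code{"logrank"}: \code{statistic}, \code{dof},
#'   \code{p}, per-group observed and expected event counts.
#' @examples
#' logrankTest(c(2, 4, 6, 1, 3, 5), c(1, 1, 0, 1, 1, 1),
#'             rep(c("a", "b"), each = 3))
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) stop("log-rank needs at least two non-empty groups")
  if (any(table(group) == 0L)) stop("every group must be non-empty")
  eventTimes <- sort(unique(time[event == 1]))
  if (!length(eventTimes)) stop("no events observed")
  J <- length(eventTimes)
  gi <- as.integer(group)
  # at-risk counts per group at each event time via sorted-time bisection
  nRisk <- matrix(0, J, k)
  dMat <- matrix(0, J, k)
  for (g in seq_len(k)) {
    tg <- sort(time[gi == g])
    nRisk[, g] <- length(tg) - findInterval(eventTimes, tg, left.open = TRUE)
    tge <- time[gi == g & event == 1]
    if (length(tge))
      dMat[, g] <- tabulate(match(tge, eventTimes), nbins = J)
  }
  nTot <- rowSums(nRisk)
  dTot <- rowSums(dMat)
  O <- colSums(dMat)
  E <- colSums(nRisk * dTot / nTot)
  f <- ifelse(nTot > 1, dTot * (nTot - dTot) / (nTot - 1), 0)
  prop <- nRisk / nTot
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (g in seq_len(k))
    for (h in seq_len(g)) {
      V[g, h] <- V[h, g] <- sum(f * (((g == h) * prop[, g]) -
                                       prop[, g] * prop[, h]))
    }
  names(O) <- names(E) <- levels(group)
  z <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vsub, z)),
                   error = function(e) drop(t(z) %*% .pseudoInverse(Vsub) %*% z))
  dof <- k - 1L
  structure(list(statistic = stat, dof = dof,
                 p = stats::pchisq(stat, dof, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank")
}

.pseudoInverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$dof, x$p))
  invisible(x)
}
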