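#' Cox proportional-hazards regression via Newton-Raphson
#'
#' Maximizes the Cox partial likelihood with the Efron tie correction
#' (default; Breslow available). Standard errors come from the inverse of
#' the observed information at the maximum; per-covariate Wald z tests are
#' reported two-sided. An optional \code{strata} term gives a stratified
#' partial likelihood (separate risk sets per stratum, shared
#' coefficients).
#'
#' Convergence is declared when the log partial likelihood changes by less
#' than \code{tol} between iterations (step-halving on overshoot, at most
#' \code{maxIter} iterations). Monotone-likelihood separation (a coefficient
#' drifting without bound) is detected and flagged via
#' \code{converged = FALSE} rather than returned silently; downstream
#' screening treats unconverged fits as failures.
#'
#' @param x covariate matrix (n x p) or vector; no constant covariate
#'   allowed.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator; at least one event required.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param strata optional stratification factor.
#' @param tol convergence tolerance on the log partial likelihood change.
#' @param maxIter maximum Newton-Raphson iterations.
#' @return object of class \code{"coxfit"}: \code{coefficients},
#'   \code{hazardRatios} (= exp(coef)), \code{se}, \code{z}, \code{p},
#'   \code{var}, \code{loglik} (null and final), \code{score} (the score
#'   test at beta = 0: statistic, dof, p), \code{iter}, \code{converged},
#'   \code{n}, \code{nEvent}.
#' @examples
#' set.seed(1)
#' x <- rbinom(40, 1, 0.5)
#' t <- rexp(40, 0.1 * exp(0.7 * x))
#' fit <- coxFitPL(x, t, rep(1, 40))
#' fit$hazardRatios
#' @export
coxFitPL <- function(x, time, event, ties = c("efron", "breslow"),
                     strata = NULL, tol = 1e-9, maxIter = 100L) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) {
    nm <- if (!is.null(names(x))) NULL else deparse(substitute(x))[1L]
    x <- matrix(x, ncol = 1L,
                dimnames = list(NULL, if (is.null(nm)) "x" else nm))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(x) || any(!is.finite(x))) stop("covariates must be finite")
  if (any(time <= 0)) stop("times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) stop("at least one event is required")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant covariate: ", paste(colnames(x)[sds == 0], collapse = ", "))
  if (is.null(strata)) strata <- rep(1L, n)
  strata <- as.integer(factor(strata))

  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  # per-stratum precomputation: sort by time decreasing so risk-set sums
  # are cumulative sums from the top
  pairI <- rep(seq_len(p), times = p:1)
  pairJ <- unlist(lapply(seq_len(p), function(i) i:p))
  prep <- lapply(split(seq_len(n), strata), function(idx) {
    ord <- idx[order(time[idx], decreasing = TRUE)]
    ts <- time[ord]; es <- event[ord]
    uet <- sort(unique(ts[es == 1]), decreasing = TRUE)
    list(ord = ord, ts = ts, es = es, xs = xc[ord, , drop = FALSE],
         deathSets = lapply(uet, function(t)
           list(riskEnd = max(which(ts >= t)),
                dIdx = which(ts == t & es == 1))))
  })

  derivs <- function(beta) {
    ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
    S2 <- matrix(0, p, p)
    lowIdx <- cbind(pairI, pairJ); uppIdx <- cbind(pairJ, pairI)
    for (st in prep) {
      eta <- drop(st$xs %*% beta)
      w <- exp(eta)
      wx <- w * st$xs
      cum0 <- cumsum(w)
      cum1 <- apply(wx, 2L, cumsum)
      if (p == 1L) cum1 <- matrix(cum1, ncol = 1L)
      # risk-set sums of w * x_i x_j as cumulative sums over the unique
      # covariate pairs, so each death time costs O(p^2), not O(n p^2)
      cum2 <- apply(wx[, pairI, drop = FALSE] * st$xs[, pairJ, drop = FALSE],
                    2L, cumsum)
      if (nrow(st$xs) == 1L) cum2 <- matrix(cum2, nrow = 1L)
      for (ds in st$deathSets) {
        D <- ds$dIdx; d <- length(D)
        S0 <- cum0[ds$riskEnd]
        S1 <- cum1[ds$riskEnd, ]
        v2 <- cum2[ds$riskEnd, ]
        S2[lowIdx] <- v2; S2[uppIdx] <- v2
        if (ties == "efron" && d > 1L) {
          S0D <- sum(w[D])
          S1D <- colSums(wx[D, , drop = FALSE])
          XD <- st$xs[D, , drop = FALSE]
          S2D <- crossprod(XD, w[D] * XD)
          l <- seq_len(d) - 1
          denom <- S0 - (l / d) * S0D
          A <- sum(1 / denom); B <- sum((l / d) / denom)
          A2 <- sum(1 / denom^2); B2 <- sum(((l / d) / denom)^2)
          AB <- sum((l / d) / denom^2)
          ll <- ll + sum(eta[D]) - sum(log(denom))
          U <- U + colSums(XD) - (S1 * A - S1D * B)
          mm <- A2 * tcrossprod(S1) + B2 * tcrossprod(S1D) -
            AB * (tcrossprod(S1, S1D) + tcrossprod(S1D, S1))
          I <- I + (S2 * A - S2D * B) - mm
        } else {
          XD <- st$xs[D, , drop = FALSE]
          ll <- ll + sum(eta[D]) - d * log(S0)
          U <- U + colSums(XD) - d * S1 / S0
          I <- I + d * (S2 / S0 - tcrossprod(S1 / S0))
        }
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  d0 <- derivs(beta)
  nullLoglik <- d0$ll
  scoreStat <- tryCatch(drop(t(d0$U) %*% solve(d0$I, d0$U)),
                        error = function(e) NA_real_)
  converged <- FALSE
  iter <- 0L
  llOld <- d0$ll
  dcur <- d0
  while (iter < maxIter) {
    iter <- iter + 1L
    step <- tryCatch(solve(dcur$I, dcur$U), error = function(e) NULL)
    if (is.null(step)) break
    halve <- 0L
    repeat {
      betaNew <- beta + step / 2^halve
      dNew <- derivs(betaNew)
      if (is.finite(dNew$ll) && dNew$ll >= llOld - 1e-12) break
      halve <- halve + 1L
      if (halve > 20L) break
    }
    if (halve > 20L) break
    beta <- betaNew
    dcur <- dNew
    if (abs(dNew$ll - llOld) < tol) {
      converged <- TRUE
      llOld <- dNew$ll
      break
    }
    llOld <- dNew$ll
  }
  if (max(abs(beta)) > 15) converged <- FALSE  # monotone-likelihood separation

  var <- tryCatch(solve(dcur$I), error = function(e) {
    converged <<- FALSE
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(var), 0))
  z <- beta / se
  names(beta) <- names(se) <- names(z) <- colnames(x)
  dimnames(var) <- list(colnames(x), colnames(x))
  structure(list(
    coefficients = beta,
    hazardRatios = exp(beta),
    se = se,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    var = var,
    loglik = c(null = nullLoglik, final = llOld),
    score = list(statistic = scoreStat, dof = p,
                 p = stats::pchisq(scoreStat, p, lower.tail = FALSE)),
    iter = iter,
    converged = converged,
    ties = ties,
    n = n,
    nEvent = sum(event)), class = "coxfit")
}

#' @export
print.coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, %s after %d iterations\n",
              x$ties, x$n, x$nEvent,
              if (x$converged) "converged" else "NOT converged", x$iter))
  print(data.frame(coef = x$coefficients, HR = x$hazardRatios, se = x$se,
                   z = x$z, p = x$p))
  invisible(x)
}

#' Forest-plot-style table for a Cox fit
#'
#' One row per covariate with the hazard ratio, Wald confidence interval and
#' p-value, ready for plotting.
#'
#' @param fit a \code{"coxfit"}.
#' @param level confidence level (default 0.95).
#' @return \code{data.frame} with columns \code{term}, \code{hr},
#'   \code{hr_low}, \code{hr_high}, \code{p}.
#' @export
coxForestTable <- function(fit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(fit$coefficients),
             hr = unname(fit$hazardRatios),
             hr_low = exp(unname(fit$coefficients - zq * fit$se)),
             hr_high = exp(unname(fit$coefficients + zq * fit$se)),
             p = unname(fit$p))
}
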