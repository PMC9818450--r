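.DEFAULT_CONFOUNDERS <- c("age", "sex", "wbc", "transplant", "eln")

# Confounder design columns: age and WBC continuous, sex and transplant
# single indicators, ELN as two indicators with favorable as reference.
.confounderMatrix <- function(cd, confounders) {
  cols <- list(); notes <- character()
  for (cf in confounders) {
    if (!cf %in% colnames(cd)) {
      notes <- c(notes, sprintf("confounder '%s' unavailable; excluded", cf))
      next
    }
    v <- cd[[cf]]
    cols <- c(cols, switch(cf,
      age = list(age = as.numeric(v)),
      wbc = list(wbc = as.numeric(v)),
      sex = list(sex_male = as.numeric(v == "male")),
      transplant = list(transplant_allo = as.numeric(v == "allo")),
      eln = list(eln_intermediate = as.numeric(v == "intermediate"),
                 eln_adverse = as.numeric(v == "adverse")),
      stats::setNames(list(as.numeric(v)), cf)))
  }
  if (!length(cols))
    return(list(x = NULL, notes = notes))
  x <- do.call(cbind, cols)
  const <- apply(x, 2L, function(col) stats::sd(col, na.rm = TRUE) == 0 ||
                   all(is.na(col)))
  if (any(const)) {
    notes <- c(notes, sprintf("constant confounder column(s) excluded: %s",
                              paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    if (!ncol(x)) x <- NULL
  }
  list(x = x, notes = notes)
}

.evalGates <- function(auc, sens, spec, uniP, multiP, multiRetained,
                       aucGate = 0.5, sensGate = 0.5, specGate = 0.5,
                       alpha = 0.05, gateMode = "strict") {
  c(auc_gate  = isTRUE(auc > aucGate),
    sens_gate = isTRUE(sens > sensGate),
    spec_gate = isTRUE(spec > specGate),
    uni_p_gate = isTRUE(is.finite(uniP) && uniP < alpha),
    multi_p_gate = if (gateMode == "strict")
      isTRUE(is.finite(multiP) && multiP < alpha && multiRetained)
    else isTRUE(multiRetained))
}

.failedScreenRow <- function(cohort, geneId, reason) {
  data.frame(cohort = cohort, gene_id = geneId,
             cutpoint = NA_real_, auc = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_, n_high = NA_integer_, n_low = NA_integer_,
             uni_hr = NA_real_, uni_p = NA_real_,
             multi_hr = NA_real_, multi_p = NA_real_,
             auc_gate = FALSE, sens_gate = FALSE, spec_gate = FALSE,
             uni_p_gate = FALSE, multi_p_gate = FALSE,
             pass = FALSE, direction = NA_character_, reason = reason,
             stringsAsFactors = FALSE)
}

#' Screen one gene for prognostic value in a cohort
#'
#' The per-gene discovery cascade: (1) Youden-optimal cutpoint of the gene's
#' expression against the survival endpoint at the evaluation horizon
#' (\code{\link{optimalCutpoint}}); (2) dichotomization into high/low
#' expression groups; (3) univariate Cox regression on the group indicator
#' and a confounder-adjusted multivariate Cox regression (group + age, sex,
#' WBC, transplant type, ELN category, as available); (4) filter gates:
#' AUC > 0.5, sensitivity > 0.5, specificity > 0.5 (strict inequalities),
#' univariate p < alpha and multivariate p < alpha. A gene passes only if
#' all five gates hold; the effect direction comes from the sign of the
#' adjusted group coefficient.
#'
#' Degenerate inputs (constant expression, no admissible cutpoint, an
#' unconverged adjusted fit) yield a failed row with the reason recorded —
#' never an aborted screen.
#'
#' @param cohort a \linkS4class{SurvCohort}.
#' @param geneId gene to screen.
#' @param confounders clinical fields to adjust for; fields absent from the
#'   cohort are excluded and noted.
#' @param horizon ROC evaluation horizon in months (default 36).
#' @param alpha significance level for both Cox gates (default 0.05).
#' @param aucGate,sensGate,specGate ROC gate thresholds (defaults 0.5).
#' @param band candidate-cutpoint percentile band (default 10th-90th).
#' @param endpoint survival endpoint to model (\code{"OS"}, \code{"DFS"},
#'   \code{"EFS"}). The cutpoint itself is always derived from OS when
#'   available (\code{reuseOsCutpoint = TRUE}), so secondary endpoints are
#'   evaluated on the OS-defined groups.
#' @param gateMode \code{"strict"} (multivariate p < alpha required) or
#'   \code{"uniThenRetain"} (multivariate gate = the adjusted fit converged
#'   and kept the univariate effect direction).
#' @param reuseOsCutpoint reuse the OS-derived cutpoint for DFS/EFS.
#' @return one-row ledger \code{data.frame} (see \code{\link{screenCohort}}).
#' @export
screenGene <- function(cohort, geneId, confounders = .DEFAULT_CONFOUNDERS,
                       horizon = 36, alpha = 0.05, aucGate = 0.5,
                       sensGate = 0.5, specGate = 0.5, band = c(0.1, 0.9),
                       endpoint = "OS",
                       gateMode = c("strict", "uniThenRetain"),
                       reuseOsCutpoint = TRUE) {
  gateMode <- match.arg(gateMode)
  if (!geneId %in% rownames(cohort))
    stop("gene not in cohort: ", geneId)
  ctx <- .screenContext(cohort, confounders, horizon, endpoint,
                        reuseOsCutpoint)
  .screenGeneFast(cohort, geneId, ctx, alpha, aucGate, sensGate, specGate,
                  band, gateMode)
}

# cohort-level precomputation shared across genes
.screenContext <- function(cohort, confounders, horizon, endpoint,
                           reuseOsCutpoint) {
  surv <- endpointSurv(cohort, endpoint)
  cutSurv <- if (endpoint != "OS" && reuseOsCutpoint &&
                 "OS" %in% availableEndpoints(cohort))
    endpointSurv(cohort, "OS") else surv
  cd <- clinicalData(cohort)[surv$keep, , drop = FALSE]
  conf <- .confounderMatrix(cd, confounders)
  list(surv = surv, cutSurv = cutSurv,
       prep = .tdPrep(cutSurv$time, cutSurv$event, horizon),
       conf = conf, horizon = horizon, endpoint = endpoint,
       name = cohortName(cohort), expr = exprsMatrix(cohort))
}

.screenGeneFast <- function(cohort, geneId, ctx, alpha, aucGate, sensGate,
                            specGate, band, gateMode) {
  markerCut <- ctx$expr[geneId, ctx$cutSurv$keep]
  marker <- ctx$expr[geneId, ctx$surv$keep]
  cp <- tryCatch(.cutpointFast(markerCut, ctx$prep, band, geneId),
                 error = function(e) e)
  if (inherits(cp, "error"))
    return(.failedScreenRow(ctx$name, geneId,
                            paste0("degenerate dichotomization: ",
                                   conditionMessage(cp))))
  highInd <- as.numeric(marker > cp$cutpoint)
  if (stats::sd(highInd) == 0)
    return(.failedScreenRow(ctx$name, geneId,
                            "degenerate dichotomization: one group empty on the modelled endpoint"))
  uni <- tryCatch(coxFitPL(matrix(highInd, ncol = 1,
                                  dimnames = list(NULL, "marker_high")),
                           ctx$surv$time, ctx$surv$event),
                  error = function(e) e)
  if (inherits(uni, "error"))
    return(.failedScreenRow(ctx$name, geneId,
                            paste0("univariate fit failed: ",
                                   conditionMessage(uni))))
  multi <- NULL; multiOk <- FALSE
  design <- cbind(marker_high = highInd, ctx$conf$x)
  cc <- stats::complete.cases(design)
  if (sum(ctx$surv$event[cc]) >= 1 && stats::sd(design[cc, 1L]) > 0) {
    multi <- tryCatch(coxFitPL(design[cc, , drop = FALSE],
                               ctx$surv$time[cc], ctx$surv$event[cc]),
                      error = function(e) NULL)
    multiOk <- !is.null(multi) && multi$converged
  }
  multiBeta <- if (!is.null(multi)) multi$coefficients[["marker_high"]] else NA_real_
  multiP <- if (!is.null(multi)) multi$p[["marker_high"]] else NA_real_
  uniBeta <- uni$coefficients[["marker_high"]]
  retained <- multiOk &&
    (gateMode == "strict" || sign(multiBeta) == sign(uniBeta))
  gates <- .evalGates(cp$auc, cp$sensitivity, cp$specificity,
                      uni$p[["marker_high"]], multiP,
                      multiRetained = if (gateMode == "strict") multiOk else retained,
                      aucGate, sensGate, specGate, alpha, gateMode)
  dirBeta <- if (multiOk) multiBeta else uniBeta
  data.frame(cohort = ctx$name, gene_id = geneId,
             cutpoint = cp$cutpoint, auc = cp$auc,
             sensitivity = cp$sensitivity, specificity = cp$specificity,
             n_high = cp$nHigh, n_low = cp$nLow,
             uni_hr = unname(uni$hazardRatios[["marker_high"]]),
             uni_p = unname(uni$p[["marker_high"]]),
             multi_hr = if (is.null(multi)) NA_real_ else
               unname(multi$hazardRatios[["marker_high"]]),
             multi_p = unname(multiP),
             auc_gate = gates[["auc_gate"]], sens_gate = gates[["sens_gate"]],
             spec_gate = gates[["spec_gate"]],
             uni_p_gate = gates[["uni_p_gate"]],
             multi_p_gate = gates[["multi_p_gate"]],
             pass = all(gates),
             direction = if (dirBeta > 0) "high_is_worse" else "low_is_worse",
             reason = if (multiOk) NA_character_ else
               "adjusted fit unavailable or unconverged",
             stringsAsFactors = FALSE)
}

#' Screen every gene of a cohort
#'
#' Maps \code{\link{screenGene}} over a gene set, isolating per-gene
#' failures (a degenerate gene yields a failed ledger row with its reason;
#' the run continues). Confounder availability notes are emitted once per
#' cohort. Alongside the unadjusted gates, Benjamini-Hochberg
#' adjusted univariate p-values are reported in \code{uni_p_bh} for
#' reference only — they enter no gate, since cross-cohort intersection is
#' the screen's false-discovery control.
#'
#' @inheritParams screenGene
#' @param genes genes to screen (default: all rows of the cohort).
#' @param verbose emit progress messages.
#' @return object of class \code{"cohortScreen"}: \code{cohort} (name),
#'   \code{ledger} (one row per gene), \code{horizon}, \code{notes}.
#' @export
screenCohort <- function(cohort, genes = rownames(cohort),
                         confounders = .DEFAULT_CONFOUNDERS, horizon = 36,
                         alpha = 0.05, aucGate = 0.5, sensGate = 0.5,
                         specGate = 0.5, band = c(0.1, 0.9),
                         endpoint = "OS",
                         gateMode = c("strict", "uniThenRetain"),
                         reuseOsCutpoint = TRUE, verbose = TRUE) {
  gateMode <- match.arg(gateMode)
  if (!length(genes)) stop("empty gene list")
  missing <- setdiff(genes, rownames(cohort))
  if (length(missing))
    stop("gene(s) not in cohort: ", paste(utils::head(missing, 5), collapse = ", "))
  ctx <- .screenContext(cohort, confounders, horizon, endpoint,
                        reuseOsCutpoint)
  if (verbose && length(ctx$conf$notes))
    message(sprintf("screen [%s]: %s", cohortName(cohort),
                    paste(ctx$conf$notes, collapse = "; ")))
  rows <- lapply(genes, function(g)
    tryCatch(.screenGeneFast(cohort, g, ctx, alpha, aucGate, sensGate,
                             specGate, band, gateMode),
             error = function(e)
               .failedScreenRow(ctx$name, g, conditionMessage(e))))
  ledger <- do.call(rbind, rows)
  ledger$uni_p_bh <- stats::p.adjust(ledger$uni_p, method = "BH")
  if (verbose)
    message(sprintf("screen [%s]: %d/%d genes pass all gates",
                    cohortName(cohort), sum(ledger$pass), nrow(ledger)))
  structure(list(cohort = cohortName(cohort), ledger = ledger,
                 horizon = horizon, endpoint = ctx$endpoint,
                 notes = ctx$conf$notes),
            class = "cohortScreen")
}

#' @export
print.cohortScreen <- function(x, ...) {
  cat(sprintf("Cohort screen [%s, %s, horizon %.4g]: %d genes, %d pass\n",
              x$cohort, x$endpoint, x$horizon, nrow(x$ledger),
              sum(x$ledger$pass)))
  invisible(x)
}

#' Cross-cohort intersection of screen hits
#'
#' Merges per-cohort screens: the intersection contains the genes that pass
#' all five gates in \emph{every} cohort with the \emph{same} effect
#' direction. Opposite-direction hits are excluded — a gene cannot be both
#' protective and deleterious across cohorts of the same disease.
#'
#' @param screens list of \code{"cohortScreen"} objects (>= 2) with
#'   distinct cohort names.
#' @return a \linkS4class{ScreenSummary}.
#' @export
intersectCohorts <- function(screens) {
  stopifnot(is.list(screens), length(screens) >= 2L)
  if (!all(vapply(screens, inherits, logical(1), "cohortScreen")))
    stop("screens must be a list of cohortScreen objects")
  names(screens) <- vapply(screens, `[[`, character(1), "cohort")
  if (anyDuplicated(names(screens))) stop("duplicated cohort names")
  geneSets <- lapply(screens, function(s) s$ledger$gene_id)
  shared <- Reduce(intersect, geneSets)
  if (!length(shared)) stop("cohorts share no gene ids")
  passSets <- lapply(screens, function(s)
    s$ledger[s$ledger$pass, c("gene_id", "direction")])
  inter <- Reduce(function(a, b)
    merge(a, b, by = c("gene_id", "direction")), passSets)
  inter <- inter[order(inter$gene_id), , drop = FALSE]
  rownames(inter) <- NULL
  methods::new("ScreenSummary",
               ledgers = lapply(screens, `[[`, "ledger"),
               intersection = inter,
               horizon = screens[[1L]]$horizon)
}

#' @rdname survscreen-generics
#' @export
setMethod("intersectionGenes", "ScreenSummary",
          function(x) x@intersection)

#' @rdname survscreen-generics
#' @export
setMethod("screenLedger", "ScreenSummary", function(x, cohort) {
  if (missing(cohort)) return(x@ledgers)
  if (!cohort %in% names(x@ledgers)) stop("unknown cohort: ", cohort)
  x@ledgers[[cohort]]
})

setMethod("show", "ScreenSummary", function(object) {
  cat(sprintf("ScreenSummary: %d cohorts (%s), horizon %.4g months\n",
              length(object@ledgers),
              paste(names(object@ledgers), collapse = ", "),
              object@horizon))
  for (nm in names(object@ledgers)) {
    led <- object@ledgers[[nm]]
    cat(sprintf("  %s: %d genes screened, %d pass\n", nm, nrow(led),
                sum(led$pass)))
  }
  cat(sprintf("  intersection (consistent direction): %d gene(s)%s\n",
              nrow(object@intersection),
              if (nrow(object@intersection))
                paste0(" — ", paste(object@intersection$gene_id,
                                    collapse = ", ")) else ""))
})
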