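.ELN_LEVELS <- c("favorable", "intermediate", "adverse")

#' Refine a categorical risk system with a binary expression marker
#'
#' Recategorizes patients by combining their base risk category (e.g. the
#' ELN favorable/intermediate/adverse classes) with a high/low expression
#' label. Under the default mapping, marker-high patients shift one level
#' toward adverse (favorable to intermediate, intermediate to adverse,
#' adverse stays adverse) while marker-low patients keep their base
#' category. Any total mapping can be supplied instead once a bespoke
#' scheme is wanted.
#'
#' @param baseGroups factor (or character) of ordered base categories, worst
#'   last; default levels are the ELN classes.
#' @param markerLabels two-level high/low labels aligned with
#'   \code{baseGroups} (e.g. from \code{\link{dichotomize}}).
#' @param mapping optional \code{data.frame} with columns \code{base},
#'   \code{marker}, \code{refined} covering every (base, marker)
#'   combination present; \code{NULL} uses the one-level-shift default.
#' @param levels ordered category levels when \code{baseGroups} is not a
#'   factor.
#' @return factor of refined categories (same ordering of levels), with the
#'   mapping used attached as attribute \code{"mapping"}.
#' @examples
#' base <- c("favorable", "intermediate", "adverse", "favorable")
#' marker <- c("high", "low", "high", "low")
#' refineRisk(base, marker)
#' @export
refineRisk <- function(baseGroups, markerLabels, mapping = NULL,
                       levels = .ELN_LEVELS) {
  if (!is.factor(baseGroups)) baseGroups <- factor(baseGroups, levels = levels)
  lv <- base::levels(baseGroups)
  if (anyNA(baseGroups)) stop("unknown base category present")
  markerLabels <- as.character(markerLabels)
  if (!all(markerLabels %in% c("high", "low")))
    stop("marker labels must be 'high'/'low'")
  stopifnot(length(baseGroups) == length(markerLabels))
  if (is.null(mapping)) {
    shifted <- lv[pmin(match(lv, lv) + 1L, length(lv))]
    mapping <- rbind(
      data.frame(base = lv, marker = "low", refined = lv,
                 stringsAsFactors = FALSE),
      data.frame(base = lv, marker = "high", refined = shifted,
                 stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(mapping),
            all(c("base", "marker", "refined") %in% colnames(mapping)))
  key <- paste(as.character(baseGroups), markerLabels, sep = "\r")
  mapKey <- paste(mapping$base, mapping$marker, sep = "\r")
  if (anyDuplicated(mapKey)) stop("duplicate (base, marker) rows in mapping")
  hit <- match(key, mapKey)
  if (anyNA(hit)) {
    bad <- unique(sub("\r", " + ", key[is.na(hit)]))
    stop("unmapped (base, marker) combination(s): ",
         paste(bad, collapse = ", "))
  }
  refined <- factor(mapping$refined[hit],
                    levels = unique(c(lv, mapping$refined)))
  names(refined) <- names(baseGroups)
  attr(refined, "mapping") <- mapping
  refined
}

#' Compare the stratification power of two groupings
#'
#' Evaluates two candidate groupings of the same samples (typically a base
#' risk system and its marker-refined version) on one survival endpoint:
#' Kaplan-Meier curve per category and the log-rank test across categories,
#' for each grouping. Categories with fewer than 2 samples are retained
#' with a warning; a grouping with a single category is an error (the
#' log-rank statistic has no degrees of freedom there).
#'
#' @param cohort a \linkS4class{SurvCohort}.
#' @param groupingA,groupingB factors aligned with the cohort samples.
#' @param endpoint survival endpoint (default \code{"OS"}).
#' @return object of class \code{"stratComparison"}: for each grouping a
#'   list of per-category \code{"kmcurve"}s and a \code{"logrank"} result.
#' @export
evaluateStratification <- function(cohort, groupingA, groupingB,
                                   endpoint = "OS") {
  surv <- endpointSurv(cohort, endpoint)
  stopifnot(length(groupingA) == ncol(cohort),
            length(groupingB) == ncol(cohort))
  evalOne <- function(g, label) {
    g <- droplevels(factor(g)[surv$keep])
    if (nlevels(g) < 2L)
      stop(sprintf("grouping '%s' has a single category: log-rank undefined",
                   label))
    small <- names(which(table(g) < 2L))
    if (length(small))
      warning(sprintf("grouping '%s': category with < 2 samples retained (%s)",
                      label, paste(small, collapse = ", ")), call. = FALSE)
    km <- lapply(split(seq_along(g), g), function(idx)
      kmEstimate(surv$time[idx], surv$event[idx]))
    list(km = km, logrank = logrankTest(surv$time, surv$event, g))
  }
  structure(list(base = evalOne(groupingA, "A"),
                 refined = evalOne(groupingB, "B"),
                 endpoint = endpoint, n = length(surv$time)),
            class = "stratComparison")
}

#' @export
print.stratComparison <- function(x, ...) {
  cat(sprintf("Stratification comparison (%s, n = %d)\n", x$endpoint, x$n))
  cat(sprintf("  base:    chi-square %.3f on %d df, p = %.4g\n",
              x$base$logrank$statistic, x$base$logrank$dof,
              x$base$logrank$p))
  cat(sprintf("  refined: chi-square %.3f on %d df, p = %.4g\n",
              x$refined$logrank$statistic, x$refined$logrank$dof,
              x$refined$logrank$p))
  invisible(x)
}

#' Marker hazard within treatment subgroups, with interaction
#'
#' Contrasts the marker's effect on survival between treatment arms (e.g.
#' transplanted vs chemotherapy-only patients): a univariate Cox fit of the
#' marker indicator within each subgroup, plus a pooled fit stratified by
#' treatment with the marker and a marker-by-treatment interaction term.
#' Stratification gives each arm its own baseline hazard, so the pooled
#' interaction model reparametrizes the two subgroup fits exactly: the
#' marker coefficient is the first arm's log hazard ratio, and marker +
#' interaction is the second arm's.
#'
#' @param cohort a \linkS4class{SurvCohort}.
#' @param markerLabels high/low labels aligned with the cohort samples.
#' @param treatmentColumn clinical column giving the arm (default
#'   \code{"treatment"}); must have exactly two observed levels, each with
#'   at least one event.
#' @param endpoint survival endpoint (default \code{"OS"}).
#' @return object of class \code{"subgroupHazard"}: \code{fits} (named list
#'   of per-arm \code{"coxfit"}s), \code{interaction} (the pooled
#'   stratified fit; coefficient \code{marker_x_arm2} is the log ratio of
#'   the arm-specific hazard ratios), \code{arms}.
#' @export
subgroupHazard <- function(cohort, markerLabels, treatmentColumn = "treatment",
                           endpoint = "OS") {
  cd <- clinicalData(cohort)
  if (!treatmentColumn %in% colnames(cd))
    stop("treatment column not in clinical table: ", treatmentColumn)
  surv <- endpointSurv(cohort, endpoint)
  arm <- factor(cd[[treatmentColumn]][surv$keep])
  arm <- droplevels(arm)
  if (nlevels(arm) != 2L)
    stop("treatment column must have exactly two observed levels")
  marker <- as.numeric(as.character(markerLabels)[surv$keep] == "high")
  if (stats::sd(marker) == 0) stop("marker labels are constant")
  arms <- levels(arm)
  fits <- lapply(arms, function(a) {
    idx <- which(arm == a)
    if (sum(surv$event[idx]) == 0)
      stop(sprintf("subgroup '%s' has zero events", a))
    coxFitPL(matrix(marker[idx], ncol = 1,
                    dimnames = list(NULL, "marker_high")),
             surv$time[idx], surv$event[idx])
  })
  names(fits) <- arms
  design <- cbind(marker_high = marker,
                  marker_x_arm2 = marker * (arm == arms[2L]))
  inter <- coxFitPL(design, surv$time, surv$event, strata = arm)
  structure(list(fits = fits, interaction = inter, arms = arms,
                 endpoint = endpoint), class = "subgroupHazard")
}

#' @export
print.subgroupHazard <- function(x, ...) {
  cat(sprintf("Marker hazard by treatment subgroup (%s)\n", x$endpoint))
  for (a in x$arms)
    cat(sprintf("  %s: HR = %.3f (p = %.4g, %d events)\n", a,
                x$fits[[a]]$hazardRatios[["marker_high"]],
                x$fits[[a]]$p[["marker_high"]], x$fits[[a]]$nEvent))
  cat(sprintf("  interaction log-HR (%s vs %s): %.3f (p = %.4g)\n",
              x$arms[2L], x$arms[1L],
              x$interaction$coefficients[["marker_x_arm2"]],
              x$interaction$p[["marker_x_arm2"]]))
  invisible(x)
}
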