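#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CLINICAL_LEVELS <- list(
  sex        = c("male", "female"),
  transplant = c("allo", "auto", "none"),
  eln        = c("favorable", "intermediate", "adverse"),
  treatment  = c("HSCT", "chemo_only"),
  cr_status  = c("CR/CRi", "refractory")
)

.ENDPOINT_COLS <- list(
  OS  = c("os_time",  "os_event"),
  DFS = c("dfs_time", "dfs_event"),
  EFS = c("efs_time", "efs_event")
)

#' Cohort container: expression matrix plus clinical survival table
#'
#' A \code{SurvCohort} extends \linkS4class{SummarizedExperiment}: the
#' \code{"exprs"} assay holds normalized log-scale expression (genes x
#' samples) and \code{colData} holds the clinical table (survival endpoints
#' and covariates). Sample identifiers of the two components are aligned by
#' construction; use the \code{\link{SurvCohort}} constructor, which
#' harmonizes them.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; cohort-level fields
#'   (name, ELN dialect, harmonization drop counts) live in
#'   \code{metadata()}.
#' @seealso \code{\link{SurvCohort}}, \code{\link{clinicalData}},
#'   \code{\link{availableEndpoints}}
#' @export
setClass("SurvCohort", contains = "SummarizedExperiment")

setValidity("SurvCohort", function(object) {
  msg <- character()
  if (nrow(object) == 0L || ncol(object) == 0L)
    msg <- c(msg, "cohort must contain at least one gene and one sample")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("os_time", "os_event") %in% colnames(cd))) {
    msg <- c(msg, "clinical table must provide os_time and os_event")
  } else {
    ot <- cd$os_time; oe <- cd$os_event
    if (!is.numeric(ot) || anyNA(ot) || any(ot <= 0))
      msg <- c(msg, "os_time must be strictly positive and complete")
    if (!all(oe %in% c(0, 1)))
      msg <- c(msg, "os_event must be 0/1")
  }
  for (v in names(.CLINICAL_LEVELS)) {
    if (v %in% colnames(cd)) {
      bad <- setdiff(unique(as.character(stats::na.omit(cd[[v]]))),
                     .CLINICAL_LEVELS[[v]])
      if (length(bad))
        msg <- c(msg, sprintf("unknown %s value(s): %s", v,
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Multi-cohort screen summary
#'
#' Result of \code{\link{intersectCohorts}}: the per-cohort gene ledgers
#' (one row per screened gene, with cutpoint, ROC metrics, Cox fits and the
#' five filter gates) together with the cross-cohort intersection — genes
#' that pass every gate in every cohort with a consistent effect direction.
#'
#' @slot ledgers named list of per-cohort ledger \code{data.frame}s as
#'   returned by \code{\link{screenCohort}}.
#' @slot intersection \code{data.frame} with columns \code{gene_id} and
#'   \code{direction} (\code{"high_is_worse"} or \code{"low_is_worse"}).
#' @slot horizon evaluation horizon in months shared by the ledgers.
#' @seealso \code{\link{screenCohort}}, \code{\link{intersectCohorts}}
#' @export
setClass("ScreenSummary",
  representation(ledgers = "list", intersection = "data.frame",
                 horizon = "numeric"))

setValidity("ScreenSummary", function(object) {
  msg <- character()
  if (length(object@ledgers) < 2L)
    msg <- c(msg, "at least two cohort ledgers required")
  if (!all(c("gene_id", "direction") %in% colnames(object@intersection)))
    msg <- c(msg, "intersection needs gene_id and direction columns")
  for (nm in names(object@ledgers)) {
    led <- object@ledgers[[nm]]
    passed <- led$gene_id[led$pass]
    if (!all(object@intersection$gene_id %in% passed))
      msg <- c(msg, sprintf(
        "intersection gene absent from pass set of cohort '%s'", nm))
  }
  if (length(msg)) msg else TRUE
})
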