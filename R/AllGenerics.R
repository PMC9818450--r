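#' @name survscreen-generics
#' @title Accessor generics for cohort and screen objects
#' @param x a \linkS4class{SurvCohort} or \linkS4class{ScreenSummary}.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname survscreen-generics
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname survscreen-generics
#' @export
setGeneric("elnDialect", function(x) standardGeneric("elnDialect"))

#' @rdname survscreen-generics
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname survscreen-generics
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname survscreen-generics
#' @export
setGeneric("availableEndpoints",
           function(x) standardGeneric("availableEndpoints"))

#' @rdname survscreen-generics
#' @export
setGeneric("intersectionGenes",
           function(x) standardGeneric("intersectionGenes"))

#' @rdname survscreen-generics
#' @param cohort cohort name.
#' @export
setGeneric("screenLedger",
           function(x, cohort, ...) standardGeneric("screenLedger"))
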