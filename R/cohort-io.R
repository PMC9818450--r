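#' Read a gene-expression matrix from delimited text
#'
#' Expects genes as rows (first column = gene identifier) and a header row
#' of sample identifiers; tab- or comma-delimited (auto-detected from the
#' header line). Values are normalized log-scale expression.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header line.
#' @param strict if \code{TRUE} (default) any missing or non-numeric cell is
#'   a hard error reporting its gene/sample coordinates.
#' @return numeric matrix (genes x samples) with dimnames in file order.
#' @export
readExpressionMatrix <- function(path, sep = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene-id column and at least one sample column")
  geneIds <- df[[1L]]
  sampleIds <- colnames(df)[-1L]
  dup <- geneIds[duplicated(geneIds)]
  if (length(dup)) stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sampleIds[duplicated(sampleIds)]
  if (length(dup)) stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(vals <- array(as.numeric(raw), dim = dim(raw)))
  if (strict && anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s' (value '%s')",
                 geneIds[bad[1L]], sampleIds[bad[2L]], raw[bad[1L], bad[2L]]))
  }
  dimnames(vals) <- list(geneIds, sampleIds)
  vals
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of \code{\link{readExpressionMatrix}}: gene ids in the first
#' column (\code{gene_id}), samples as remaining columns. Values are written
#' with full double precision so a read/write/read round trip is exact for
#' finite inputs.
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.TIME_FACTORS <- c(months = 1, days = 12 / 365.25, years = 12)

#' Read and validate a clinical survival table
#'
#' Loads a delimited clinical table, renames columns to the canonical schema
#' via \code{columnMap}, decodes categorical encodings, converts times to
#' months, and validates: survival times strictly positive, event flags in
#' \{0,1\}, categories among the known levels.
#'
#' Canonical fields: \code{sample_id}, \code{os_time}, \code{os_event}
#' (required); \code{dfs_time}/\code{dfs_event}, \code{efs_time}/
#' \code{efs_event}, \code{age}, \code{sex} (male/female), \code{wbc},
#' \code{transplant} (allo/auto/none), \code{eln}
#' (favorable/intermediate/adverse), \code{treatment} (HSCT/chemo_only),
#' \code{cr_status} (CR/CRi vs refractory) optional.
#'
#' @param path file path (tab- or comma-delimited, auto-detected).
#' @param columnMap named list/vector: canonical field -> file column name.
#'   Canonical names absent from the map but present verbatim in the file
#'   are picked up automatically.
#' @param encodings named list of recode maps for categorical fields, e.g.
#'   \code{list(sex = c("0" = "female", "1" = "male"))}.
#' @param timeUnit unit of the time columns in the file: \code{"months"}
#'   (default), \code{"days"} or \code{"years"}; converted to months.
#' @return \code{data.frame} with canonical columns, one row per sample,
#'   rownames = sample ids.
#' @export
readClinicalTable <- function(path, columnMap = list(), encodings = list(),
                              timeUnit = c("months", "days", "years")) {
  timeUnit <- match.arg(timeUnit)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  canonical <- c("sample_id", unlist(.ENDPOINT_COLS, use.names = FALSE),
                 "age", "sex", "wbc", "transplant", "eln", "treatment",
                 "cr_status")
  out <- list()
  for (field in canonical) {
    src <- if (!is.null(columnMap[[field]])) columnMap[[field]]
           else if (field %in% colnames(df)) field else NA_character_
    if (is.na(src)) next
    if (!src %in% colnames(df))
      stop(sprintf("mapped column '%s' for field '%s' not in file", src, field))
    out[[field]] <- df[[src]]
  }
  for (req in c("sample_id", "os_time", "os_event"))
    if (is.null(out[[req]])) stop("mandatory field missing: ", req)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id))
    stop("duplicated sample id(s): ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  for (v in intersect(names(encodings), colnames(out))) {
    code <- encodings[[v]]
    out[[v]] <- unname(code[as.character(out[[v]])])
  }
  fac <- .TIME_FACTORS[[timeUnit]]
  for (ep in names(.ENDPOINT_COLS)) {
    tc <- .ENDPOINT_COLS[[ep]][1L]; ec <- .ENDPOINT_COLS[[ep]][2L]
    if (is.null(out[[tc]]) != is.null(out[[ec]]))
      stop(sprintf("endpoint %s needs both %s and %s", ep, tc, ec))
    if (is.null(out[[tc]])) next
    out[[tc]] <- as.numeric(out[[tc]]) * fac
    keep <- !is.na(out[[tc]])
    if (any(out[[tc]][keep] <= 0))
      stop(sprintf("%s must be strictly positive (offending sample: %s)", tc,
                   out$sample_id[keep & out[[tc]] <= 0][1L]))
    ev <- out[[ec]][!is.na(out[[ec]])]
    if (!all(ev %in% c(0, 1)))
      stop(sprintf("%s must be 0/1", ec))
  }
  for (v in names(.CLINICAL_LEVELS)) {
    if (is.null(out[[v]])) next
    bad <- setdiff(unique(as.character(stats::na.omit(out[[v]]))),
                   .CLINICAL_LEVELS[[v]])
    if (length(bad))
      stop(sprintf("unknown %s value(s): %s (declare an encoding)", v,
                   paste(bad, collapse = ", ")))
  }
  rownames(out) <- out$sample_id
  attr(out, "endpoints") <- names(Filter(function(cols)
    all(cols %in% colnames(out)), .ENDPOINT_COLS))
  out
}

#' Build a harmonized cohort from expression and clinical components
#'
#' Restricts both components to the shared sample ids (kept in expression
#' order), reports how many samples each side dropped, and returns a
#' validated \linkS4class{SurvCohort}.
#'
#' @param expression numeric matrix genes x samples (see
#'   \code{\link{readExpressionMatrix}}).
#' @param clinical clinical \code{data.frame} with a \code{sample_id} column
#'   (see \code{\link{readClinicalTable}}).
#' @param name cohort name.
#' @param elnDialect which ELN classification the \code{eln} column follows.
#' @return a \linkS4class{SurvCohort}.
#' @examples
#' expr <- matrix(rnorm(12), 3, 4,
#'                dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' clin <- data.frame(sample_id = paste0("S", 1:4),
#'                    os_time = c(10, 20, 5, 30), os_event = c(1, 0, 1, 0))
#' co <- SurvCohort(expr, clin, name = "toy")
#' availableEndpoints(co)
#' @export
SurvCohort <- function(expression, clinical, name = "cohort",
                       elnDialect = c("ELN2017", "ELN2010")) {
  elnDialect <- match.arg(elnDialect)
  stopifnot(is.matrix(expression), is.data.frame(clinical),
            "sample_id" %in% colnames(clinical))
  shared <- intersect(colnames(expression), clinical$sample_id)
  if (!length(shared))
    stop("expression and clinical tables share no sample ids")
  dropExpr <- ncol(expression) - length(shared)
  dropClin <- nrow(clinical) - length(shared)
  if (dropExpr + dropClin > 0)
    message(sprintf("harmonize [%s]: dropped %d expression-only and %d clinical-only sample(s)",
                    name, dropExpr, dropClin))
  expression <- expression[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- clinical$sample_id
  eps <- names(Filter(function(cols) all(cols %in% colnames(clinical)),
                      .ENDPOINT_COLS))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expression),
    colData = S4Vectors::DataFrame(clinical[, setdiff(colnames(clinical), "sample_id"),
                                            drop = FALSE],
                                   row.names = shared))
  obj <- methods::new("SurvCohort", se)
  metadata(obj)$cohortName <- name
  metadata(obj)$elnDialect <- elnDialect
  metadata(obj)$endpoints <- eps
  metadata(obj)$dropped <- c(expression = dropExpr, clinical = dropClin)
  methods::validObject(obj)
  obj
}

#' @rdname survscreen-generics
#' @export
setMethod("cohortName", "SurvCohort", function(x) metadata(x)$cohortName)

#' @rdname survscreen-generics
#' @export
setMethod("elnDialect", "SurvCohort", function(x) metadata(x)$elnDialect)

#' @rdname survscreen-generics
#' @export
setMethod("clinicalData", "SurvCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname survscreen-generics
#' @export
setMethod("exprsMatrix", "SurvCohort", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname survscreen-generics
#' @export
setMethod("availableEndpoints", "SurvCohort", function(x)
  metadata(x)$endpoints)

setMethod("show", "SurvCohort", function(object) {
  cat(sprintf("SurvCohort '%s' (%s): %d genes x %d samples\n",
              cohortName(object), elnDialect(object),
              nrow(object), ncol(object)))
  cd <- clinicalData(object)
  cat(sprintf("  endpoints: %s | events (OS): %d/%d\n",
              paste(availableEndpoints(object), collapse = ", "),
              sum(cd$os_event), nrow(cd)))
  cat(sprintf("  clinical covariates: %s\n",
              paste(setdiff(colnames(cd),
                            unlist(.ENDPOINT_COLS, use.names = FALSE)),
                    collapse = ", ")))
})

#' Extract a survival endpoint from a cohort
#'
#' @param cohort a \linkS4class{SurvCohort}.
#' @param endpoint one of \code{"OS"}, \code{"DFS"}, \code{"EFS"}.
#' @return list with \code{time}, \code{event} and the index of samples with
#'   complete endpoint data (\code{keep}).
#' @export
endpointSurv <- function(cohort, endpoint = c("OS", "DFS", "EFS")) {
  endpoint <- match.arg(endpoint)
  if (!endpoint %in% availableEndpoints(cohort))
    stop(sprintf("endpoint %s not available in cohort '%s'", endpoint,
                 cohortName(cohort)))
  cols <- .ENDPOINT_COLS[[endpoint]]
  cd <- clinicalData(cohort)
  time <- cd[[cols[1L]]]; event <- cd[[cols[2L]]]
  keep <- which(!is.na(time) & !is.na(event))
  list(time = time[keep], event = event[keep], keep = keep)
}

#' Dichotomize a continuous marker at a cutpoint
#'
#' Samples with value strictly greater than the cutpoint are labelled
#' \code{"high"}; ties at the cutpoint go to \code{"low"}. The cutpoint must
#' lie strictly inside the observed range so that both groups are non-empty.
#' Labels are rank-based, hence invariant under any strictly increasing
#' transform applied jointly to values and cutpoint.
#'
#' @param values named numeric vector (names = sample ids).
#' @param cutpoint numeric threshold.
#' @param geneId optional marker identifier carried in the result.
#' @return factor with levels \code{c("low", "high")}, names preserved, and
#'   attributes \code{cutpoint} and \code{geneId}.
#' @examples
#' dichotomize(c(a = 1, b = 2, c = 3, d = 4), 2.5)
#' @export
dichotomize <- function(values, cutpoint, geneId = NA_character_) {
  stopifnot(is.numeric(values), length(values) >= 2L, is.finite(cutpoint))
  high <- values > cutpoint
  if (all(high)) stop("cutpoint below the observed range: low group empty")
  if (!any(high)) stop("cutpoint at or above the observed range: high group empty")
  labels <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  names(labels) <- names(values)
  attr(labels, "cutpoint") <- cutpoint
  attr(labels, "geneId") <- geneId
  labels
}
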