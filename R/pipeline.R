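#' Read and validate a pipeline run configuration
#'
#' The run config is a JSON or YAML file (or an equivalent named list)
#' declaring either a \code{simulate} block (multi-cohort generator
#' settings) or a \code{cohorts} list (paths + column maps for on-disk
#' expression/clinical tables), plus the screening settings: endpoint,
#' horizon, gate thresholds, confounders, optional refinement block, seed
#' and output directory. Validation happens before any data file is
#' touched.
#'
#' @param config path to a JSON/YAML file, or a named list.
#' @return the validated config list (class \code{"runConfig"}).
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  defaults <- list(endpoint = "OS", horizon = 36,
                   gates = list(auc = 0.5, sens = 0.5, spec = 0.5,
                                alpha = 0.05),
                   confounders = as.list(.DEFAULT_CONFOUNDERS),
                   gate_mode = "strict", band = c(0.1, 0.9), seed = 1L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in names(defaults$gates))
    if (is.null(config$gates[[k]])) config$gates[[k]] <- defaults$gates[[k]]
  g <- config$gates
  for (k in c("auc", "sens", "spec", "alpha"))
    if (!is.numeric(g[[k]]) || g[[k]] <= 0 || g[[k]] >= 1)
      stop(sprintf("gate threshold '%s' must lie in (0, 1), got %s",
                   k, format(g[[k]])))
  if (!config$endpoint %in% names(.ENDPOINT_COLS))
    stop("endpoint must be one of OS, DFS, EFS")
  if (!is.numeric(config$horizon) || config$horizon <= 0)
    stop("horizon must be a positive number of months")
  if (!config$gate_mode %in% c("strict", "uniThenRetain"))
    stop("gate_mode must be 'strict' or 'uniThenRetain'")
  hasSim <- !is.null(config$simulate)
  hasCohorts <- !is.null(config$cohorts) && length(config$cohorts)
  if (hasSim == hasCohorts)
    stop("config must declare exactly one of 'simulate' or 'cohorts'")
  if (hasCohorts) {
    for (co in config$cohorts) {
      for (f in c("name", "expression", "clinical"))
        if (is.null(co[[f]])) stop("cohort declaration missing field: ", f)
      for (f in c("expression", "clinical"))
        if (!file.exists(co[[f]]))
          stop(sprintf("declared path does not exist (%s): %s", f, co[[f]]))
    }
  }
  structure(config, class = c("runConfig", "list"))
}

.loadConfigCohorts <- function(config) {
  if (!is.null(config$simulate)) {
    sb <- config$simulate
    cfgs <- trioConfigs(
      nGenes = if (is.null(sb$n_genes)) 200 else sb$n_genes,
      plantedBeta = if (is.null(sb$planted_beta)) log(2.5) else sb$planted_beta,
      censoringFraction = if (is.null(sb$censoring_fraction)) 0.35
        else sb$censoring_fraction,
      nSamples = if (is.null(sb$n_samples)) c(69, 77, 134)
        else unlist(sb$n_samples))
    lapply(simulateCohortSet(cfgs, masterSeed = config$seed), `[[`, "cohort")
  } else {
    lapply(config$cohorts, function(co) {
      expr <- readExpressionMatrix(co$expression)
      clin <- readClinicalTable(
        co$clinical,
        columnMap = if (is.null(co$column_map)) list() else co$column_map,
        encodings = if (is.null(co$encodings)) list()
          else lapply(co$encodings, unlist),
        timeUnit = if (is.null(co$time_unit)) "months" else co$time_unit)
      SurvCohort(expr, clin, name = co$name,
                 elnDialect = if (is.null(co$eln_dialect)) "ELN2017"
                 else co$eln_dialect)
    })
  }
}

.writeTsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the end-to-end screening pipeline
#'
#' Loads (or simulates) every declared cohort, screens all genes per cohort,
#' intersects the hits across cohorts, and for each intersection gene
#' exports Kaplan-Meier tables by expression group, a forest-plot table of
#' the confounder-adjusted Cox fit, and (when ELN categories are present) a
#' base-vs-refined stratification comparison. Outputs are written
#' all-or-nothing: files land in a temporary directory that is renamed to
#' \code{outDir} only on success, so an aborted run leaves no partial
#' output. The run manifest (\code{manifest.json}: config echo, seed,
#' package version) is sufficient to reproduce every output byte-for-byte
#' via \code{\link{rerunFromManifest}}.
#'
#' @param config run configuration: path or list (see
#'   \code{\link{readRunConfig}}).
#' @param outDir output directory; must not already exist unless
#'   \code{overwrite = TRUE}.
#' @param overwrite replace an existing output directory.
#' @param verbose emit progress messages.
#' @return a \linkS4class{ScreenSummary}, invisibly; side effect: the
#'   report bundle in \code{outDir}.
#' @export
runScreenPipeline <- function(config, outDir = config$out_dir,
                              overwrite = FALSE, verbose = TRUE) {
  config <- readRunConfig(config)
  # canonicalize through the manifest serialization before computing, so a
  # manifest-driven re-run consumes bit-identical parameter values
  config <- readRunConfig(jsonlite::fromJSON(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                     null = "null"),
    simplifyDataFrame = FALSE))
  if (is.null(outDir)) stop("no output directory given (out_dir)")
  if (dir.exists(outDir)) {
    if (!overwrite) stop("output directory exists: ", outDir)
  }
  tmp <- paste0(outDir, ".partial")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  cohorts <- .loadConfigCohorts(config)
  screens <- lapply(cohorts, function(co)
    screenCohort(co,
                 confounders = unlist(config$confounders),
                 horizon = config$horizon,
                 alpha = config$gates$alpha, aucGate = config$gates$auc,
                 sensGate = config$gates$sens, specGate = config$gates$spec,
                 band = unlist(config$band), endpoint = config$endpoint,
                 gateMode = config$gate_mode, verbose = verbose))
  summary <- intersectCohorts(screens)

  for (nm in names(summary@ledgers))
    .writeTsv(summary@ledgers[[nm]],
              file.path(tmp, sprintf("ledger_%s.tsv", nm)))
  .writeTsv(summary@intersection, file.path(tmp, "intersection.tsv"))

  for (i in seq_len(nrow(summary@intersection))) {
    gene <- summary@intersection$gene_id[i]
    kmRows <- list(); forestRows <- list(); refRows <- list()
    for (j in seq_along(cohorts)) {
      co <- cohorts[[j]]
      led <- summary@ledgers[[cohortName(co)]]
      cut <- led$cutpoint[led$gene_id == gene]
      labels <- dichotomize(exprsMatrix(co)[gene, ], cut, geneId = gene)
      surv <- endpointSurv(co, config$endpoint)
      for (lev in levels(labels)) {
        pos <- which(labels[surv$keep] == lev)
        km <- kmEstimate(surv$time[pos], surv$event[pos])
        kmRows[[length(kmRows) + 1L]] <-
          data.frame(cohort = cohortName(co), group = lev, kmTable(km))
      }
      cd <- clinicalData(co)[surv$keep, , drop = FALSE]
      conf <- .confounderMatrix(cd, unlist(config$confounders))
      design <- cbind(marker_high = as.numeric(
        exprsMatrix(co)[gene, surv$keep] > cut), conf$x)
      cc <- stats::complete.cases(design)
      fit <- coxFitPL(design[cc, , drop = FALSE], surv$time[cc],
                      surv$event[cc])
      forestRows[[length(forestRows) + 1L]] <-
        data.frame(cohort = cohortName(co), coxForestTable(fit))
      if ("eln" %in% colnames(clinicalData(co))) {
        refined <- refineRisk(clinicalData(co)$eln, as.character(labels))
        comp <- evaluateStratification(co, factor(clinicalData(co)$eln,
                                                  levels = .ELN_LEVELS),
                                       refined, endpoint = config$endpoint)
        refRows[[length(refRows) + 1L]] <- data.frame(
          cohort = cohortName(co),
          base_chisq = comp$base$logrank$statistic,
          base_p = comp$base$logrank$p,
          refined_chisq = comp$refined$logrank$statistic,
          refined_p = comp$refined$logrank$p)
      }
    }
    .writeTsv(do.call(rbind, kmRows), file.path(tmp, sprintf("km_%s.tsv", gene)))
    .writeTsv(do.call(rbind, forestRows),
              file.path(tmp, sprintf("forest_%s.tsv", gene)))
    if (length(refRows))
      .writeTsv(do.call(rbind, refRows),
                file.path(tmp, sprintf("refinement_%s.tsv", gene)))
  }

  manifest <- list(package = "survscreen",
                   version = as.character(utils::packageVersion("survscreen")),
                   config = unclass(config))
  manifest$config$out_dir <- NULL
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  if (dir.exists(outDir)) unlink(outDir, recursive = TRUE)
  if (!file.rename(tmp, outDir))
    stop("could not move results into place: ", outDir)
  on.exit()
  if (verbose)
    message(sprintf("pipeline: report written to %s (%d intersection gene(s))",
                    outDir, nrow(summary@intersection)))
  invisible(summary)
}

#' Re-run a pipeline from its manifest
#'
#' Reads the config echoed in a run's \code{manifest.json} and executes the
#' pipeline again; with the packaged deterministic generator and seeded
#' config this reproduces every output file byte-identically.
#'
#' @param manifestPath path to a \code{manifest.json}.
#' @param outDir output directory for the re-run.
#' @param ... passed to \code{\link{runScreenPipeline}}.
#' @return a \linkS4class{ScreenSummary}, invisibly.
#' @export
rerunFromManifest <- function(manifestPath, outDir, ...) {
  manifest <- jsonlite::fromJSON(manifestPath, simplifyDataFrame = FALSE)
  if (is.null(manifest$config)) stop("manifest has no config echo")
  runScreenPipeline(manifest$config, outDir = outDir, ...)
}
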