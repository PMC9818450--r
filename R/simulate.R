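.DEFAULT_CONFOUNDER_BETAS <- c(age = 0.02, sex_male = 0.1, wbc = 0.004,
                               transplant_allo = -0.1,
                               eln_intermediate = 0.4, eln_adverse = 0.8)

#' Configuration for a simulated survival cohort
#'
#' Declares one cohort of the Weibull proportional-hazards simulator:
#' gene-wise standard-normal log-expression; clinical covariates drawn from
#' realistic marginals (age truncated-normal 55 +/- 12 on [18, 80], sex
#' Bernoulli(0.5), WBC log-normal, transplant type allo/auto, ELN
#' categorical favorable/intermediate/adverse with weights 0.25/0.5/0.25);
#' and right-censored event times from a Weibull baseline multiplied by
#' exp(linear predictor). Planted genes act on the continuous per-SD
#' expression scale, so dichotomization performance is emergent, not baked
#' in. Censoring is administrative (uniform), calibrated exactly to the
#' target fraction.
#'
#' @param name cohort name.
#' @param nSamples number of samples.
#' @param nGenes number of genes (>= number of planted genes).
#' @param plantedGenes \code{data.frame} with columns \code{gene_id} and
#'   \code{beta} (log hazard ratio per SD of expression); may be empty.
#' @param confounderBetas named log-hazard coefficients for the clinical
#'   covariates (age and WBC per unit, centered at 55 years and 15 x 10^9/L;
#'   indicators for male sex, allo transplant, and the two non-favorable ELN
#'   classes).
#' @param weibullShape,weibullScale baseline Weibull shape and scale
#'   (months); the defaults (1.1, 40) put the baseline median near 29
#'   months, typical of adult AML trial cohorts.
#' @param censoringFraction target fraction of censored samples in [0, 1).
#' @param interaction optional \code{list(gene_id =, arm =, beta =)}: extra
#'   per-SD log hazard for that gene restricted to one treatment arm.
#' @param probHSCT probability a sample is in the HSCT arm (default 1: a
#'   fully transplanted cohort).
#' @param probAllo probability an HSCT sample received an allograft.
#' @param elnDialect ELN classification dialect label for the cohort.
#' @param seed default RNG seed used by \code{\link{simulateCohort}}.
#' @return validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(name = "sim", nSamples = 100, nGenes = 200,
                      plantedGenes = data.frame(gene_id = character(),
                                                beta = numeric()),
                      confounderBetas = .DEFAULT_CONFOUNDER_BETAS,
                      weibullShape = 1.1, weibullScale = 40,
                      censoringFraction = 0.35, interaction = NULL,
                      probHSCT = 1, probAllo = 0.7,
                      elnDialect = "ELN2017", seed = 1L) {
  stopifnot(nSamples >= 2, nGenes >= 1, weibullShape > 0, weibullScale > 0,
            censoringFraction >= 0, censoringFraction < 1,
            probHSCT >= 0, probHSCT <= 1, probAllo >= 0, probAllo <= 1)
  stopifnot(is.data.frame(plantedGenes),
            all(c("gene_id", "beta") %in% colnames(plantedGenes)),
            nrow(plantedGenes) <= nGenes)
  if (!is.null(interaction))
    stopifnot(is.list(interaction),
              all(c("gene_id", "arm", "beta") %in% names(interaction)))
  structure(list(name = name, nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes), plantedGenes = plantedGenes,
                 confounderBetas = confounderBetas,
                 weibullShape = weibullShape, weibullScale = weibullScale,
                 censoringFraction = censoringFraction,
                 interaction = interaction, probHSCT = probHSCT,
                 probAllo = probAllo, elnDialect = elnDialect,
                 seed = as.integer(seed)),
            class = "simConfig")
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Generate one synthetic cohort with known ground truth
#'
#' Draws a cohort under \code{config} (see \code{\link{simConfig}}): event
#' times follow a Weibull proportional-hazards model whose linear predictor
#' sums the planted per-SD gene effects, the confounder effects and any
#' arm-restricted interaction; administrative censoring times are uniform
#' with the upper bound calibrated so the realized censored fraction equals
#' the target exactly (to rounding by 1/n). All times are in months and
#' continuous, so ties do not occur. The same config and seed reproduce the
#' cohort bit-identically.
#'
#' @param config a \code{"simConfig"}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return list with elements \code{cohort} (a \linkS4class{SurvCohort})
#'   and \code{truth} (class \code{"syntheticTruth"}: planted genes and
#'   true coefficients, censoring scheme, realized censoring fraction,
#'   seed).
#' @examples
#' cfg <- simConfig(nSamples = 60, nGenes = 20,
#'                  plantedGenes = data.frame(gene_id = "G0001",
#'                                            beta = log(2.5)))
#' sim <- simulateCohort(cfg, seed = 42)
#' sim$truth$realizedCensoring
#' @export
simulateCohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(seed)
  n <- config$nSamples; g <- config$nGenes
  geneIds <- sprintf("G%04d", seq_len(g))
  bad <- setdiff(config$plantedGenes$gene_id, geneIds)
  if (length(bad)) stop("planted gene id(s) outside the gene set: ",
                        paste(bad, collapse = ", "))
  sampleIds <- sprintf("%s_S%03d", config$name, seq_len(n))
  expr <- matrix(stats::rnorm(g * n), g, n,
                 dimnames = list(geneIds, sampleIds))
  age <- .rtruncnorm(n, 55, 12, 18, 80)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
  wbc <- stats::rlnorm(n, meanlog = log(15), sdlog = 0.8)
  treatment <- ifelse(stats::rbinom(n, 1, config$probHSCT) == 1,
                      "HSCT", "chemo_only")
  transplant <- ifelse(treatment == "HSCT",
                       ifelse(stats::rbinom(n, 1, config$probAllo) == 1,
                              "allo", "auto"),
                       "none")
  eln <- sample(.ELN_LEVELS, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))

  cb <- config$confounderBetas
  cb <- cb[names(cb) %in% names(.DEFAULT_CONFOUNDER_BETAS)]
  eta <- rep(0, n)
  if (!is.na(cb["age"]))     eta <- eta + cb[["age"]] * (age - 55)
  if (!is.na(cb["sex_male"])) eta <- eta + cb[["sex_male"]] * (sex == "male")
  if (!is.na(cb["wbc"]))     eta <- eta + cb[["wbc"]] * (wbc - 15)
  if (!is.na(cb["transplant_allo"]))
    eta <- eta + cb[["transplant_allo"]] * (transplant == "allo")
  if (!is.na(cb["eln_intermediate"]))
    eta <- eta + cb[["eln_intermediate"]] * (eln == "intermediate")
  if (!is.na(cb["eln_adverse"]))
    eta <- eta + cb[["eln_adverse"]] * (eln == "adverse")
  for (i in seq_len(nrow(config$plantedGenes)))
    eta <- eta + config$plantedGenes$beta[i] *
      expr[config$plantedGenes$gene_id[i], ]
  if (!is.null(config$interaction)) {
    ia <- config$interaction
    if (!ia$gene_id %in% geneIds) stop("interaction gene outside the gene set")
    eta <- eta + ia$beta * expr[ia$gene_id, ] * (treatment == ia$arm)
  }

  u <- stats::runif(n)
  eventTime <- config$weibullScale *
    (-log(u) / exp(eta))^(1 / config$weibullShape)

  if (config$censoringFraction == 0) {
    time <- eventTime; event <- rep(1, n); cmax <- Inf
  } else {
    # exact calibration: censored iff cmax * uc < T, i.e. cmax < T/uc;
    # place cmax between order statistics of T/uc to censor exactly k samples
    uc <- stats::runif(n)
    ratio <- eventTime / uc
    k <- min(round(config$censoringFraction * n), n - 1L)
    rs <- sort(ratio, decreasing = TRUE)
    cmax <- if (k == 0L) rs[1L] * 2 else (rs[k] + rs[k + 1L]) / 2
    cens <- cmax * uc
    event <- as.numeric(eventTime <= cens)
    time <- pmin(eventTime, cens)
  }

  clinical <- data.frame(sample_id = sampleIds, os_time = unname(time),
                         os_event = unname(event), age = age, sex = sex,
                         wbc = wbc, transplant = transplant, eln = eln,
                         treatment = treatment, stringsAsFactors = FALSE)
  cohort <- SurvCohort(expr, clinical, name = config$name,
                       elnDialect = config$elnDialect)
  truth <- structure(list(
    planted = config$plantedGenes,
    interaction = config$interaction,
    confounderBetas = cb,
    weibullShape = config$weibullShape,
    weibullScale = config$weibullScale,
    censoringMax = cmax,
    targetCensoring = config$censoringFraction,
    realizedCensoring = 1 - mean(event),
    seed = seed, name = config$name), class = "syntheticTruth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.syntheticTruth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth [%s, seed %d]: %d planted gene(s), censoring %.2f (target %.2f)\n",
              x$name, x$seed, nrow(x$planted), x$realizedCensoring,
              x$targetCensoring))
  invisible(x)
}

#' Generate several independent cohorts sharing a gene space
#'
#' Emulates a multi-cohort study: each config keeps its own sample size,
#' censoring and dialect, all share the gene identifiers (equal
#' \code{nGenes}) and hence the planted genes, and per-cohort seeds are
#' split deterministically from one master seed.
#'
#' @param configs list of \code{"simConfig"}s (>= 2) with equal
#'   \code{nGenes}.
#' @param masterSeed integer master seed.
#' @return list with one \code{list(cohort, truth)} element per config,
#'   named by cohort.
#' @export
simulateCohortSet <- function(configs, masterSeed = 1L) {
  stopifnot(is.list(configs), length(configs) >= 2L)
  if (length(unique(vapply(configs, `[[`, integer(1), "nGenes"))) != 1L)
    stop("configs must share the same number of genes")
  set.seed(masterSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(configs))
  out <- Map(function(cfg, s) simulateCohort(cfg, seed = s), configs, seeds)
  names(out) <- vapply(configs, `[[`, character(1), "name")
  out
}

#' Default three-cohort study configuration
#'
#' A trio of configs sized 69, 77 and 134 samples — the power regime of a
#' typical multi-cohort post-transplant AML study — sharing one planted
#' prognostic gene (\code{"G0001"} by default, per-SD log hazard ratio
#' \code{log(2.5)}) and 35\% censoring.
#'
#' @param nGenes genes per cohort (default 200).
#' @param plantedBeta per-SD log hazard ratio of the planted gene; 0 gives
#'   a pure-null trio with no planted gene.
#' @param censoringFraction target censoring fraction (default 0.35).
#' @param nSamples the three cohort sizes.
#' @param ... further arguments passed to \code{\link{simConfig}}.
#' @return list of three \code{"simConfig"}s.
#' @export
trioConfigs <- function(nGenes = 200, plantedBeta = log(2.5),
                        censoringFraction = 0.35,
                        nSamples = c(69, 77, 134), ...) {
  planted <- if (plantedBeta != 0)
    data.frame(gene_id = "G0001", beta = plantedBeta,
               stringsAsFactors = FALSE)
  else data.frame(gene_id = character(), beta = numeric())
  dialects <- rep(c("ELN2010", "ELN2017"), length.out = length(nSamples))
  Map(function(i, n, d) simConfig(name = sprintf("cohort%d", i),
                                  nSamples = n, nGenes = nGenes,
                                  plantedGenes = planted,
                                  censoringFraction = censoringFraction,
                                  elnDialect = d, ...),
      seq_along(nSamples), nSamples, dialects)
}

#' Write a simulated cohort as the plain-text formats the loaders read
#'
#' @param sim a \code{list(cohort, truth)} from \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return paths of the written files (expression, clinical, truth),
#'   invisibly.
#' @export
writeCohortFiles <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  name <- sim$truth$name
  ep <- file.path(dir, paste0(name, "_expression.tsv"))
  cp <- file.path(dir, paste0(name, "_clinical.tsv"))
  tp <- file.path(dir, paste0(name, "_truth.tsv"))
  writeExpressionMatrix(exprsMatrix(sim$cohort), ep)
  clin <- clinicalData(sim$cohort)
  clin <- data.frame(sample_id = rownames(clin), clin,
                     stringsAsFactors = FALSE)
  utils::write.table(clin, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  truthDf <- if (nrow(sim$truth$planted))
    data.frame(sim$truth$planted, seed = sim$truth$seed,
               realized_censoring = sim$truth$realizedCensoring)
  else data.frame(gene_id = NA, beta = NA, seed = sim$truth$seed,
                  realized_censoring = sim$truth$realizedCensoring)
  utils::write.table(truthDf, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = ep, clinical = cp, truth = tp))
}
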