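test_that("the generator is bit-identical under a fixed config and seed", {
  cfg <- simConfig(name = "det", nSamples = 50, nGenes = 10,
                   plantedGenes = data.frame(gene_id = "G0002", beta = 0.5))
  a <- simulateCohort(cfg, seed = 99)
  b <- simulateCohort(cfg, seed = 99)
  expect_identical(exprsMatrix(a$cohort), exprsMatrix(b$cohort))
  expect_identical(clinicalData(a$cohort), clinicalData(b$cohort))
  expect_identical(a$truth$censoringMax, b$truth$censoringMax)
  c <- simulateCohort(cfg, seed = 100)
  expect_false(identical(exprsMatrix(a$cohort), exprsMatrix(c$cohort)))
})

test_that("a zero censoring target yields all events", {
  cfg <- simConfig(name = "nocens", nSamples = 80, nGenes = 5,
                   censoringFraction = 0)
  sim <- simulateCohort(cfg, seed = 7)
  expect_true(all(clinicalData(sim$cohort)$os_event == 1))
  expect_equal(sim$truth$realizedCensoring, 0)
})

test_that("realized censoring tracks the target", {
  fr <- vapply(1:20, function(s) {
    cfg <- simConfig(name = "cal", nSamples = 120, nGenes = 5,
                     censoringFraction = 0.35)
    simulateCohort(cfg, seed = s)$truth$realizedCensoring
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.35), 0.05)
  expect_true(all(abs(fr - 0.35) < 0.05))
})

test_that("a correctly specified Cox fit recovers the planted coefficient", {
  beta <- log(2.5)
  cfg <- simConfig(name = "rec", nSamples = 2000, nGenes = 5,
                   plantedGenes = data.frame(gene_id = "G0001", beta = beta))
  sim <- simulateCohort(cfg, seed = 17)
  co <- sim$cohort
  cd <- clinicalData(co)
  design <- cbind(g = exprsMatrix(co)["G0001", ],
                  age = cd$age - 55, sex = as.numeric(cd$sex == "male"),
                  wbc = cd$wbc - 15,
                  allo = as.numeric(cd$transplant == "allo"),
                  eint = as.numeric(cd$eln == "intermediate"),
                  eadv = as.numeric(cd$eln == "adverse"))
  fit <- coxFitPL(design, cd$os_time, cd$os_event)
  expect_lt(abs(fit$coefficients[["g"]] - beta) / beta, 0.1)
})

test_that("the null configuration matches the closed-form Weibull survival", {
  cfg <- simConfig(name = "wb", nSamples = 2000, nGenes = 2,
                   confounderBetas = c(age = 0), censoringFraction = 0,
                   weibullShape = 1.1, weibullScale = 40)
  sim <- simulateCohort(cfg, seed = 23)
  t <- clinicalData(sim$cohort)$os_time
  ks <- suppressWarnings(
    ks.test(t, function(q) pweibull(q, shape = 1.1, scale = 40)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("null cohorts give nominal log-rank rejection on median splits", {
  rejections <- vapply(1:200, function(s) {
    cfg <- simConfig(name = "nullcal", nSamples = 2000, nGenes = 3,
                     confounderBetas = c(age = 0), censoringFraction = 0.3)
    sim <- simulateCohort(cfg, seed = 5000 + s)
    co <- sim$cohort
    g <- exprsMatrix(co)["G0001", ] > median(exprsMatrix(co)["G0001", ])
    logrankTest(clinicalData(co)$os_time, clinicalData(co)$os_event,
                g)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
})

test_that("multi-cohort generation honors sizes, shares genes, reproduces", {
  cfgs <- trioConfigs(nGenes = 12)
  sims <- simulateCohortSet(cfgs, masterSeed = 3)
  expect_equal(vapply(sims, function(s) ncol(s$cohort), numeric(1),
                      USE.NAMES = FALSE), c(69, 77, 134))
  expect_identical(rownames(sims[[1]]$cohort), rownames(sims[[3]]$cohort))
  sims2 <- simulateCohortSet(cfgs, masterSeed = 3)
  expect_identical(exprsMatrix(sims[[2]]$cohort),
                   exprsMatrix(sims2[[2]]$cohort))
  expect_error(simulateCohortSet(list(simConfig(nGenes = 5),
                                      simConfig(nGenes = 6))),
               "same number of genes")
})

test_that("simulated cohorts round-trip through the plain-text loaders", {
  cfg <- simConfig(name = "rt", nSamples = 30, nGenes = 8)
  sim <- simulateCohort(cfg, seed = 29)
  dir <- withr::local_tempdir()
  paths <- writeCohortFiles(sim, dir)
  expr <- readExpressionMatrix(paths[["expression"]])
  clin <- readClinicalTable(paths[["clinical"]])
  co <- SurvCohort(expr, clin, name = "rt")
  expect_equal(exprsMatrix(co), exprsMatrix(sim$cohort))
  expect_equal(clinicalData(co)$os_time, clinicalData(sim$cohort)$os_time)
})
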