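test_that("the default refinement shifts marker-high one level toward adverse", {
  base <- c("favorable", "intermediate", "adverse", "favorable",
            "intermediate", "adverse")
  marker <- c("high", "high", "high", "low", "low", "low")
  ref <- refineRisk(base, marker)
  expect_identical(as.character(ref),
                   c("intermediate", "adverse", "adverse",
                     "favorable", "intermediate", "adverse"))
  # marker-low categories never change; the output partitions all samples
  expect_identical(as.character(ref[4:6]), base[4:6])
  expect_false(anyNA(ref))
})

test_that("custom mappings are honored and must be total", {
  base <- c("favorable", "adverse")
  marker <- c("high", "low")
  mapping <- data.frame(base = c("favorable", "adverse"),
                        marker = c("high", "low"),
                        refined = c("adverse", "adverse"))
  ref <- refineRisk(base, marker, mapping = mapping)
  expect_identical(as.character(ref), c("adverse", "adverse"))
  expect_error(refineRisk(c("favorable", "intermediate"), c("high", "high"),
                          mapping = mapping), "unmapped")
  expect_error(refineRisk(c("bogus"), c("high")), "unknown base category")
})

test_that("stratification comparison is invariant to category renaming", {
  co <- makeToyCohort(n = 80, nGenes = 3, seed = 23)
  g1 <- factor(clinicalData(co)$eln, levels = c("favorable", "intermediate",
                                                "adverse"))
  g2 <- factor(paste0("grp_", as.integer(g1)))
  comp <- evaluateStratification(co, g1, g2)
  expect_equal(comp$base$logrank$statistic, comp$refined$logrank$statistic,
               tolerance = 1e-12)
})

test_that("single-category groupings are rejected; tiny categories warn", {
  co <- makeToyCohort(n = 30, nGenes = 3, seed = 29)
  g <- factor(rep("only", 30))
  g2 <- factor(c("a", rep("b", 29)))
  expect_error(evaluateStratification(co, g, g2), "single category")
  expect_warning(expect_warning(evaluateStratification(co, g2, g2),
                                "< 2 samples"))
})

test_that("a marker prognostic within ELN classes strengthens the stratification", {
  wins <- 0L
  for (s in 1:15) {
    cfg <- simConfig(name = "rf", nSamples = 150, nGenes = 5,
                     plantedGenes = data.frame(gene_id = "G0001",
                                               beta = log(2.5)),
                     seed = s)
    sim <- simulateCohort(cfg)
    co <- sim$cohort
    cp <- optimalCutpoint(exprsMatrix(co)["G0001", ],
                          clinicalData(co)$os_time,
                          clinicalData(co)$os_event, horizon = 36)
    labels <- dichotomize(exprsMatrix(co)["G0001", ], cp$cutpoint)
    base <- factor(clinicalData(co)$eln,
                   levels = c("favorable", "intermediate", "adverse"))
    refined <- refineRisk(base, as.character(labels))
    comp <- suppressWarnings(evaluateStratification(co, base, refined))
    wins <- wins + (comp$refined$logrank$statistic >
                      comp$base$logrank$statistic)
  }
  expect_gte(wins, 13L)
})

test_that("subgroup hazards match the pooled stratified interaction model", {
  cfg <- simConfig(name = "ia", nSamples = 200, nGenes = 5,
                   plantedGenes = data.frame(gene_id = character(),
                                             beta = numeric()),
                   interaction = list(gene_id = "G0001", arm = "HSCT",
                                      beta = log(2.5)),
                   probHSCT = 0.5, seed = 11)
  sim <- simulateCohort(cfg)
  co <- sim$cohort
  labels <- ifelse(exprsMatrix(co)["G0001", ] >
                     median(exprsMatrix(co)["G0001", ]), "high", "low")
  sh <- subgroupHazard(co, labels)
  # reparametrization identity: arm-wise fits == pooled stratified fit
  b1 <- sh$interaction$coefficients[["marker_high"]]
  b3 <- sh$interaction$coefficients[["marker_x_arm2"]]
  expect_equal(unname(sh$fits[[sh$arms[1]]]$coefficients[["marker_high"]]),
               unname(b1), tolerance = 1e-6)
  expect_equal(unname(sh$fits[[sh$arms[2]]]$coefficients[["marker_high"]]),
               unname(b1 + b3), tolerance = 1e-6)
})

test_that("an HSCT-restricted marker effect yields a larger HSCT hazard ratio", {
  recovered <- 0L
  for (s in 1:15) {
    cfg <- simConfig(name = "ia", nSamples = 220, nGenes = 5,
                     plantedGenes = data.frame(gene_id = character(),
                                               beta = numeric()),
                     interaction = list(gene_id = "G0001", arm = "HSCT",
                                        beta = log(2.5)),
                     probHSCT = 0.5, seed = 600 + s)
    sim <- simulateCohort(cfg)
    co <- sim$cohort
    labels <- ifelse(exprsMatrix(co)["G0001", ] >
                       median(exprsMatrix(co)["G0001", ]), "high", "low")
    sh <- subgroupHazard(co, labels)
    hrHSCT <- sh$fits[["HSCT"]]$hazardRatios[["marker_high"]]
    hrChemo <- sh$fits[["chemo_only"]]$hazardRatios[["marker_high"]]
    # the interaction term contrasts arm 2 against arm 1
    inter <- sh$interaction$coefficients[["marker_x_arm2"]]
    interHSCT <- if (sh$arms[2] == "HSCT") inter else -inter
    recovered <- recovered + (hrHSCT > hrChemo && interHSCT > 0)
  }
  expect_gte(recovered, 13L)
})

test_that("permuted marker labels center the interaction on zero", {
  cfg <- simConfig(name = "nullia", nSamples = 150, nGenes = 5,
                   plantedGenes = data.frame(gene_id = character(),
                                             beta = numeric()),
                   probHSCT = 0.5, seed = 37)
  sim <- simulateCohort(cfg)
  co <- sim$cohort
  set.seed(43)
  coefs <- replicate(30, {
    labels <- sample(rep(c("high", "low"), length.out = ncol(co)))
    subgroupHazard(co, labels)$interaction$coefficients[["marker_x_arm2"]]
  })
  expect_lt(abs(mean(coefs)), 0.15)
})

test_that("degenerate treatment columns are rejected", {
  co <- makeToyCohort(n = 40, nGenes = 3, seed = 47)  # all HSCT
  labels <- rep(c("high", "low"), 20)
  expect_error(subgroupHazard(co, labels), "exactly two observed levels")
})
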