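test_that("overall pass is exactly the conjunction of the five gates", {
  gates <- survscreen:::.evalGates(auc = 0.6, sens = 0.4, spec = 0.9,
                                   uniP = 0.01, multiP = 0.01,
                                   multiRetained = TRUE)
  expect_false(gates[["sens_gate"]])
  expect_true(all(gates[c("auc_gate", "spec_gate", "uni_p_gate",
                          "multi_p_gate")]))
  # AUC exactly at the threshold fails: strict inequality
  g2 <- survscreen:::.evalGates(0.5, 0.7, 0.7, 0.01, 0.01, TRUE)
  expect_false(g2[["auc_gate"]])
  # significance gates are strict too
  g3 <- survscreen:::.evalGates(0.7, 0.7, 0.7, 0.05, 0.01, TRUE)
  expect_false(g3[["uni_p_gate"]])
  # enumeration: pass iff every gate true
  for (i in 0:31) {
    bits <- as.logical(bitwAnd(i, c(1L, 2L, 4L, 8L, 16L)))
    g <- survscreen:::.evalGates(
      auc = ifelse(bits[1], 0.7, 0.4), sens = ifelse(bits[2], 0.7, 0.4),
      spec = ifelse(bits[3], 0.7, 0.4), uniP = ifelse(bits[4], 0.01, 0.5),
      multiP = ifelse(bits[5], 0.01, 0.5), multiRetained = TRUE)
    expect_identical(all(g), all(bits))
  }
})

test_that("a strongly planted gene passes the full cascade with the right direction", {
  cfg <- simConfig(name = "one", nSamples = 150, nGenes = 30,
                   plantedGenes = data.frame(gene_id = "G0001",
                                             beta = log(2.5)))
  sim <- simulateCohort(cfg, seed = 5)
  row <- screenGene(sim$cohort, "G0001")
  expect_true(row$pass)
  expect_identical(row$direction, "high_is_worse")
  expect_gt(row$auc, 0.5)
  expect_gt(row$uni_hr, 1)
  expect_lt(row$multi_p, 0.05)
})

test_that("screenCohort isolates degenerate genes and keeps running", {
  co <- makeToyCohort(n = 60, nGenes = 6, seed = 3)
  # make one gene constant: degenerate dichotomization
  em <- exprsMatrix(co)
  em["G0003", ] <- 1
  co2 <- SurvCohort(em, cbind(sample_id = colnames(co),
                              clinicalData(co)), name = "toy")
  sc <- screenCohort(co2, verbose = FALSE)
  expect_equal(nrow(sc$ledger), 6)
  bad <- sc$ledger[sc$ledger$gene_id == "G0003", ]
  expect_false(bad$pass)
  expect_match(bad$reason, "degenerate dichotomization")
  expect_true(all(!is.na(sc$ledger$auc[sc$ledger$gene_id != "G0003"])))
})

test_that("missing confounders are excluded with a note, fits still run", {
  co <- makeToyCohort(n = 60, nGenes = 4, seed = 9)
  cd <- clinicalData(co)
  cd$wbc <- NULL
  co2 <- SurvCohort(exprsMatrix(co),
                    cbind(sample_id = colnames(co), cd), name = "nowbc")
  expect_message(sc <- screenCohort(co2), "confounder 'wbc' unavailable")
  expect_true(all(!is.na(sc$ledger$multi_p) | !is.na(sc$ledger$reason)))
})

test_that("the intersection requires passing every cohort with one direction", {
  mk <- function(cohort, gene, pass, direction) {
    led <- survscreen:::.failedScreenRow(cohort, gene, NA_character_)
    led$pass <- pass
    led$direction <- direction
    led
  }
  mkScreen <- function(cohort, rows)
    structure(list(cohort = cohort, ledger = do.call(rbind, rows),
                   horizon = 36, endpoint = "OS", notes = character()),
              class = "cohortScreen")
  s1 <- mkScreen("c1", list(mk("c1", "gA", TRUE, "high_is_worse"),
                            mk("c1", "gB", TRUE, "high_is_worse"),
                            mk("c1", "gC", TRUE, "high_is_worse")))
  s2 <- mkScreen("c2", list(mk("c2", "gA", TRUE, "high_is_worse"),
                            mk("c2", "gB", FALSE, "high_is_worse"),
                            mk("c2", "gC", TRUE, "high_is_worse")))
  s3 <- mkScreen("c3", list(mk("c3", "gA", TRUE, "high_is_worse"),
                            mk("c3", "gB", TRUE, "high_is_worse"),
                            mk("c3", "gC", TRUE, "low_is_worse")))
  summ <- intersectCohorts(list(s1, s2, s3))
  ig <- intersectionGenes(summ)
  # gB fails one cohort; gC flips direction; only gA survives
  expect_identical(ig$gene_id, "gA")
  expect_identical(ig$direction, "high_is_worse")
})

test_that("screening a cohort twice gives identical ledgers", {
  co <- makeToyCohort(n = 50, nGenes = 5, seed = 13)
  s1 <- screenCohort(co, verbose = FALSE)
  s2 <- screenCohort(co, verbose = FALSE)
  expect_identical(s1$ledger, s2$ledger)
})
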