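test_that("expression matrix round-trips through TSV exactly", {
  x <- matrix(c(1.25, -0.5, 3.75, 2.125, 0.0625, -7.5,
                4.5, 1.75, -2.25, 0.875, 5.5, -0.125), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(x, path)
  y <- readExpressionMatrix(path)
  expect_identical(dimnames(y), dimnames(x))
  expect_identical(y, x)
  # and a second round trip is bit-identical too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(y, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("expression loader rejects duplicates and non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(readExpressionMatrix(path), "duplicated gene id.*gA")
  writeLines(c("gene_id\ts1\ts1", "gA\t1\t2"), path)
  expect_error(readExpressionMatrix(path), "duplicated sample id.*s1")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\tNA", "gB\t3\t4"), path)
  expect_error(readExpressionMatrix(path), "gene 'gA', sample 's2'")
})

test_that("clinical loader validates, recodes and converts units", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,surv_days,dead,gender",
               "p1,365.25,1,0", "p2,730.5,0,1"), path)
  clin <- readClinicalTable(
    path,
    columnMap = list(sample_id = "id", os_time = "surv_days",
                     os_event = "dead", sex = "gender"),
    encodings = list(sex = c("0" = "female", "1" = "male")),
    timeUnit = "days")
  expect_equal(clin$os_time, c(12, 24))
  expect_equal(clin$sex, c("female", "male"))
  expect_identical(attr(clin, "endpoints"), "OS")

  writeLines(c("id,os_time,os_event", "p1,0,1"), path)
  expect_error(readClinicalTable(path, list(sample_id = "id")),
               "strictly positive")
  writeLines(c("id,os_time,os_event", "p1,5,2"), path)
  expect_error(readClinicalTable(path, list(sample_id = "id")),
               "os_event must be 0/1")
  writeLines(c("id,os_time", "p1,5"), path)
  expect_error(readClinicalTable(path, list(sample_id = "id")),
               "mandatory field missing: os_event")
})

test_that("harmonization restricts to the sample intersection and is idempotent", {
  expr <- matrix(rnorm(6), 2, 3,
                 dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  clin <- data.frame(sample_id = c("B", "C", "D"),
                     os_time = c(5, 10, 15), os_event = c(1, 0, 1),
                     stringsAsFactors = FALSE)
  expect_message(co <- SurvCohort(expr, clin, name = "h"),
                 "dropped 1 expression-only and 1 clinical-only")
  expect_identical(colnames(co), c("B", "C"))
  expect_identical(S4Vectors::metadata(co)$dropped,
                   c(expression = 1L, clinical = 1L))
  # idempotent: re-harmonizing the harmonized parts changes nothing
  clin2 <- clinicalData(co)
  clin2$sample_id <- rownames(clin2)
  co2 <- SurvCohort(exprsMatrix(co), clin2, name = "h")
  expect_identical(exprsMatrix(co2), exprsMatrix(co))
  expect_equal(clinicalData(co2), clinicalData(co))
  # disjoint id sets are an error
  clin3 <- data.frame(sample_id = c("X", "Y"), os_time = c(1, 2),
                      os_event = c(1, 1))
  expect_error(SurvCohort(expr, clin3), "share no sample ids")
})

test_that("cohort validity rejects malformed clinical values", {
  expr <- matrix(rnorm(4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  clin <- data.frame(sample_id = c("A", "B"), os_time = c(5, 3),
                     os_event = c(1, 0), eln = c("favorable", "bogus"),
                     stringsAsFactors = FALSE)
  expect_error(SurvCohort(expr, clin), "unknown eln value")
})

test_that("dichotomize follows the strict-greater convention and keeps groups non-empty", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  g <- dichotomize(v, 2.5)
  expect_identical(names(g)[g == "high"], c("c", "d"))
  # a value equal to the cutpoint goes to the low group
  g2 <- dichotomize(v, 2)
  expect_identical(as.character(g2[["b"]]), "low")
  expect_error(dichotomize(v, 4), "high group empty")
  expect_error(dichotomize(v, 0.5), "low group empty")
})

test_that("dichotomization is invariant under strictly increasing transforms", {
  set.seed(21)
  for (i in 1:10) {
    v <- rnorm(30)
    cut <- sort(v)[sample(5:25, 1)]
    g1 <- dichotomize(v, cut)
    g2 <- dichotomize(exp(v), exp(cut))
    expect_identical(as.character(g1), as.character(g2))
  }
})
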