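# Independent oracles used to validate the analytical machinery.
# They deliberately share no code with the package implementation.

# explicit no-ties Cox partial log-likelihood for a single covariate
plainPartialLoglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force maximization of the explicit partial likelihood over a grid
gridCoxOracle <- function(x, time, event, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  llc <- vapply(coarse, plainPartialLoglik, numeric(1), x, time, event)
  b0 <- coarse[which.max(llc)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, plainPartialLoglik, numeric(1), x, time, event)
  fine[which.max(llf)]
}

# pairwise Mann-Whitney concordance of marker vs binary status
concordanceOracle <- function(marker, died) {
  mc <- marker[died]; mk <- marker[!died]
  mean(outer(mc, mk, ">") + 0.5 * outer(mc, mk, "=="))
}

# random tie-free survival fixture
makeSurvFixture <- function(n, seed, pEvent = 0.7, betaTrue = 0) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  while (sd(x) == 0) x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.08 * exp(betaTrue * x))
  event <- rbinom(n, 1, pEvent)
  if (sum(event) == 0) event[sample(n, 2)] <- 1
  list(x = x, time = time, event = event)
}

# tiny harmonizable cohort built in code
makeToyCohort <- function(n = 40, nGenes = 5, seed = 1, name = "toy") {
  set.seed(seed)
  expr <- matrix(rnorm(nGenes * n), nGenes, n,
                 dimnames = list(sprintf("G%04d", seq_len(nGenes)),
                                 sprintf("%s_S%03d", name, seq_len(n))))
  clin <- data.frame(
    sample_id = colnames(expr),
    os_time = rexp(n, 0.03) + 0.5,
    os_event = rbinom(n, 1, 0.7),
    age = runif(n, 20, 80),
    sex = sample(c("male", "female"), n, replace = TRUE),
    wbc = rlnorm(n, log(15), 0.8),
    transplant = sample(c("allo", "auto"), n, replace = TRUE),
    eln = sample(c("favorable", "intermediate", "adverse"), n,
                 replace = TRUE),
    treatment = "HSCT",
    stringsAsFactors = FALSE)
  SurvCohort(expr, clin, name = name)
}
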