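#' Compare clinical characteristics between two marker groups
#'
#' Standard bedside table statistics: continuous variables are compared by
#' the Mann-Whitney (Wilcoxon rank-sum) test — exact for small tie-free
#' samples, normal approximation otherwise — and categorical variables by
#' Fisher's exact test on the contingency table. All p-values are
#' two-sided.
#'
#' @param clinical \code{data.frame} of per-sample characteristics.
#' @param labels two-level grouping aligned with \code{clinical} rows (e.g.
#'   from \code{\link{dichotomize}}).
#' @param variables columns to test; defaults to every column that is not a
#'   survival time/event field.
#' @return \code{data.frame} with one row per variable: \code{variable},
#'   \code{test} ("mann_whitney" or "fisher_exact"), \code{statistic}
#'   (U for Mann-Whitney, odds-ratio estimate for 2x2 Fisher), \code{p}.
#' @examples
#' clin <- data.frame(age = c(40, 50, 60, 70, 55, 65),
#'                    sex = rep(c("male", "female"), 3))
#' compareGroups(clin, rep(c("low", "high"), each = 3))
#' @export
compareGroups <- function(clinical, labels, variables = NULL) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L))
    stop("labels must split the samples into two non-empty groups")
  stopifnot(nrow(clinical) == length(labels))
  if (is.null(variables))
    variables <- setdiff(colnames(clinical),
                         c("sample_id", unlist(.ENDPOINT_COLS,
                                               use.names = FALSE)))
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L)
      stop(sprintf("variable '%s' has a single observed value", v))
    if (is.numeric(x)) {
      wt <- stats::wilcox.test(x[ok] ~ labels[ok])
      data.frame(variable = v, test = "mann_whitney",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(labels[ok], x[ok])
      ft <- stats::fisher.test(tab)
      data.frame(variable = v, test = "fisher_exact",
                 statistic = if (all(dim(tab) == 2L))
                   unname(ft$estimate) else NA_real_,
                 p = ft$p.value, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Correlate gene expression with ex vivo drug response
#'
#' Spearman rank correlation between a gene's expression and per-drug
#' response AUC values across shared samples. A correlation is flagged as
#' strong when rho > 0.3 or rho < -0.3 with p < 0.05 (both conditions
#' strict).
#'
#' @param expression named numeric vector of the gene's expression
#'   (names = sample ids).
#' @param drugAuc matrix or \code{data.frame} of drug-response AUCs,
#'   samples x drugs, rownames = sample ids.
#' @param rhoThreshold absolute rho threshold (default 0.3, strict).
#' @param alpha significance threshold (default 0.05, strict).
#' @return \code{data.frame} with one row per drug: \code{drug},
#'   \code{rho}, \code{p}, \code{n}, \code{flagged}.
#' @export
correlateDrugResponse <- function(expression, drugAuc, rhoThreshold = 0.3,
                                  alpha = 0.05) {
  stopifnot(!is.null(names(expression)), !is.null(rownames(drugAuc)))
  drugAuc <- as.matrix(drugAuc)
  shared <- intersect(names(expression), rownames(drugAuc))
  rows <- lapply(colnames(drugAuc), function(drug) {
    y <- drugAuc[shared, drug]
    x <- expression[shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L)
      stop(sprintf("drug '%s': fewer than 3 paired observations", drug))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman"))
    rho <- unname(ct$estimate)
    data.frame(drug = drug, rho = rho, p = ct$p.value, n = sum(ok),
               flagged = (rho > rhoThreshold || rho < -rhoThreshold) &&
                 ct$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
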