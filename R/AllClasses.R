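#' @import methods
NULL

#' Two-locus penetrance model
#'
#' A `PenetranceModel` couples the minor allele frequencies (MAFs) of two
#' biallelic SNPs with a 3x3 penetrance table giving
#' \eqn{p_{ij} = P(\mathrm{case} \mid SNP1 = i, SNP2 = j)} for minor allele
#' doses \eqn{i, j \in \{0, 1, 2\}}. Rows index the SNP1 dose and columns the
#' SNP2 dose. Together with Hardy-Weinberg equilibrium and independence of
#' the two loci, the model fully determines the joint distribution of
#' genotype and case-control status in the population.
#'
#' @slot maf1 Minor allele frequency of SNP1, in (0, 0.5].
#' @slot maf2 Minor allele frequency of SNP2, in (0, 0.5].
#' @slot pen 3x3 numeric matrix of penetrances in \[0, 1\]; `pen[i + 1, j + 1]`
#'   is the case probability for SNP1 dose `i` and SNP2 dose `j`.
#' @slot label Free-text scenario name.
#'
#' @seealso [PenetranceModel()], [populationPrevalence()],
#'   [modelHeritability()], [builtinModels()]
#' @export
setClass("PenetranceModel",
  representation(
    maf1 = "numeric",
    maf2 = "numeric",
    pen = "matrix",
    label = "character"
  )
)

setValidity("PenetranceModel", function(object) {
  msg <- character()
  for (m in c(object@maf1, object@maf2)) {
    if (length(m) != 1L || is.na(m) || m <= 0 || m > 0.5)
      msg <- c(msg, "minor allele frequencies must be single values in (0, 0.5]")
  }
  p <- object@pen
  if (!is.numeric(p) || !identical(dim(p), c(3L, 3L)))
    msg <- c(msg, "penetrance table must be a 3x3 numeric matrix")
  else if (anyNA(p) || any(p < 0) || any(p > 1))
    msg <- c(msg, "penetrance entries must be probabilities in [0, 1]")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single character string")
  if (length(msg)) msg else TRUE
})

#' Create a penetrance model
#'
#' @param maf1,maf2 Minor allele frequencies of SNP1 and SNP2, in (0, 0.5].
#' @param pen 3x3 matrix of penetrances, rows = SNP1 dose 0..2,
#'   columns = SNP2 dose 0..2.
#' @param label Optional scenario name.
#'
#' @return A [PenetranceModel-class] object.
#' @examples
#' m <- PenetranceModel(0.5, 0.5, matrix(0.5, 3, 3), "null model")
#' populationPrevalence(m)
#' @export
PenetranceModel <- function(maf1, maf2, pen, label = "") {
  pen <- as.matrix(pen)
  if (!is.numeric(pen) || !identical(dim(pen), c(3L, 3L)))
    stop("penetrance table must be a 3x3 numeric matrix")
  dimnames(pen) <- list(SNP1 = 0:2, SNP2 = 0:2)
  new("PenetranceModel", maf1 = as.numeric(maf1), maf2 = as.numeric(maf2),
      pen = pen, label = as.character(label))
}

#' @describeIn PenetranceModel-class MAF of SNP1.
#' @param object A `PenetranceModel`.
#' @export
setGeneric("maf1", function(object) standardGeneric("maf1"))
#' @describeIn PenetranceModel-class MAF of SNP2.
#' @export
setGeneric("maf2", function(object) standardGeneric("maf2"))
#' @describeIn PenetranceModel-class The 3x3 penetrance matrix.
#' @export
setGeneric("penetrance", function(object) standardGeneric("penetrance"))
#' @describeIn PenetranceModel-class The scenario label.
#' @export
setGeneric("modelLabel", function(object) standardGeneric("modelLabel"))

#' @rdname PenetranceModel-class
setMethod("maf1", "PenetranceModel", function(object) object@maf1)
#' @rdname PenetranceModel-class
setMethod("maf2", "PenetranceModel", function(object) object@maf2)
#' @rdname PenetranceModel-class
setMethod("penetrance", "PenetranceModel", function(object) object@pen)
#' @rdname PenetranceModel-class
setMethod("modelLabel", "PenetranceModel", function(object) object@label)

setMethod("show", "PenetranceModel", function(object) {
  lbl <- if (nzchar(object@label)) object@label else "<unnamed>"
  cat("PenetranceModel:", lbl, "\n")
  cat("  MAF SNP1:", object@maf1, " MAF SNP2:", object@maf2, "\n")
  cat("  prevalence K =", format(populationPrevalence(object), digits = 6),
      " heritability h2 =", format(modelHeritability(object), digits = 4), "\n")
  print(round(object@pen, 3))
})

#' Fitted logistic genotype model
#'
#' Result of [fitLogistic()]: a maximum-likelihood logistic regression of
#' case-control status on the two SNP dose factors (treatment coding,
#' reference genotype (0, 0)), either main effects only or with the full
#' 9-level SNP1 x SNP2 interaction, optionally adjusted for covariates.
#'
#' @slot kind `"main"` or `"interaction"`.
#' @slot covariates Names of covariate columns included in the fit.
#' @slot coefficients Named coefficient vector; `NA` entries mark dummies
#'   dropped because the corresponding genotype cell (or factor level) was
#'   absent from the training data.
#' @slot logLik Bernoulli log-likelihood at the optimum.
#' @slot df Number of estimated (non-`NA`) coefficients.
#' @slot cellProbs 3x3 fitted case probability per genotype cell
#'   (covariate-free fits only; all-`NA` otherwise).
#' @slot cellsPresent 3x3 logical: genotype cells occupied in training data.
#' @slot converged Logical, IRLS convergence flag.
#' @slot separated Logical; `TRUE` when some occupied cell is pure case or
#'   pure control so fitted probabilities saturate at 0/1.
#' @slot nobs Number of training rows.
#' @slot fit The underlying [stats::glm] object (used for covariate
#'   prediction), or `NULL` for the covariate-free closed-form path.
#' @export
setClass("LogisticFit",
  representation(
    kind = "character",
    covariates = "character",
    coefficients = "numeric",
    logLik = "numeric",
    df = "integer",
    cellProbs = "matrix",
    cellsPresent = "matrix",
    converged = "logical",
    separated = "logical",
    nobs = "integer",
    fit = "ANY"
  )
)

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit (", object@kind,
      if (length(object@covariates))
        paste0(" + ", paste(object@covariates, collapse = ", ")) else "",
      ")\n", sep = "")
  cat("  n =", object@nobs, " df =", object@df,
      " logLik =", format(object@logLik, digits = 6), "\n")
  if (!all(is.na(object@cellProbs))) {
    cat("  fitted P(case) by genotype cell:\n")
    print(round(object@cellProbs, 3))
  }
  if (object@separated) cat("  note: perfect separation in some cell(s)\n")
})

#' Per-scenario comparison of PICV and traditional cross validation
#'
#' Result of [runScenario()]: per-replicate |train - test| gaps for the four
#' performance measures under both splitters and both model specifications,
#' with one-sided Kolmogorov-Smirnov comparisons (PICV hypothesized smaller)
#' and median/maximum summaries.
#'
#' @slot label Scenario label.
#' @slot n Dataset size per replicate.
#' @slot replicates Number of requested replicates.
#' @slot gaps Numeric array `[replicate, method, spec, measure]` of
#'   |train - test| gaps (`NA` = undefined measure in that replicate).
#' @slot ks `data.frame` with one row per (spec, measure): KS statistic `D`,
#'   p-value, retained sample size, and count of replicates dropped pairwise
#'   because either method's gap was undefined.
#' @slot medianMax `data.frame` with per-(spec, measure) medians and maxima
#'   for both methods plus strict "PICV smaller" indicators.
#' @slot failures Number of replicates that failed (recorded, not fatal).
#' @slot valid `FALSE` when more than 10% of replicates failed.
#' @slot baseSeed,scenarioIndex Seed bookkeeping for reproducibility.
#' @export
setClass("ScenarioResult",
  representation(
    label = "character",
    n = "integer",
    replicates = "integer",
    gaps = "array",
    ks = "data.frame",
    medianMax = "data.frame",
    failures = "integer",
    valid = "logical",
    baseSeed = "integer",
    scenarioIndex = "integer"
  )
)

setMethod("show", "ScenarioResult", function(object) {
  cat("ScenarioResult:", object@label, "\n")
  cat("  n =", object@n, ", replicates =", object@replicates,
      "(", object@failures, "failed )\n")
  if (!object@valid) cat("  WARNING: >10% replicate failures; marked invalid\n")
  cat("  one-sided KS (PICV gaps smaller):\n")
  print(object@ks, digits = 3, row.names = FALSE)
})
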