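## Logistic genotype models. SNP doses enter as 3-level factors with
## treatment (reference-cell) coding, reference level 0 = homozygous for
## the major allele at both loci; the interaction model adds the dummies
## for the Cartesian product of the two factors, giving one free
## parameter per occupied genotype cell (a saturated model when no
## covariates are present).

## Explicit treatment-coded dummy columns for the two dose factors.
## Building the design by hand (rather than via factor terms) keeps
## unused dose levels and empty genotype cells as all-zero columns, which
## IRLS resolves to NA coefficients; predictions then fall back to the
## remaining terms, and no "new factor level" failures can occur.
dummyDesign <- function(snp1, snp2, kind) {
  d <- data.frame(
    snp1_1 = as.integer(snp1 == 1), snp1_2 = as.integer(snp1 == 2),
    snp2_1 = as.integer(snp2 == 1), snp2_2 = as.integer(snp2 == 2))
  if (kind == "interaction") {
    for (i in 1:2) for (j in 1:2)
      d[[paste0("snp1_", i, ".snp2_", j)]] <-
        d[[paste0("snp1_", i)]] * d[[paste0("snp2_", j)]]
  }
  d
}

cellCounts <- function(data) {
  cell <- 3L * data$snp1 + data$snp2
  list(cases = tabulate(cell[data$status == 1] + 1L, 9L),
       controls = tabulate(cell[data$status == 0] + 1L, 9L))
}

cellGrid <- function() {
  data.frame(s1 = factor(rep(0:2, each = 3), levels = 0:2),
             s2 = factor(rep(0:2, times = 3), levels = 0:2))
}

## Bernoulli log-likelihood from per-cell counts and probabilities,
## with the convention 0 * log(0) = 0 (saturated pure cells).
cellLogLik <- function(cases, controls, p) {
  eps <- 1e-12
  sum(ifelse(cases > 0, cases * log(pmax(p, eps)), 0) +
      ifelse(controls > 0, controls * log(pmax(1 - p, eps)), 0))
}

#' Fit a logistic main-effects or interaction model
#'
#' Maximum-likelihood logistic regression of case-control status on the
#' two SNP dose factors, optionally with the full SNP1 x SNP2 interaction
#' and numeric covariates. Covariate-free fits are computed from the
#' genotype-cell sufficient statistics (a weighted binomial IRLS on at
#' most 9 cells); the covariate-free interaction model is saturated, so
#' its fitted cell probabilities equal the observed per-cell case
#' fractions exactly. Genotype cells absent from the training data have
#' their dummies dropped (coefficient `NA`); predictions for such cells
#' fall back to the main-effects part of the fit. Perfect separation
#' within a cell saturates the fitted probability at 0/1 and sets the
#' `separated` flag rather than failing.
#'
#' @param data A genotype dataset `data.frame` with at least one case and
#'   one control.
#' @param kind `"main"` (dose factors only) or `"interaction"` (adds the
#'   9-level Cartesian-product term).
#' @param covariates Character vector of covariate column names.
#'
#' @return A [LogisticFit-class] object.
#' @examples
#' set.seed(1)
#' d <- simulateBalancedDataset(builtinModels()[["Scenario 15"]], 600)
#' fit <- fitLogistic(d, "interaction")
#' fit
#' @export
fitLogistic <- function(data, kind = c("main", "interaction"),
                        covariates = character()) {
  kind <- match.arg(kind)
  checkGenotypeDataset(data, covariates)
  if (length(unique(data$status)) < 2L)
    stop("cannot fit a logistic model to a single-class outcome")
  ctl <- stats::glm.control(maxit = 100)
  present <- matrix(FALSE, 3, 3, dimnames = list(SNP1 = 0:2, SNP2 = 0:2))

  if (length(covariates) == 0L) {
    cc <- cellCounts(data)
    tot <- cc$cases + cc$controls
    present[] <- matrix(tot > 0, 3, 3, byrow = TRUE)
    grid <- cellGrid()
    design <- dummyDesign(rep(0:2, each = 3), rep(0:2, times = 3), kind)
    agg <- cbind(design, cases = cc$cases, controls = cc$controls)
    occ <- tot > 0
    form <- stats::as.formula(paste("cbind(cases, controls) ~",
                                    paste(names(design), collapse = " + ")))
    gfit <- suppressWarnings(
      stats::glm(form, family = stats::binomial(),
                 data = agg[occ, , drop = FALSE], control = ctl))
    probs <- suppressWarnings(
      stats::predict(gfit, newdata = design, type = "response"))
    cellProbs <- matrix(probs, 3, 3, byrow = TRUE,
                        dimnames = list(SNP1 = 0:2, SNP2 = 0:2))
    if (kind == "interaction") {
      # exact saturated closed form on occupied cells (matches IRLS)
      frac <- matrix(ifelse(tot > 0, cc$cases / pmax(tot, 1L), NA_real_),
                     3, 3, byrow = TRUE)
      cellProbs[present] <- frac[present]
    }
    pOcc <- t(cellProbs)[occ]    # row-major cell order
    ll <- cellLogLik(cc$cases[occ], cc$controls[occ], pOcc)
    separated <- any(pOcc < 1e-8 | pOcc > 1 - 1e-8)
    fitObj <- NULL
    nobs <- nrow(data)
  } else {
    design <- dummyDesign(data$snp1, data$snp2, kind)
    df2 <- cbind(data.frame(status = data$status), design,
                 data[, covariates, drop = FALSE])
    form <- stats::as.formula(paste(
      "status ~", paste(c(names(design), covariates), collapse = " + ")))
    gfit <- suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = df2,
                 control = ctl))
    present[] <- matrix(tabulate(3L * data$snp1 + data$snp2 + 1L, 9L) > 0,
                        3, 3, byrow = TRUE)
    cellProbs <- matrix(NA_real_, 3, 3,
                        dimnames = list(SNP1 = 0:2, SNP2 = 0:2))
    ll <- as.numeric(stats::logLik(gfit))
    mu <- gfit$fitted.values
    separated <- any(mu < 1e-8 | mu > 1 - 1e-8)
    fitObj <- gfit
    nobs <- nrow(df2)
  }

  new("LogisticFit",
      kind = kind, covariates = covariates,
      coefficients = stats::coef(gfit),
      logLik = ll, df = sum(!is.na(stats::coef(gfit))),
      cellProbs = cellProbs, cellsPresent = present,
      converged = isTRUE(gfit$converged), separated = separated,
      nobs = as.integer(nobs), fit = fitObj)
}

#' Predicted case probabilities
#'
#' Evaluates a fitted logistic genotype model on new rows through the
#' logistic link. For covariate-free fits the prediction is the fitted
#' cell probability of the row's genotype; rows in genotype cells absent
#' from training are predicted from the main-effects part of the fit
#' (their interaction dummy was dropped).
#'
#' @param fit A [LogisticFit-class].
#' @param data A genotype dataset `data.frame` containing any covariates
#'   the fit requires.
#'
#' @return Numeric vector of case probabilities, one per row.
#' @export
predictProb <- function(fit, data) {
  stopifnot(is(fit, "LogisticFit"))
  checkGenotypeDataset(data, fit@covariates)
  if (length(fit@covariates) == 0L) {
    p <- fit@cellProbs[cbind(data$snp1 + 1L, data$snp2 + 1L)]
    return(unname(p))
  }
  nd <- cbind(dummyDesign(data$snp1, data$snp2, fit@kind),
              data[, fit@covariates, drop = FALSE])
  unname(suppressWarnings(
    stats::predict(fit@fit, newdata = nd, type = "response")))
}

#' Classify probabilities at a cutoff
#'
#' Predicted label is case (1) when the probability strictly exceeds the
#' cutoff; ties at the cutoff are classified as control (0).
#'
#' @param probs Numeric vector of probabilities in \[0, 1\].
#' @param cutoff Decision threshold, default 0.5.
#' @return Integer vector of 0/1 labels (same length as `probs`).
#' @export
classifyProb <- function(probs, cutoff = 0.5) {
  if (length(probs) && (anyNA(probs) || any(probs < 0 | probs > 1)))
    stop("'probs' must be probabilities in [0, 1]")
  as.integer(probs > cutoff)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' Twice the log-likelihood difference between a nested pair of fits on
#' the same rows, referred to the chi-square distribution with degrees of
#' freedom equal to the difference in estimated parameters (4 for the
#' covariate-free interaction vs main-effects comparison when all cells
#' are occupied).
#'
#' @param fitNull,fitAlt [LogisticFit-class] objects on the same data;
#'   `fitAlt` must nest `fitNull` (same covariates with the interaction
#'   added, or additional covariates).
#'
#' @return An object of class `"htest"` with the statistic, degrees of
#'   freedom, and p-value.
#' @export
likelihoodRatioTest <- function(fitNull, fitAlt) {
  stopifnot(is(fitNull, "LogisticFit"), is(fitAlt, "LogisticFit"))
  if (fitNull@nobs != fitAlt@nobs)
    stop("fits were not computed on the same data (different row counts)")
  nested <- (identical(fitNull@kind, fitAlt@kind) ||
             (fitNull@kind == "main" && fitAlt@kind == "interaction")) &&
            all(fitNull@covariates %in% fitAlt@covariates)
  if (!nested || fitAlt@df < fitNull@df)
    stop("'fitAlt' must nest 'fitNull'")
  stat <- max(0, 2 * (fitAlt@logLik - fitNull@logLik))
  df <- fitAlt@df - fitNull@df
  p <- if (df == 0L) as.numeric(stat <= 1e-10)
       else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(
    list(statistic = c("X-squared" = stat), parameter = c(df = df),
         p.value = p,
         method = "Likelihood-ratio test of nested logistic genotype models",
         data.name = paste(fitNull@kind, "vs", fitAlt@kind)),
    class = "htest")
}
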