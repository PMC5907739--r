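CV_METHODS <- c("traditional", "picv")
MODEL_SPECS <- c("main", "interaction")
MEASURES <- c("sensitivity", "specificity", "ppv", "npv")

#' Derived replicate seed
#'
#' Counter-based seed for replicate `replicate` of scenario
#' `scenarioIndex` under a study base seed, so that every replicate is
#' reproducible in isolation and no global random state is shared between
#' replicates. The value is
#' `(baseSeed * 16807 + scenarioIndex * 1e6 + replicate) mod (2^31 - 1)`.
#'
#' @param baseSeed Integer study seed.
#' @param scenarioIndex Scenario counter (1-based).
#' @param replicate Replicate counter.
#' @return Integer seed.
#' @export
derivedSeed <- function(baseSeed, scenarioIndex, replicate) {
  as.integer((baseSeed * 16807 + scenarioIndex * 1e6 + replicate) %%
             2147483647)
}

## Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Train/test performance quads for both model specs under one split.
evaluateSplit <- function(data, split, cutoff) {
  train <- data[split$train, , drop = FALSE]
  test <- data[split$test, , drop = FALSE]
  out <- list()
  for (spec in MODEL_SPECS) {
    fit <- fitLogistic(train, spec)
    out[[spec]] <- list(
      train = confusionMeasures(train$status,
                                classifyProb(predictProb(fit, train), cutoff)),
      test = confusionMeasures(test$status,
                               classifyProb(predictProb(fit, test), cutoff)))
  }
  out
}

#' Run one paired cross-validation replicate
#'
#' Simulates one balanced case-control dataset from the model and applies
#' both splitters — traditional random and PICV genotype-stratified — to
#' the same dataset (pairing the comparison reduces Monte Carlo variance).
#' For each split and each model specification, the model is fit on the
#' training partition and both partitions are classified at the cutoff.
#'
#' @param model A [PenetranceModel-class].
#' @param n Dataset size (even).
#' @param trainFraction Training fraction, default two thirds.
#' @param cutoff Classification threshold, default 0.5.
#'
#' @return Nested list `result[[method]][[spec]]$train` / `$test`, each a
#'   measure vector from [confusionMeasures()].
#' @export
runReplicate <- function(model, n = 2000, trainFraction = 2/3,
                         cutoff = 0.5) {
  data <- simulateBalancedDataset(model, n)
  splits <- list(
    traditional = traditionalSplit(nrow(data), trainFraction),
    picv = picvSplit(genotypeStrata(data), trainFraction))
  lapply(splits, function(s) evaluateSplit(data, s, cutoff))
}

#' Compare PICV with traditional cross validation for one scenario
#'
#' Runs `replicates` paired replicates of [runReplicate()], collects the
#' |train - test| consistency gaps of the four performance measures for
#' both splitters and both model specifications, and compares the gap
#' distributions with the one-sided two-sample KS test (PICV hypothesized
#' smaller) for each of the 8 (measure, spec) combinations. Replicates
#' where a gap is undefined for either method are excluded pairwise from
#' that KS comparison, with counts reported. Each replicate runs under a
#' [derivedSeed()], so results are fully determined by
#' `(baseSeed, scenarioIndex)` and the configuration.
#'
#' @param model A [PenetranceModel-class].
#' @param n Dataset size per replicate.
#' @param replicates Number of replicates (>= 1).
#' @param trainFraction,cutoff Passed to [runReplicate()].
#' @param baseSeed Study base seed.
#' @param scenarioIndex Scenario counter used for seed derivation.
#' @param paired Apply both splitters to the same dataset (default). With
#'   `paired = FALSE` an independent dataset is simulated for each
#'   splitter.
#' @param resplit Simulate a single dataset for the scenario and re-split
#'   it every replicate, instead of the default of a fresh dataset per
#'   replicate.
#'
#' @return A [ScenarioResult-class] object.
#' @export
runScenario <- function(model, n = 2000, replicates = 200,
                        trainFraction = 2/3, cutoff = 0.5, baseSeed = 1,
                        scenarioIndex = 1L, paired = TRUE,
                        resplit = FALSE) {
  stopifnot(is(model, "PenetranceModel"), replicates >= 1)
  gaps <- array(NA_real_,
                dim = c(replicates, 2L, 2L, 4L),
                dimnames = list(NULL, method = CV_METHODS,
                                spec = MODEL_SPECS, measure = MEASURES))
  failures <- 0L
  fixedData <- if (resplit)
    withSeed(derivedSeed(baseSeed, scenarioIndex, 0L),
             simulateBalancedDataset(model, n))
  else NULL
  for (r in seq_len(replicates)) {
    rep_res <- tryCatch(
      withSeed(derivedSeed(baseSeed, scenarioIndex, r), {
        if (resplit || !paired) {
          res <- list()
          for (m in CV_METHODS) {
            data <- if (resplit) fixedData else simulateBalancedDataset(model, n)
            s <- if (m == "traditional")
              traditionalSplit(nrow(data), trainFraction)
            else picvSplit(genotypeStrata(data), trainFraction)
            res[[m]] <- evaluateSplit(data, s, cutoff)
          }
          res
        } else {
          runReplicate(model, n, trainFraction, cutoff)
        }
      }),
      error = function(e) e)
    if (inherits(rep_res, "error")) {
      failures <- failures + 1L
      warning("replicate ", r, " failed: ", conditionMessage(rep_res),
              call. = FALSE)
      next
    }
    for (m in CV_METHODS) for (sp in MODEL_SPECS) {
      gaps[r, m, sp, ] <- trainTestGap(rep_res[[m]][[sp]]$train,
                                       rep_res[[m]][[sp]]$test)
    }
  }

  ks <- do.call(rbind, lapply(MODEL_SPECS, function(sp) {
    do.call(rbind, lapply(MEASURES, function(ms) {
      gt <- gaps[, "traditional", sp, ms]
      gp <- gaps[, "picv", sp, ms]
      keep <- !is.na(gt) & !is.na(gp)
      if (sum(keep) == 0)
        return(data.frame(spec = sp, measure = ms, D = NA_real_,
                          p = NA_real_, nUsed = 0L,
                          dropped = replicates))
      h <- ksOneSided(gt[keep], gp[keep])
      data.frame(spec = sp, measure = ms, D = unname(h$statistic),
                 p = h$p.value, nUsed = sum(keep),
                 dropped = sum(!keep) - failures)
    }))
  }))
  medianMax <- do.call(rbind, lapply(MODEL_SPECS, function(sp) {
    do.call(rbind, lapply(MEASURES, function(ms) {
      s <- medianMaxSummary(gaps[, "traditional", sp, ms],
                            gaps[, "picv", sp, ms])
      data.frame(spec = sp, measure = ms,
                 medianTraditional = s$medianTraditional,
                 medianPicv = s$medianPicv,
                 maxTraditional = s$maxTraditional, maxPicv = s$maxPicv,
                 picvMedianSmaller = s$picvMedianSmaller,
                 picvMaxSmaller = s$picvMaxSmaller)
    }))
  }))

  new("ScenarioResult",
      label = if (nzchar(model@label)) model@label else "scenario",
      n = as.integer(n), replicates = as.integer(replicates),
      gaps = gaps, ks = ks, medianMax = medianMax,
      failures = failures,
      valid = failures <= 0.1 * replicates,
      baseSeed = as.integer(baseSeed),
      scenarioIndex = as.integer(scenarioIndex))
}

#' Run the full PICV comparison study
#'
#' Applies [runScenario()] to a list of penetrance models and assembles
#' the study tables: a per-scenario matrix of one-sided KS p-values for
#' the 8 (measure, model-spec) comparisons, and cross-scenario counts of
#' scenarios in which PICV gave strictly smaller median and maximum gaps.
#'
#' @param models Named list of [PenetranceModel-class] objects (default:
#'   the 15 bundled scenarios); labels must be unique.
#' @param n,replicates,trainFraction,cutoff,baseSeed,paired,resplit
#'   Passed to [runScenario()].
#'
#' @return List with components `ks` (data.frame, one row per scenario,
#'   one column per comparison), `counts` (data.frame of
#'   picv-median-smaller / picv-max-smaller counts per comparison),
#'   and `scenarios` (list of [ScenarioResult-class]).
#' @export
runStudy <- function(models = builtinModels(), n = 2000, replicates = 200,
                     trainFraction = 2/3, cutoff = 0.5, baseSeed = 1,
                     paired = TRUE, resplit = FALSE) {
  if (length(models) < 1L)
    stop("'models' must contain at least one penetrance model")
  labels <- vapply(models, modelLabel, character(1))
  labels[!nzchar(labels)] <- names(models)[!nzchar(labels)]
  if (anyDuplicated(labels))
    stop("duplicate scenario labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (replicates < 50)
    message("runStudy: fewer than 50 replicates; ",
            "KS comparisons will have little power")
  scenarios <- vector("list", length(models))
  for (i in seq_along(models)) {
    scenarios[[i]] <- runScenario(models[[i]], n = n,
                                  replicates = replicates,
                                  trainFraction = trainFraction,
                                  cutoff = cutoff, baseSeed = baseSeed,
                                  scenarioIndex = i, paired = paired,
                                  resplit = resplit)
  }
  names(scenarios) <- labels

  comparison <- expand.grid(measure = MEASURES, spec = MODEL_SPECS,
                            stringsAsFactors = FALSE)
  comparison <- comparison[order(match(comparison$measure, MEASURES)), ]
  colnames_ks <- paste(comparison$measure, comparison$spec, sep = "_")
  ks <- data.frame(
    scenario = labels,
    maf1 = vapply(models, maf1, numeric(1)),
    maf2 = vapply(models, maf2, numeric(1)),
    row.names = NULL)
  for (k in seq_len(nrow(comparison))) {
    ks[[colnames_ks[k]]] <- vapply(scenarios, function(sc) {
      with(sc@ks, p[spec == comparison$spec[k] &
                    measure == comparison$measure[k]])
    }, numeric(1))
  }
  counts <- comparison
  counts$picvMedianSmaller <- counts$picvMaxSmaller <- NA_integer_
  for (k in seq_len(nrow(comparison))) {
    med <- vapply(scenarios, function(sc) {
      with(sc@medianMax,
           picvMedianSmaller[spec == comparison$spec[k] &
                             measure == comparison$measure[k]])
    }, logical(1))
    mx <- vapply(scenarios, function(sc) {
      with(sc@medianMax,
           picvMaxSmaller[spec == comparison$spec[k] &
                          measure == comparison$measure[k]])
    }, logical(1))
    counts$picvMedianSmaller[k] <- sum(med, na.rm = TRUE)
    counts$picvMaxSmaller[k] <- sum(mx, na.rm = TRUE)
  }
  list(ks = ks, counts = counts, scenarios = scenarios)
}

#' Train/test consistency of the interaction likelihood-ratio test
#'
#' For a dataset with two SNPs, binary status, and optional covariates:
#' computes the interaction LRT p-value on the full data, then splits the
#' data by the chosen cross-validation method and recomputes the LRT
#' within the training and testing partitions. Consistency of the three
#' p-values indicates how well either partition represents the full data.
#' Uses the current random number stream for the split.
#'
#' @param data Genotype dataset `data.frame`.
#' @param trainFraction Training fraction, default two thirds.
#' @param method `"picv"` or `"traditional"`.
#' @param covariates Covariate column names to adjust for.
#'
#' @return List with elements `overall`, `train`, `test` (LRT p-values;
#'   `NA` with a warning if a partition has a single-class outcome),
#'   `nTrain`, `nTest`, and `method`.
#' @export
consistencyLRT <- function(data, trainFraction = 2/3,
                           method = c("picv", "traditional"),
                           covariates = character()) {
  method <- match.arg(method)
  checkGenotypeDataset(data, covariates)
  lrtP <- function(d) {
    tryCatch(
      likelihoodRatioTest(fitLogistic(d, "main", covariates),
                          fitLogistic(d, "interaction", covariates))$p.value,
      error = function(e) {
        warning("LRT undefined for a partition: ", conditionMessage(e),
                call. = FALSE)
        NA_real_
      })
  }
  split <- if (method == "picv")
    picvSplit(genotypeStrata(data), trainFraction)
  else traditionalSplit(nrow(data), trainFraction)
  list(overall = lrtP(data),
       train = lrtP(data[split$train, , drop = FALSE]),
       test = lrtP(data[split$test, , drop = FALSE]),
       nTrain = length(split$train), nTest = length(split$test),
       method = method)
}

#' Boxplot of train/test gap distributions
#'
#' Side-by-side boxplots of the |train - test| gap distributions of the
#' two cross-validation methods for one measure and model specification.
#'
#' @param result A [ScenarioResult-class].
#' @param measure One of `"sensitivity"`, `"specificity"`, `"ppv"`,
#'   `"npv"`.
#' @param spec `"interaction"` or `"main"`.
#' @return Invisibly, the list of plotted gap vectors.
#' @export
plotGapDistributions <- function(result, measure = "sensitivity",
                                 spec = "interaction") {
  stopifnot(is(result, "ScenarioResult"),
            measure %in% MEASURES, spec %in% MODEL_SPECS)
  vals <- list(traditional = result@gaps[, "traditional", spec, measure],
               PICV = result@gaps[, "picv", spec, measure])
  graphics::boxplot(vals,
                    main = paste0(result@label, ": |train - test| ",
                                  measure, " (", spec, " model)"),
                    ylab = "|train - test|")
  invisible(vals)
}
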