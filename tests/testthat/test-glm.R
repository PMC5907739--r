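test_that("covariate-free interaction fit is saturated on cell fractions", {
  set.seed(10)
  d <- simulateBalancedDataset(builtinModels()[["Scenario 3"]], 600)
  fit <- fitLogistic(d, "interaction")
  cell <- 3 * d$snp1 + d$snp2
  for (c0 in 0:8) {
    rows <- cell == c0
    if (!any(rows)) next
    expect_equal(unname(fit@cellProbs[c0 %/% 3 + 1, c0 %% 3 + 1]),
                 mean(d$status[rows]), tolerance = 1e-6)
  }
  # predictions on training rows reproduce the cell fractions
  p <- predictProb(fit, d)
  expect_equal(p, ave(d$status, cell), tolerance = 1e-6)
})

test_that("a constant SNP2 reduces the main-effects fit to one factor", {
  set.seed(11)
  n <- 400
  d <- data.frame(snp1 = sample(0:2, n, replace = TRUE), snp2 = 0L,
                  status = rbinom(n, 1, 0.5))
  fit <- fitLogistic(d, "main")
  oracle <- glm(status ~ factor(snp1, levels = 0:2), binomial, data = d)
  expect_equal(fit@logLik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  expect_equal(fit@df, 3L)  # intercept + 2 SNP1 dummies estimable
})

test_that("genotype-independent status drives coefficients to zero", {
  set.seed(12)
  d <- simulateBalancedDataset(
    PenetranceModel(0.5, 0.5, matrix(0.5, 3, 3)), 20000)
  fit <- fitLogistic(d, "interaction")
  expect_true(all(abs(fit@coefficients) < 0.45, na.rm = TRUE))
  expect_lt(abs(fit@coefficients[["(Intercept)"]]), 0.2)  # logit(0.5) = 0
})

test_that("classification applies a strict cutoff with ties to control", {
  expect_identical(classifyProb(c(0.49, 0.51)), c(0L, 1L))
  expect_identical(classifyProb(0.5), 0L)
  expect_identical(classifyProb(numeric(0)), integer(0))
  expect_error(classifyProb(c(0.2, 1.2)), "0, 1")
})

test_that("main-effects prediction at the reference genotype is logistic(b0)", {
  set.seed(13)
  d <- simulateBalancedDataset(builtinModels()[["Scenario 15"]], 1000)
  fit <- fitLogistic(d, "main")
  p00 <- predictProb(fit, data.frame(snp1 = 0L, snp2 = 0L, status = 0L))
  expect_equal(p00, plogis(unname(fit@coefficients["(Intercept)"])),
               tolerance = 1e-8)
})

test_that("empty training cells fall back to the main-effects prediction", {
  set.seed(14)
  d <- simulateBalancedDataset(builtinModels()[["Scenario 15"]], 800)
  d <- d[!(d$snp1 == 2 & d$snp2 == 2), ]
  fit <- fitLogistic(d, "interaction")
  expect_false(fit@cellsPresent[3, 3])
  expect_true(is.na(fit@coefficients[["snp1_2.snp2_2"]]))
  p22 <- predictProb(fit, data.frame(snp1 = 2L, snp2 = 2L, status = 1L))
  co <- fit@coefficients
  manual <- plogis(co[["(Intercept)"]] + co[["snp1_2"]] + co[["snp2_2"]])
  expect_equal(p22, manual, tolerance = 1e-8)
})

test_that("perfect separation saturates and is flagged, not fatal", {
  d <- data.frame(snp1 = rep(c(0L, 2L), each = 20),
                  snp2 = 0L, status = rep(c(0L, 1L), each = 20))
  fit <- fitLogistic(d, "interaction")
  expect_true(fit@separated)
  expect_equal(unname(fit@cellProbs[1, 1]), 0)
  expect_equal(unname(fit@cellProbs[3, 1]), 1)
  expect_error(fitLogistic(data.frame(snp1 = 0:1, snp2 = 0L,
                                      status = c(1L, 1L)), "main"),
               "single-class")
})

test_that("the LRT compares nested fits on the chi-square scale", {
  set.seed(15)
  d <- simulateBalancedDataset(builtinModels()[["Scenario 15"]], 2000)
  fmain <- fitLogistic(d, "main")
  fint <- fitLogistic(d, "interaction")
  lrt <- likelihoodRatioTest(fmain, fint)
  expect_equal(unname(lrt$parameter), 4)  # 9 - 5 parameters
  expect_gte(unname(lrt$statistic), 0)
  expect_equal(lrt$p.value,
               pchisq(unname(lrt$statistic), 4, lower.tail = FALSE))
  # nesting monotonicity of the log-likelihood
  expect_gte(fint@logLik, fmain@logLik - 1e-10)
  # identical fits: zero statistic, p = 1
  same <- likelihoodRatioTest(fmain, fmain)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  d2 <- d[1:1000, ]
  expect_error(likelihoodRatioTest(fitLogistic(d2, "main"), fint),
               "same data")
})

test_that("the LRT statistic is invariant to dose relabeling", {
  set.seed(16)
  d <- simulateBalancedDataset(builtinModels()[["Scenario 5"]], 1500)
  stat1 <- likelihoodRatioTest(fitLogistic(d, "main"),
                               fitLogistic(d, "interaction"))$statistic
  flip <- data.frame(snp1 = 2L - d$snp1, snp2 = 2L - d$snp2,
                     status = d$status)
  stat2 <- likelihoodRatioTest(fitLogistic(flip, "main"),
                               fitLogistic(flip, "interaction"))$statistic
  expect_equal(unname(stat1), unname(stat2), tolerance = 1e-7)
})

test_that("covariate adjustment changes the fit and supports prediction", {
  set.seed(17)
  n <- 1500
  d <- simulatePopulation(builtinModels()[["Scenario 15"]], n)
  d$age <- rnorm(n, 50, 8)
  # re-draw status with a real age effect on the logit scale
  d$status <- rbinom(n, 1, plogis(-2 + 0.04 * d$age))
  fit0 <- fitLogistic(d, "main")
  fitA <- fitLogistic(d, "main", covariates = "age")
  expect_equal(fitA@df, fit0@df + 1L)
  expect_gt(fitA@logLik, fit0@logLik)
  expect_gt(fitA@coefficients[["age"]], 0)
  p <- predictProb(fitA, d)
  expect_length(p, n)
  expect_true(all(p >= 0 & p <= 1))
  lrt <- likelihoodRatioTest(fit0, fitA)  # covariates nest too
  expect_equal(unname(lrt$parameter), 1)
  expect_error(predictProb(fitA, d[, c("snp1", "snp2", "status")]),
               "covariate")
})
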