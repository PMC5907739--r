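test_that("HWE genotype probabilities follow (1-q)^2, 2q(1-q), q^2", {
  expect_equal(unname(hweGenotypeProbs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hweGenotypeProbs(0.1)), c(0.81, 0.18, 0.01))
  expect_equal(unname(hweGenotypeProbs(0)), c(1, 0, 0))
  expect_error(hweGenotypeProbs(0.6), "0, 0.5")
  expect_error(hweGenotypeProbs(-0.1), "0, 0.5")
  expect_error(hweGenotypeProbs(c(0.1, 0.2)))
})

test_that("joint genotype probabilities are the HWE outer product", {
  m <- PenetranceModel(0.5, 0.5, matrix(0.5, 3, 3))
  f <- jointGenotypeProbs(m)
  expect_equal(unname(f[1, 1]), 0.0625)
  expect_equal(unname(f[1, 2]), 0.125)
  expect_equal(unname(f[2, 2]), 0.25)
  m2 <- PenetranceModel(0.1, 0.1, matrix(0.5, 3, 3))
  expect_equal(unname(jointGenotypeProbs(m2)[1, 1]), 0.81^2)

  set.seed(101)
  for (k in 1:10) {
    mod <- randomModel()
    f <- jointGenotypeProbs(mod)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    # rows/columns marginalize back to single-locus HWE
    expect_equal(rowSums(f), hweGenotypeProbs(maf1(mod)), tolerance = 1e-12)
    expect_equal(colSums(f), hweGenotypeProbs(maf2(mod)), tolerance = 1e-12)
  }
})

test_that("prevalence and heritability match a literal 9-term loop oracle", {
  set.seed(202)
  for (k in 1:20) {
    mod <- randomModel()
    expect_equal(populationPrevalence(mod),
                 oraclePrevalence(maf1(mod), maf2(mod), penetrance(mod)),
                 tolerance = 1e-12)
    expect_equal(modelHeritability(mod),
                 oracleHeritability(maf1(mod), maf2(mod), penetrance(mod)),
                 tolerance = 1e-12)
  }
  # constant penetrance: prevalence is the constant, heritability zero
  flat <- PenetranceModel(0.3, 0.2, matrix(0.37, 3, 3))
  expect_equal(populationPrevalence(flat), 0.37, tolerance = 1e-12)
  expect_equal(modelHeritability(flat), 0, tolerance = 1e-12)
  degenerate <- PenetranceModel(0.3, 0.2, matrix(1, 3, 3))
  expect_error(modelHeritability(degenerate), "degenerate")
})

test_that("bundled scenario algebra reproduces oracle-frozen values", {
  mods <- builtinModels()
  # values frozen from the independent loop oracle on the bundled tables
  expect_equal(populationPrevalence(mods[["Scenario 15"]]), 0.4999375,
               tolerance = 1e-9)
  expect_equal(modelHeritability(mods[["Scenario 15"]]), 0.0050277345,
               tolerance = 1e-8)
  expect_equal(populationPrevalence(mods[["Scenario 1"]]), 0.5000722,
               tolerance = 1e-9)
  expect_equal(modelHeritability(mods[["Scenario 1"]]), 0.0049622641,
               tolerance = 1e-8)
  expect_equal(marginalPenetrances(mods[["Scenario 15"]])$snp1,
               c(0.49975, 0.5, 0.5), tolerance = 1e-9)
})

test_that("marginal penetrances obey the law of total probability", {
  flat <- PenetranceModel(0.25, 0.4, matrix(0.42, 3, 3))
  expect_equal(marginalPenetrances(flat)$snp1, rep(0.42, 3))
  expect_equal(marginalPenetrances(flat)$snp2, rep(0.42, 3))
  set.seed(303)
  for (k in 1:10) {
    mod <- randomModel()
    marg <- marginalPenetrances(mod)
    expect_equal(marg$snp1, oracleMarginal1(maf2(mod), penetrance(mod)),
                 tolerance = 1e-12)
    K <- populationPrevalence(mod)
    expect_equal(sum(hweGenotypeProbs(maf1(mod)) * marg$snp1), K,
                 tolerance = 1e-12)
    expect_equal(sum(hweGenotypeProbs(maf2(mod)) * marg$snp2), K,
                 tolerance = 1e-12)
  }
})

test_that("the 15 bundled models load with the published parameters", {
  mods <- builtinModels()
  expect_length(mods, 15)
  expect_identical(names(mods), paste("Scenario", 1:15))
  s1 <- mods[["Scenario 1"]]
  expect_equal(maf1(s1), 0.1)
  expect_equal(maf2(s1), 0.1)
  expect_equal(unname(penetrance(s1)[1, ]), c(0.493, 0.526, 0.611))
  expect_equal(maf1(mods[["Scenario 12"]]), 0.5)
  expect_equal(maf2(mods[["Scenario 12"]]), 0.2)
  # the published design: heritability 0.005 for every scenario
  h2 <- vapply(mods, modelHeritability, numeric(1))
  expect_true(all(h2 > 0.0049 & h2 < 0.0051))
  # 14 of 15 scenarios imply the design prevalence of 0.5 to ~3e-4;
  # the published Scenario 11 table is a known misprint (prevalence 0.33)
  K <- vapply(mods, populationPrevalence, numeric(1))
  expect_true(all(abs(K[-11] - 0.5) < 0.001))
  expect_equal(unname(K[11]), 0.328205, tolerance = 1e-9)
})

test_that("penetrance model validity is enforced", {
  expect_error(PenetranceModel(0.7, 0.1, matrix(0.5, 3, 3)), "0, 0.5")
  expect_error(PenetranceModel(0.1, 0, matrix(0.5, 3, 3)), "0, 0.5")
  expect_error(PenetranceModel(0.1, 0.1, matrix(0.5, 2, 2)), "3x3")
  expect_error(PenetranceModel(0.1, 0.1, matrix(1.5, 3, 3)), "0, 1")
})

test_that("penetrance models round-trip through the YAML format", {
  mod <- PenetranceModel(0.15, 0.45,
                         matrix(seq(0.1, 0.9, by = 0.1), 3, 3),
                         label = "round trip")
  path <- withr::local_tempfile(fileext = ".yaml")
  writePenetranceModel(mod, path)
  back <- readPenetranceModel(path)
  expect_equal(maf1(back), maf1(mod))
  expect_equal(maf2(back), maf2(mod))
  expect_equal(unname(penetrance(back)), unname(penetrance(mod)))
  expect_identical(modelLabel(back), "round trip")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("maf1: 0.1", bad)
  expect_error(readPenetranceModel(bad), "must contain keys")
})
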