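test_that("spec validation enforces the documented invariants", {
  expect_error(syntheticSpec(nSubjects = 2), "at least 3")
  expect_error(syntheticSpec(goFractionComplex = 0), "strictly in")
  expect_error(syntheticSpec(noiseSd = 0), "positive")
  expect_error(syntheticSpec(exgaussParams = list(
    simple = c(mu = 300, sigma = 0, tau = 50),
    complex = c(mu = 300, sigma = 30, tau = 50))), "positive")
  expect_error(plantedDimension(c(1, 2)), "named")
  expect_error(plantedDimension(c(a = Inf)), "finite")
})

test_that("identical spec and seed give bit-identical outputs", {
  spec <- syntheticSpec(seed = 123)
  t1 <- generateStudyTables(spec)
  t2 <- generateStudyTables(spec)
  expect_identical(t1, t2)
  l1 <- generateTrials(spec, "S05", "complex")
  l2 <- generateTrials(spec, "S05", "complex")
  expect_identical(l1, l2)
  spec2 <- syntheticSpec(seed = 124)
  expect_false(identical(generateStudyTables(spec2), t1))
  # different subjects / tasks get independent streams
  expect_false(identical(generateTrials(spec, "S06", "complex")$rt_ms,
                         l1$rt_ms))
})

test_that("complex-task GO fraction matches its binomial target", {
  spec <- syntheticSpec(nTrialsPerTask = 10000, seed = 31)
  log <- generateTrials(spec, 1, "complex")
  phat <- mean(log$is_go)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(phat - 0.25), 3 * se)
})

test_that("degenerate ex-Gaussian parameters collapse the RT distribution", {
  spec <- syntheticSpec(nTrialsPerTask = 200, goFractionSimple = 0.99,
                        omissionRate = 0, seed = 8)
  log <- generateTrials(spec, 1, "simple",
                        exgauss = c(mu = 350, sigma = 1e-9, tau = 1e-9))
  rts <- log$rt_ms[!is.na(log$rt_ms)]
  expect_lt(max(rts) - min(rts), 1e-6)
  expect_equal(mean(rts), 350, tolerance = 1e-6)
})

test_that("commission responses appear on NO-GO trials at the set rate", {
  spec <- syntheticSpec(nTrialsPerTask = 20000, commissionRate = 0.1,
                        seed = 77)
  log <- generateTrials(spec, 2, "complex")
  nogo <- !log$is_go
  rate <- mean(log$responded[nogo])
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / sum(nogo)))
  # rt present iff responded
  expect_true(all(is.na(log$rt_ms) == !log$responded))
})

test_that("marginal rescaling reproduces target sample moments exactly", {
  tabs <- generateStudyTables(syntheticSpec(seed = 9))
  expect_equal(mean(tabs$biological$IAF), 10.303, tolerance = 1e-6)
  expect_equal(sd(tabs$biological$IAF), 0.718, tolerance = 1e-6)
  expect_equal(mean(tabs$behavioral$SKWCRT), 1.41, tolerance = 1e-6)
  expect_equal(sd(tabs$demographic$age), 8.5, tolerance = 1e-6)
})

test_that("planted loadings must name known variables on two or more blocks", {
  expect_error(generateStudyTables(syntheticSpec(
    latentEffects = list(plantedDimension(c(NOPE = 0.5, CRT = 0.5))),
    seed = 1)), "not in variable layout")
  expect_error(generateStudyTables(syntheticSpec(
    latentEffects = list(plantedDimension(c("SLF-L" = 0.5, "UNC-L" = 0.4))),
    seed = 1)), "at least two blocks")
})

test_that("the empirical correlation structure matches the closed-form factor model", {
  eff <- studySupportEffects()
  spec <- syntheticSpec(nSubjects = 5000, latentEffects = eff, seed = 55)
  tabs <- generateStudyTables(spec)
  d <- cbind(tabs$biological[-1], tabs$demographic[-1], tabs$behavioral[-1])
  oracle <- popCovOracle(eff, colnames(d), noiseSd = 1)
  emp <- cor(d)
  expect_lt(max(abs(emp - oracle$cor)), 0.05)
})

test_that("large-sample canonical correlations match the factor-model oracle", {
  eff <- studySupportEffects()[1]
  spec <- syntheticSpec(nSubjects = 5000, latentEffects = eff, seed = 56)
  bs <- generateBlocks(spec)
  fit <- fitSmcca(bs, c(sqrt(6), 1, sqrt(2)), nDims = 1, maxIter = 100)
  vars <- unlist(lapply(blocks(bs), colnames), use.names = FALSE)
  oracle <- popCovOracle(eff, vars, noiseSd = 1)
  idx <- split(seq_along(vars), rep(blockNames(bs), blockDims(bs)))
  pairs <- list(c("biological", "demographic"),
                c("biological", "behavioral"),
                c("demographic", "behavioral"))
  robs <- canonicalCorrelations(fit)[, 1]
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]
    j <- pairs[[k]][2]
    rModel <- modelScoreCor(oracle$covAnalysis, vars,
                            weightMatrix(fit, i)[, 1],
                            weightMatrix(fit, j)[, 1],
                            idx[[i]], idx[[j]])
    expect_lt(abs(abs(robs[paste(i, j, sep = ":")]) - abs(rModel)), 0.02)
  }
})

test_that("a null generator yields only weak canonical correlations at large n", {
  spec <- syntheticSpec(nSubjects = 600, latentEffects = list(), seed = 57)
  fit <- suppressWarnings(fitSmcca(generateBlocks(spec), c(2.5, 1.3, 1.8),
                                   nDims = 1, maxIter = 100))
  expect_lt(max(abs(canonicalCorrelations(fit))), 0.25)
})

test_that("sex is Bernoulli with the study's male fraction", {
  spec <- syntheticSpec(nSubjects = 4000, latentEffects = list(), seed = 58)
  tabs <- generateStudyTables(spec)
  expect_true(all(tabs$demographic$sex %in% c(0, 1)))
  expect_lt(abs(mean(tabs$demographic$sex) - 10 / 24),
            3 * sqrt((10 / 24) * (14 / 24) / 4000))
})

test_that("the trial-derived behavioral path carries the planted effects", {
  eff <- studySupportEffects()
  spec <- syntheticSpec(nSubjects = 150, latentEffects = eff, seed = 60)
  tabs <- generateStudyTables(spec, behavioralFrom = "trials")
  expect_false(is.null(tabs$logs))
  expect_equal(nrow(tabs$behavioral), 150)
  d <- cbind(tabs$biological[-1], tabs$behavioral[-1])
  # CRT was planted on the same factor as SLF: correlation must survive the
  # trial simulation and re-summarization
  expect_gt(cor(d[["SLF-L"]], d[["CRT"]]), 0.2)
  # trial path and direct path agree on subject-level targets up to
  # trial-sampling noise
  direct <- generateStudyTables(spec, behavioralFrom = "direct")
  expect_gt(cor(direct$behavioral$CRT, tabs$behavioral$CRT), 0.9)
})

test_that("synthetic outputs round-trip through disk with provenance", {
  spec <- syntheticSpec(seed = 61)
  tabs <- generateStudyTables(spec)
  dir <- tempfile("synth")
  writeSyntheticData(tabs, spec, dir)
  expect_true(file.exists(file.path(dir, "biological.csv")))
  expect_true(file.exists(file.path(dir, "synthetic_spec.yaml")))
  back <- read.csv(file.path(dir, "biological.csv"), check.names = FALSE)
  expect_equal(back$IAF, tabs$biological$IAF, tolerance = 1e-9)
  y <- yaml::read_yaml(file.path(dir, "synthetic_spec.yaml"))
  expect_equal(y$seed, 61)
})
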