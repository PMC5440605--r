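# Synthetic-data generators: determinism, distributional targets, planted
# structure.

test_that("simulateCohort is deterministic for a fixed seed and validates input", {
  a <- simulateCohort(21, seed = 1)
  b <- simulateCohort(21, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, simulateCohort(21, seed = 2)))
  expect_false(anyDuplicated(a$subject_id) > 0)

  expect_error(simulateCohort(1), "at least 2")
  expect_error(simulateCohort(10, outcomeSpec = list(x = list(family = "gamma"))),
               "unknown distribution family")
})

test_that("cell proportions are a simplex", {
  co <- simulateCohort(50, seed = 3)
  p <- as.matrix(co[, grep("^cell_", names(co))])
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, 50), tolerance = 1e-12)
})

test_that("lognormal outcomes are right-skewed as specified", {
  co <- simulateCohort(1000,
    outcomeSpec = list(pct_fat = list(family = "lognormal", meanlog = 3,
                                      sdlog = 0.4)), seed = 7)
  # large-sample check against the lognormal moment skewness
  # (e^s2+2)sqrt(e^s2-1) = 1.32 at sdlog 0.4, so well above 1
  expect_gt(momentSkewness(co$pct_fat), 1)
})

test_that("collinear cell mixtures regress on the outcome with R2 >= 0.9", {
  co <- simulateCohort(500, collinearCells = TRUE, seed = 11)
  y <- co$pct_fat
  for (col in grep("^cell_", names(co), value = TRUE)) {
    r2 <- summary(lm(co[[col]] ~ y))$r.squared
    expect_gte(r2, 0.9)
  }
})

test_that("within-block Spearman correlation hits its target", {
  co <- simulateCohort(500, seed = 5)
  me <- simulateMethylation(co, nCpg = 10,
    blockSpec = list(list(cpgs = 1:5, rho = 0.9),
                     list(cpgs = 6:10, rho = 0.9)), seed = 6)
  v <- methValues(me)
  rhos <- c()
  for (b in list(1:5, 6:10)) {
    cm <- cor(v[, b], method = "spearman")
    rhos <- c(rhos, cm[upper.tri(cm)])
  }
  expect_gte(median(rhos), 0.8)
  expect_lte(median(rhos), 1.0)
  expect_true(all(v >= 0 & v <= 100))
})

test_that("null generator leaves methylation uncorrelated with the outcome", {
  co <- simulateCohort(500, seed = 9)
  me <- simulateMethylation(co, nCpg = 20,
    blockSpec = list(list(cpgs = 1:20, rho = 0.5)), seed = 10)
  r <- cor(methValues(me), co$pct_fat)
  expect_lt(mean(abs(r)), 0.1)
})

test_that("planted slopes are recovered by OLS within 2 standard errors", {
  co <- simulateCohort(250, seed = 13)
  me <- simulateMethylation(co, nCpg = 4,
    blockSpec = list(list(cpgs = 1:4, rho = 0.8)),
    effects = list(list(cpgs = 1:2, slope = -0.5)),
    baselines = rep(50, 4), seed = 14)
  fit <- summary(lm(methValues(me)[, 1] ~ co$pct_fat))$coefficients
  expect_lt(abs(fit[2, 1] - (-0.5)), 2 * fit[2, 2])
})

test_that("block overlap and heavy clipping are rejected/reported", {
  co <- simulateCohort(20, seed = 1)
  expect_error(simulateMethylation(co, nCpg = 4,
    blockSpec = list(list(cpgs = 1:3, rho = 0.8),
                     list(cpgs = 3:4, rho = 0.8))), "partition")
  expect_warning(simulateMethylation(co, nCpg = 2,
    blockSpec = list(list(cpgs = 1:2, rho = 0.8)),
    effects = list(list(cpgs = 1:2, slope = 20)),
    baselines = c(50, 50), seed = 2), "clipping")
})

test_that("array signal follows the stated linear model exactly at zero noise", {
  des <- smallDesign(2)
  co <- simulateCohort(4, seed = 1)
  zero <- simulateMethylation(co, nCpg = length(des$cpgs),
    blockSpec = segmentBlocks(2), baselines = rep(50, 50),
    positions = des$cpgs, seed = 2)
  zero@values[] <- 0
  sig0 <- simulateArray(zero, des$probes, gain = 1, baseline = 0,
                        noiseSd = 1e-12, failedRate = 0, dMax = des$dMax,
                        seed = 3)
  expect_equal(max(abs(signalMatrix(sig0))), 0, tolerance = 1e-9)

  full <- zero
  full@values[] <- 100
  sigF <- simulateArray(full, des$probes, gain = 1, baseline = 0,
                        noiseSd = 1e-12, failedRate = 0, dMax = des$dMax,
                        seed = 3)
  cs <- Matrix::rowSums(couplingWeights(
    buildCoupling(des$probes, des$cpgs, dMax = des$dMax)))
  expect_equal(unname(signalMatrix(sigF)[, 1]), unname(cs),
               tolerance = 1e-9)
})

test_that("planted failed probes are detected and counted binomially", {
  des <- arrayDesign(nSegments = 67, probesPerWindow = 3)  # ~1000 probes
  co <- simulateCohort(6, seed = 1)
  me <- simulateMethylation(co, nCpg = length(des$cpgs),
    blockSpec = segmentBlocks(67), baselines = rep(50, length(des$cpgs)),
    positions = des$cpgs, seed = 2)
  sig <- simulateArray(me, des$probes, failedRate = 0.1, dMax = des$dMax,
                       seed = 3)
  n <- length(des$probes)
  flagged <- which(failedProbes(detectFailedProbes(sig, epsilon = 0.05)))
  expect_identical(flagged, groundTruth(sig)$plantedFailed)
  # binomial 95% interval around n * 0.1
  expect_gt(length(flagged), 0.1 * n - 1.96 * sqrt(n * 0.1 * 0.9))
  expect_lt(length(flagged), 0.1 * n + 1.96 * sqrt(n * 0.1 * 0.9))
})

test_that("expression links carry the planted sign; zero magnitude is null", {
  co <- simulateCohort(300, seed = 20)
  me <- simulateMethylation(co, nCpg = 9,
    blockSpec = list(list(cpgs = 1:9, rho = 0.9)),
    baselines = rep(50, 9), seed = 21)
  nPos <- 0; nNeg <- 0; reps <- 40
  for (s in seq_len(reps)) {
    ex <- simulateExpression(me,
      links = list(up = list(cpgs = 4:8, sign = 1, magnitude = 0.08),
                   dn = list(cpgs = 9, sign = -1, magnitude = 0.08)),
      seed = s)
    drv <- rowMeans(methValues(me)[, 4:8])
    nPos <- nPos + (coef(lm(ex$dct_up ~ drv))[2] > 0)
    nNeg <- nNeg + (coef(lm(ex$dct_dn ~ methValues(me)[, 9]))[2] < 0)
  }
  expect_gte(nPos / reps, 0.95)
  expect_gte(nNeg / reps, 0.95)

  ex0 <- simulateExpression(me,
    links = list(nul = list(cpgs = 1:3, sign = 1, magnitude = 0)), seed = 1)
  expect_lt(abs(cor(ex0$dct_nul, rowMeans(methValues(me)[, 1:3]))), 0.15)
  # recomputing dCt from the Ct columns recovers the stored values
  expect_equal(deltaCt(ex0$ct_nul, ex0$ct_ref1, ex0$ct_ref2), ex0$dct_nul,
               tolerance = 1e-12)
  expect_error(simulateExpression(me,
    links = list(x = list(cpgs = 12, sign = 1, magnitude = 1))),
    "outside matrix")
  expect_error(simulateExpression(me,
    links = list(x = list(cpgs = 1, sign = 2, magnitude = 1))),
    "sign")
})
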