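# Coupling construction, failed-probe detection, calibration, and the grid
# posterior for window methylation.

test_that("coupling weights follow the triangular decay", {
  # CpGs at 0-based 100, 120, 140; probe with midpoint 100 (0-based)
  cpgs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(101, 121, 141), width = 1))
  probe <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 76, end = 125))
  names(probe) <- "p1"
  cm <- buildCoupling(probe, cpgs, dMax = 40)
  w <- as.matrix(couplingWeights(cm))
  expect_equal(unname(w[1, ]), c(1, 0.5, 0))   # d = 0, dMax/2, dMax
  expect_error(buildCoupling(probe, rev(cpgs), dMax = 40), "sorted")
  expect_error(buildCoupling(probe, cpgs, dMax = 0), "positive")
})

test_that("failed probes are flagged by the epsilon band", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 50))
  names(gr) <- c("a", "b")
  sig <- ArraySignals(gr, matrix(c(0.0, 0.5), ncol = 1))
  out <- detectFailedProbes(sig, epsilon = 0.05)
  expect_identical(unname(failedProbes(out)), c(TRUE, FALSE))
  expect_error(detectFailedProbes(sig, epsilon = 0), "positive")
})

test_that("grid posterior matches a brute-force enumeration oracle", {
  # window [0, 100); one CpG at its centre; probes with coupling sums 1, 0.5
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 1, width = 100))
  cpgs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 51, width = 1))
  probes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(26, 46), end = c(75, 95)))  # mids 50, 70
  names(probes) <- c("p1", "p2")
  cm <- buildCoupling(probes, cpgs, dMax = 40)
  s <- Matrix::rowSums(couplingWeights(cm))
  expect_equal(unname(s), c(1, 0.5))

  y <- c(0.5, 0.25)
  sig <- ArraySignals(probes, matrix(y, ncol = 1))
  prof <- estimateWindowMethylation(sig, cm, win, gain = 1, baseline = 0,
                                    noiseSd = 0.1, gridStep = 0.01)
  # independent naive enumeration of the same posterior
  grid <- seq(0, 1, by = 0.01)
  lik <- vapply(grid, function(m)
    prod(dnorm(y, mean = m * s, sd = 0.1)), numeric(1))
  post <- lik / sum(lik)
  expect_equal(methMode(prof)[1, 1], 0.5)
  expect_equal(methMean(prof)[1, 1], sum(grid * post), tolerance = 1e-12)
  ci <- methCI(prof)
  expect_lte(ci$lo[1, 1], methMean(prof)[1, 1])
  expect_gte(ci$hi[1, 1], methMean(prof)[1, 1])
  expect_equal(probesUsed(prof), 2L)
})

test_that("noise-free signals put the posterior mode at the truth", {
  des <- smallDesign(2)
  co <- simulateCohort(3, seed = 1)
  me <- simulateMethylation(co, nCpg = length(des$cpgs),
    blockSpec = segmentBlocks(2), baselines = rep(50, 50),
    positions = des$cpgs, seed = 2)
  me@values[] <- 0
  sig <- simulateArray(me, des$probes, gain = 1, baseline = 0.5,
                       noiseSd = 1e-9, failedRate = 0, dMax = des$dMax, seed = 3)
  cm <- buildCoupling(des$probes, des$cpgs, dMax = des$dMax)
  prof <- estimateWindowMethylation(sig, cm, des$windows, gain = 1,
                                    baseline = 0.5, noiseSd = 0.05)
  expect_true(all(methMode(prof) == 0))

  me@values[] <- 100
  sigF <- simulateArray(me, des$probes, gain = 1, baseline = 0.5,
                        noiseSd = 1e-9, failedRate = 0, dMax = des$dMax, seed = 3)
  profF <- estimateWindowMethylation(sigF, cm, des$windows, gain = 1,
                                     baseline = 0.5, noiseSd = 0.05)
  expect_true(all(methMode(profF) == 1))
})

test_that("posterior mean is monotone in any single probe signal", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 1, width = 100))
  cpgs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 51, width = 1))
  probes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(26, 46), end = c(75, 95)))
  names(probes) <- c("p1", "p2")
  cm <- buildCoupling(probes, cpgs, dMax = 40)
  means <- vapply(seq(-0.2, 1.2, by = 0.05), function(y1) {
    sig <- ArraySignals(probes, matrix(c(y1, 0.3), ncol = 1))
    methMean(estimateWindowMethylation(sig, cm, win, gain = 1, baseline = 0,
                                       noiseSd = 0.1))[1, 1]
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-12))
})

test_that("removing failed probes leaves fully-clean windows unchanged", {
  fix <- makeDiscovery(seed = 4, nSeg = 6, n = 8, failedRate = 0.15)
  cm <- buildCoupling(fix$sig, fix$des$cpgs, dMax = fix$des$dMax)
  profAll <- estimateWindowMethylation(fix$sig, cm, fix$des$windows,
    gain = 1, baseline = 0.5, noiseSd = 0.15)
  sigClean <- detectFailedProbes(fix$sig, 0.05)
  profClean <- estimateWindowMethylation(sigClean, cm, fix$des$windows,
    gain = 1, baseline = 0.5, noiseSd = 0.15)
  failedIdx <- which(failedProbes(sigClean))
  expect_gt(length(failedIdx), 0)
  # windows whose probes are all clean: 3 probes per window, in order
  winOf <- rep(seq_len(30), each = 3)
  cleanWins <- setdiff(seq_len(30), unique(winOf[failedIdx]))
  expect_equal(methMean(profAll)[cleanWins, ],
               methMean(profClean)[cleanWins, ], tolerance = 1e-12)
})

test_that("windows without usable probes are NA, never imputed", {
  win <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 1001), width = 100))
  cpgs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(51, 1051), width = 1))
  probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 26, end = 75))
  names(probes) <- "p1"
  cm <- buildCoupling(probes, cpgs, dMax = 40)
  sig <- ArraySignals(probes, matrix(0.4, ncol = 1))
  prof <- estimateWindowMethylation(sig, cm, win, gain = 1, baseline = 0,
                                    noiseSd = 0.1)
  expect_false(is.na(methMean(prof)[1, 1]))
  expect_true(is.na(methMean(prof)[2, 1]))
  expect_identical(probesUsed(prof), c(1L, 0L))
})

test_that("calibration recovers gain, baseline and noise from designated windows", {
  des <- smallDesign(4)
  co <- simulateCohort(10, seed = 6)
  me <- simulateMethylation(co, nCpg = length(des$cpgs),
    blockSpec = segmentBlocks(4), baselines = rep(50, 100),
    positions = des$cpgs, seed = 7)
  # designate segment 1 fully methylated, segment 2 unmethylated
  v <- methValues(me)
  v[, 1:25] <- 100; v[, 26:50] <- 0
  me2 <- CpGMethylationMatrix(v, cpgPositions(me))
  sig <- simulateArray(me2, des$probes, gain = 1.6, baseline = 0.4,
                       noiseSd = 0.1, failedRate = 0, dMax = des$dMax, seed = 8)
  cm <- buildCoupling(sig, des$cpgs, dMax = des$dMax)
  cal <- calibrateSignalModel(sig, cm, fullWindows = des$windows[1:5],
                              zeroWindows = des$windows[6:10])
  expect_equal(cal$gain, 1.6, tolerance = 0.05)
  expect_equal(cal$baseline, 0.4, tolerance = 0.05)
  expect_lt(abs(cal$noiseSd - 0.1), 0.015)
})

test_that("estimator input contracts are enforced", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 1, width = 100))
  cpgs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 51, width = 1))
  probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 26, end = 75))
  names(probes) <- "p1"
  cm <- buildCoupling(probes, cpgs, dMax = 40)
  sig <- ArraySignals(probes, matrix(0.4, ncol = 1))
  expect_error(estimateWindowMethylation(sig, cm, win, gain = 0,
    baseline = 0, noiseSd = 0.1), "gain")
  expect_error(estimateWindowMethylation(sig, cm, win, gain = 1,
    baseline = 0, noiseSd = 0), "noiseSd")
  expect_error(estimateWindowMethylation(sig, cm, win, gain = 1,
    baseline = 0, noiseSd = 0.1, gridStep = 0.03), "divide")
  # jeffreys prior runs and keeps the interval bracketing the mean
  p <- estimateWindowMethylation(sig, cm, win, gain = 1, baseline = 0,
                                 noiseSd = 0.3, prior = "jeffreys")
  expect_lte(methCI(p)$lo[1, 1], methMean(p)[1, 1])
  expect_gte(methCI(p)$hi[1, 1], methMean(p)[1, 1])
})
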