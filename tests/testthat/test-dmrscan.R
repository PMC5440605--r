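# Robust window regression, tertile filter, span enrichment and the
# DMR-calling orchestration.

test_that("Huber fit reduces to OLS on clean linear data", {
  x <- seq_len(20)
  y <- 1 + 2 * x
  fit <- huberRegression(y, x)
  expect_equal(fit$coef[2], 2, tolerance = 1e-8)
  set.seed(42)
  y2 <- 1 + 2 * x + rnorm(20, 0, 0.3)  # no gross outliers
  h <- huberRegression(y2, x)
  o <- coef(lm(y2 ~ x))
  expect_equal(h$coef[2], unname(o[2]), tolerance = 0.05)
})

test_that("Huber resists a gross outlier better than OLS", {
  set.seed(1)
  x <- seq(0, 10, length.out = 30)
  y <- x + rnorm(30, 0, 0.2)
  y[30] <- y[30] + 25
  h <- huberRegression(y, x)$coef[2]
  o <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(h - 1), abs(o - 1))
})

test_that("Huber IRLS matches an independently coded oracle", {
  # oracle: plain IRLS loop with the same published definitions
  irlsOracle <- function(y, x, k = 1.345, tol = 1e-8, maxit = 50) {
    X <- cbind(1, x)
    b <- solve(t(X) %*% X) %*% t(X) %*% y
    for (i in seq_len(maxit)) {
      r <- as.vector(y - X %*% b)
      s <- median(abs(r)) / 0.6745
      if (s < 1e-10) break
      w <- pmin(1, k * s / abs(r))
      W <- diag(w)
      bn <- solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y
      if (max(abs(bn - b)) < tol * max(1, max(abs(b)))) { b <- bn; break }
      b <- bn
    }
    as.vector(b)
  }
  set.seed(7)
  x <- rnorm(10)
  y <- 2 - 1.5 * x + rt(10, df = 3)
  fit <- huberRegression(y, x)
  expect_equal(fit$coef, irlsOracle(y, x), tolerance = 1e-6)
  # and stays close to the reference M-estimator implementation
  rl <- MASS::rlm(y ~ x, k = 1.345, maxit = 100)
  expect_equal(fit$coef[2], unname(coef(rl)[2]), tolerance = 1e-3)
})

test_that("window regression handles missing windows and small n", {
  meth <- rbind(seq(30, 53, by = 1),       # 24 subjects, slope 1 per unit
                rep(NA_real_, 24))
  pheno <- seq_len(24)
  st <- robustWindowRegression(meth, pheno)
  expect_equal(st$slope[1], 1, tolerance = 1e-8)
  expect_true(is.na(st$slope[2]))
  expect_identical(st$n[2], 0L)
  expect_error(robustWindowRegression(meth, rep(1, 24)), "variance")
})

test_that("tertile difference is the group-3 minus group-1 absolute gap", {
  # 9 subjects, phenotype 1..9; window means 30 in low, 55 in high tertile
  meth <- matrix(c(rep(30, 3), rep(40, 3), rep(55, 3)), nrow = 1)
  expect_equal(tertileDifference(meth, 1:9)[1], 25)
  meth2 <- matrix(c(rep(30, 3), rep(40, 3), rep(45, 3)), nrow = 1)
  expect_equal(tertileDifference(meth2, 1:9)[1], 15)
  # strict inequality at the filter: exactly 20 fails
  meth3 <- matrix(c(rep(30, 3), rep(40, 3), rep(50, 3)), nrow = 1)
  st <- data.frame(p_value = 0.001)
  expect_false(flagWindows(st, tertileDifference(meth3, 1:9),
                           pThreshold = 0.01, diffThreshold = 20))
  expect_true(flagWindows(st, tertileDifference(meth, 1:9), 0.01, 20))
  expect_false(flagWindows(data.frame(p_value = 0.001), 10, 0.01, 20))
  expect_false(flagWindows(data.frame(p_value = 0.5), 25, 0.01, 20))
})

test_that("span enrichment equals exhaustive hypergeometric enumeration", {
  flagged <- c(rep(TRUE, 10), rep(FALSE, 90))  # 10 flagged of 100
  spans <- list(1:5, 11:15)
  res <- spanEnrichment(flagged, spans)
  expect_equal(res$fisher_p[1], choose(10, 5) / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(res$fisher_p[1], 3.35e-6, tolerance = 0.01)
  expect_equal(res$fisher_p[2], 1)       # 0 flagged -> upper tail from 0

  # brute force on random small instances (N <= 30)
  set.seed(3)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    fl <- runif(N) < runif(1)
    sz <- sample(2:max(2, N %/% 2), 1)
    sp <- list(seq_len(sz))
    got <- spanEnrichment(fl, sp)$fisher_p[1]
    want <- enumFisherP(sum(fl[sp[[1]]]), sum(fl), N, sz)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(spanEnrichment(flagged, list(integer(0))), "zero windows")
})

test_that("spans are maximal runs broken by gaps over 100 nt", {
  win <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 101, 201, 501, 601), width = 100))
  sp <- makeSpans(win, maxGap = 100)
  expect_equal(sp, list(1:3, 4:5))
  # singleton runs are dropped by the minimum-size rule
  win2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 1001, 1101), width = 100))
  expect_equal(makeSpans(win2), list(2:3))
})

test_that("a planted DMR is called and a fully-failed DMR is not", {
  fix <- makeDiscovery(seed = 31, nSeg = 10, dmrSegment = 4)
  calls <- callDMRs(fix$sig, fix$des$cpgs, fix$des$windows, fix$co$pct_fat,
                    gain = 1, baseline = 0.5, noiseSd = 0.15, dMax = 40)
  expect_true(4 %in% calls$span)
  expect_true(all(calls$robust_to_failed_probes))

  # force every probe of the planted span to read as failed
  sig2 <- fix$sig
  idx <- ((4 - 1) * 15 + 1):(4 * 15)   # the 15 probes of segment 4
  set.seed(9)
  mat <- signalMatrix(sig2)
  mat[idx, ] <- matrix(runif(length(idx) * ncol(mat), -0.015, 0.015),
                       length(idx))
  sig2 <- ArraySignals(probeRanges(sig2), mat)
  calls2 <- callDMRs(sig2, fix$des$cpgs, fix$des$windows, fix$co$pct_fat,
                     gain = 1, baseline = 0.5, noiseSd = 0.15, dMax = 40)
  expect_false(4 %in% calls2$span)
})

test_that("DMR calls are invariant to probe record order", {
  fix <- makeDiscovery(seed = 33, nSeg = 6, dmrSegment = 2)
  calls <- callDMRs(fix$sig, fix$des$cpgs, fix$des$windows, fix$co$pct_fat,
                    gain = 1, baseline = 0.5, noiseSd = 0.15, dMax = 40)
  set.seed(5)
  perm <- sample(length(fix$des$probes))
  sigP <- ArraySignals(probeRanges(fix$sig)[perm],
                       signalMatrix(fix$sig)[perm, , drop = FALSE])
  callsP <- callDMRs(sigP, fix$des$cpgs, fix$des$windows, fix$co$pct_fat,
                     gain = 1, baseline = 0.5, noiseSd = 0.15, dMax = 40)
  expect_equal(calls, callsP)
})
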