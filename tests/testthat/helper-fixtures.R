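# Shared fixture builders: everything is generated in code at test time.

# a small tiled design (nSeg segments x 5 windows)
smallDesign <- function(nSeg = 10) arrayDesign(nSegments = nSeg)

# per-segment block spec for a design's CpGs
segmentBlocks <- function(nSeg, perSeg = 25, rho = 0.85) {
  lapply(seq_len(nSeg), function(s)
    list(cpgs = ((s - 1) * perSeg + 1):(s * perSeg), rho = rho))
}

# cohort + methylation + array signals over a small design, optionally with
# a planted DMR in `dmrSegment`
makeDiscovery <- function(seed, nSeg = 10, n = 24, dmrSegment = NULL,
                          slope = -3, failedRate = 0.05) {
  des <- smallDesign(nSeg)
  co <- simulateCohort(n, seed = seed)
  eff <- NULL
  if (!is.null(dmrSegment)) {
    cpgs <- ((dmrSegment - 1) * 25 + 1):(dmrSegment * 25)
    eff <- list(list(cpgs = cpgs, slope = slope))
  }
  me <- simulateMethylation(co, nCpg = length(des$cpgs),
    blockSpec = segmentBlocks(nSeg), effects = eff,
    baselines = rep(50, length(des$cpgs)), positions = des$cpgs,
    seed = seed + 1000L)
  sig <- simulateArray(me, des$probes, dMax = des$dMax,
                       failedRate = failedRate, seed = seed + 2000L)
  list(des = des, co = co, me = me, sig = sig)
}

# window-mean ground truth (% -> fraction), windows x subjects layout
windowTruth <- function(me, perWindow = 5) {
  v <- methValues(me) / 100
  nw <- ncol(v) / perWindow
  t(apply(v, 1, function(r) tapply(r, rep(seq_len(nw), each = perWindow),
                                   mean)))
}

# brute-force hypergeometric upper-tail by direct enumeration with choose()
enumFisherP <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# independent OLS oracle via normal equations + t quantiles
olsOracle <- function(y, X, level = 0.95) {
  X <- cbind(1, X)
  XtX <- solve(t(X) %*% X)
  b <- XtX %*% t(X) %*% y
  r <- y - X %*% b
  s2 <- sum(r^2) / (length(y) - ncol(X))
  se <- sqrt(diag(XtX) * s2)
  tq <- qt(1 - (1 - level) / 2, length(y) - ncol(X))
  tt <- b / se
  list(beta = as.vector(b), se = as.vector(se),
       ci = cbind(as.vector(b) - tq * se, as.vector(b) + tq * se),
       p = as.vector(2 * pt(-abs(tt), length(y) - ncol(X))))
}
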