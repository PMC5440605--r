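# Phenotype-associated DMR calling over the window tiling:
# per-window Huber robust regression (methylation on phenotype, guarding
# against heteroscedastic estimates), a tertile-difference filter, one-sided
# Fisher-exact enrichment of flagged windows within contiguous spans, and an
# intersection requiring each call to survive removal of failed probes.
# No genome-wide multiple-testing correction is applied: the stringent
# joint filter (window p, absolute group difference, span enrichment in two
# datasets) is the screening criterion.

#' Huber robust regression (IRLS)
#'
#' M-estimation of `y = a + b x` with the Huber loss, fitted by iteratively
#' reweighted least squares: tuning constant `k = 1.345`, residual scale
#' re-estimated each iteration as `median(|r|)/0.6745`, convergence
#' tolerance `1e-8` on the coefficients, at most 50 iterations. The
#' coefficient variance uses the large-sample sandwich
#' `s^2 * sum(psi^2)/(n-p) / mean(psi')^2 * (X'X)^{-1}`; p-values come from
#' the normal approximation. With no gross residuals the fit coincides with
#' OLS.
#'
#' @param y Response (percent methylation).
#' @param x Predictor (phenotype).
#' @param k Huber tuning constant.
#' @param tol Convergence tolerance.
#' @param maxit Iteration cap.
#' @return List: `coef` (intercept, slope), `se`, `p`, `scale`,
#'   `iterations`, `converged`.
#' @export
huberRegression <- function(y, x, k = 1.345, tol = 1e-8, maxit = 50L) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("zero phenotype variance")
  X <- cbind(1, x)
  b <- stats::lm.fit(X, y)$coefficients
  iter <- 0L; converged <- FALSE
  s <- 1
  repeat {
    iter <- iter + 1L
    r <- y - X %*% b
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-10) { converged <- TRUE; break }
    w <- pmin(1, k * s / pmax(abs(r), 1e-300))
    bNew <- stats::lm.wfit(X, y, as.vector(w))$coefficients
    if (max(abs(bNew - b)) < tol * max(1, max(abs(b)))) {
      b <- bNew; converged <- TRUE; break
    }
    b <- bNew
    if (iter >= maxit) break
  }
  r <- as.vector(y - X %*% b)
  s <- stats::median(abs(r)) / 0.6745
  if (s < 1e-10) {
    se <- c(0, 0)
  } else {
    u <- r / s
    psi <- pmax(-k, pmin(k, u))
    dpsi <- as.numeric(abs(u) <= k)
    denom <- mean(dpsi)^2
    vscale <- s^2 * sum(psi^2) / (n - 2) / denom
    XtXinv <- solve(crossprod(X))
    se <- sqrt(diag(XtXinv) * vscale)
  }
  z <- ifelse(se > 0, b / se, ifelse(b == 0, 0, Inf * sign(b)))
  p <- 2 * stats::pnorm(-abs(z))
  list(coef = as.vector(b), se = se, p = as.vector(p), scale = s,
       iterations = iter, converged = converged)
}

profileToPercent <- function(profile) {
  if (is(profile, "MethylationProfile")) 100 * methMean(profile)
  else as.matrix(profile)
}

#' Per-window robust regression of methylation on phenotype
#'
#' Huber IRLS fit of window percent methylation on the phenotype, one model
#' per window, complete-case. Windows with fewer than `minSubjects`
#' complete observations are reported as untestable (`NA` statistics), not
#' as an error.
#'
#' @param profile [MethylationProfile-class] or a windows x subjects matrix
#'   of percent methylation.
#' @param phenotype Numeric phenotype vector, one value per subject.
#' @param minSubjects Minimum complete cases per window (default 8).
#' @return `data.frame`: `window`, `n`, `slope` (percent methylation per
#'   unit phenotype), `se`, `p_value`.
#' @export
robustWindowRegression <- function(profile, phenotype, minSubjects = 8L) {
  meth <- profileToPercent(profile)
  if (ncol(meth) != length(phenotype))
    stop("phenotype length must match the number of subjects")
  if (stats::var(phenotype, na.rm = TRUE) == 0)
    stop("zero phenotype variance")
  nw <- nrow(meth)
  out <- data.frame(window = seq_len(nw), n = NA_integer_,
                    slope = NA_real_, se = NA_real_, p_value = NA_real_)
  for (w in seq_len(nw)) {
    y <- meth[w, ]
    ok <- is.finite(y) & is.finite(phenotype)
    out$n[w] <- sum(ok)
    if (sum(ok) < minSubjects) next
    fit <- huberRegression(y[ok], phenotype[ok])
    out$slope[w] <- fit$coef[2]
    out$se[w] <- fit$se[2]
    out$p_value[w] <- fit$p[2]
  }
  out
}

#' Absolute methylation difference between phenotype tertiles
#'
#' Subjects are split into phenotype tertiles (stable order on ties; group
#' sizes differing by at most one, extras assigned to the lower groups
#' first). The statistic per window is
#' `|mean %meth(top tertile) - mean %meth(bottom tertile)|`.
#'
#' @inheritParams robustWindowRegression
#' @return Numeric vector, one absolute percent difference per window.
#' @export
tertileDifference <- function(profile, phenotype) {
  meth <- profileToPercent(profile)
  n <- length(phenotype)
  if (n < 3L) stop("need at least 3 subjects")
  ord <- order(phenotype)              # stable: ties keep subject order
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- base + as.integer(seq_len(3L) <= rem)
  g1 <- ord[seq_len(sizes[1])]
  g3 <- ord[(n - sizes[3] + 1L):n]
  lo <- rowMeans(meth[, g1, drop = FALSE], na.rm = TRUE)
  hi <- rowMeans(meth[, g3, drop = FALSE], na.rm = TRUE)
  abs(hi - lo)
}

#' Flag windows passing the stringent joint filter
#'
#' A window is flagged iff its regression p-value is below `pThreshold`
#' AND its tertile difference strictly exceeds `diffThreshold` (percent).
#'
#' @param stats `data.frame` from [robustWindowRegression()].
#' @param tertileDiff Vector from [tertileDifference()].
#' @param pThreshold Window p-value threshold (default 0.01).
#' @param diffThreshold Absolute percent-difference threshold (default 20;
#'   strict inequality).
#' @return Logical vector; `NA` for untestable windows.
#' @export
flagWindows <- function(stats, tertileDiff, pThreshold = 0.01,
                        diffThreshold = 20) {
  if (pThreshold <= 0 || pThreshold > 1) stop("invalid pThreshold")
  if (diffThreshold < 0) stop("invalid diffThreshold")
  flag <- stats$p_value < pThreshold & tertileDiff > diffThreshold
  flag[is.na(stats$p_value)] <- NA
  flag
}

#' Contiguous window spans
#'
#' Maximal runs of consecutively tiled windows: a new span starts wherever
#' the gap between neighbouring windows exceeds `maxGap` nt (default 100,
#' so directly abutting 100-nt tiles stay in one span).
#'
#' @param windows `GRanges` tiling, sorted.
#' @param maxGap Gap (nt) above which a run breaks.
#' @param minWindows Drop spans with fewer windows than this (default 2).
#' @return List of integer vectors of window indices.
#' @export
makeSpans <- function(windows, maxGap = 100, minWindows = 2L) {
  n <- length(windows)
  if (n == 0L) return(list())
  gap <- start0(windows)[-1L] - end0(windows)[-n]
  sameChr <- as.character(GenomicRanges::seqnames(windows))[-1L] ==
    as.character(GenomicRanges::seqnames(windows))[-n]
  brk <- which(!sameChr | gap > maxGap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  spans <- Map(seq.int, starts, ends)
  spans[lengths(spans) >= minWindows]
}

#' Fisher-exact span enrichment
#'
#' One-sided Fisher exact test (hypergeometric upper tail) for enrichment
#' of flagged windows within each span, against the background of all
#' tested windows. Untestable (`NA`) windows are excluded from both the
#' span counts and the background.
#'
#' @param flagged Logical per window (`NA` = untestable).
#' @param spans List of integer window-index vectors (see [makeSpans()]).
#' @return `data.frame`: `span`, `n_windows`, `k_flagged`, `fisher_p`.
#' @export
spanEnrichment <- function(flagged, spans) {
  if (any(lengths(spans) == 0L)) stop("span with zero windows")
  tested <- !is.na(flagged)
  N <- sum(tested)
  K <- sum(flagged[tested])
  res <- data.frame(span = seq_along(spans),
                    n_windows = NA_integer_, k_flagged = NA_integer_,
                    fisher_p = NA_real_)
  for (i in seq_along(spans)) {
    idx <- spans[[i]]
    nw <- sum(tested[idx])
    k <- sum(flagged[idx][tested[idx]])
    res$n_windows[i] <- nw
    res$k_flagged[i] <- k
    if (nw > 0L)
      res$fisher_p[i] <- stats::phyper(k - 1, K, N - K, nw,
                                       lower.tail = FALSE)
  }
  res
}

#' Call phenotype-associated DMRs with failed-probe robustness
#'
#' Orchestrates the scan twice: (a) on the full probe set as supplied and
#' (b) after flagging failed probes (|log2 ratio| < `epsilon`) and
#' re-estimating window methylation without them. Each run performs
#' per-window Huber regression, the tertile-difference filter and
#' Fisher-exact span enrichment; a span is called a DMR only if it passes
#' the Fisher threshold in BOTH runs. Probe records are sorted internally,
#' so the output is invariant to the input record order.
#'
#' @param signals [ArraySignals-class] (probes x subjects).
#' @param cpgs `GRanges` of CpG positions.
#' @param windows `GRanges` tiling.
#' @param phenotype Numeric phenotype per subject (column order of
#'   `signals`).
#' @param gain,baseline,noiseSd Signal-model parameters.
#' @param dMax Coupling range (nt).
#' @param epsilon Failed-probe band (default 0.05).
#' @param pThreshold,diffThreshold Window filter thresholds (defaults 0.01
#'   and 20).
#' @param spanThreshold Span Fisher threshold (default 0.01).
#' @param maxGap Span-breaking gap (default 100 nt).
#' @param gridStep,prior Passed to [estimateWindowMethylation()].
#' @param minSubjects Passed to [robustWindowRegression()].
#' @return `data.frame` of calls sorted by `fisher_p` (the less favourable
#'   of the two runs): span coordinates, window counts, flagged counts and
#'   Fisher p per run, and `robust_to_failed_probes` (TRUE by
#'   construction for every emitted call).
#' @export
callDMRs <- function(signals, cpgs, windows, phenotype,
                     gain, baseline, noiseSd, dMax = 40,
                     epsilon = 0.05, pThreshold = 0.01, diffThreshold = 20,
                     spanThreshold = 0.01, maxGap = 100,
                     gridStep = 0.01, prior = "flat", minSubjects = 8L) {
  ord <- order(as.character(GenomicRanges::seqnames(probeRanges(signals))),
               GenomicRanges::start(probeRanges(signals)),
               GenomicRanges::end(probeRanges(signals)),
               probeIds(signals))
  signals <- ArraySignals(probeRanges(signals)[ord],
                          signalMatrix(signals)[ord, , drop = FALSE],
                          truth = groundTruth(signals))
  coupling <- buildCoupling(signals, cpgs, dMax = dMax)
  spans <- makeSpans(windows, maxGap = maxGap)

  runScan <- function(sig) {
    prof <- estimateWindowMethylation(sig, coupling, windows, gain = gain,
                                      baseline = baseline, noiseSd = noiseSd,
                                      gridStep = gridStep, prior = prior)
    st <- robustWindowRegression(prof, phenotype, minSubjects = minSubjects)
    td <- tertileDifference(prof, phenotype)
    flag <- flagWindows(st, td, pThreshold, diffThreshold)
    spanEnrichment(flag, spans)
  }

  full <- runScan(signals)
  clean <- runScan(detectFailedProbes(signals, epsilon = epsilon))

  pass <- !is.na(full$fisher_p) & !is.na(clean$fisher_p) &
    full$fisher_p < spanThreshold & clean$fisher_p < spanThreshold
  idx <- which(pass)
  calls <- data.frame(
    span = idx,
    chrom = vapply(idx, function(i) as.character(
      GenomicRanges::seqnames(windows))[spans[[i]][1]], character(1)),
    start = vapply(idx, function(i) start0(windows)[spans[[i]][1]], numeric(1)),
    end = vapply(idx, function(i)
      end0(windows)[spans[[i]][length(spans[[i]])]], numeric(1)),
    n_windows = full$n_windows[idx],
    k_flagged_full = full$k_flagged[idx],
    fisher_p_full = full$fisher_p[idx],
    k_flagged_clean = clean$k_flagged[idx],
    fisher_p_clean = clean$fisher_p[idx],
    robust_to_failed_probes = rep(TRUE, length(idx))
  )
  calls$fisher_p <- pmax(calls$fisher_p_full, calls$fisher_p_clean)
  calls[order(calls$fisher_p, calls$span), , drop = FALSE]
}
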