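# Cellular-heterogeneity handling: reference-free surrogate variables by
# residual SVD with a permutation (parallel-analysis) retention rule,
# reference-based cell proportions by constrained least squares, VIF
# diagnostics, and the collinearity guard that refuses an adjustment which
# would destabilize the model rather than fitting it silently.

#' Reference-free surrogate variables
#'
#' Residualizes each feature (window methylation) on the primary phenotype
#' by OLS, takes the SVD of the residual matrix, and retains components
#' whose singular value exceeds the 95th percentile of the corresponding
#' singular value under `nPerm` independent column-wise permutations of the
#' residuals (parallel analysis). Retention stops at the first component
#' that fails. The retained left singular vectors are orthonormal surrogate
#' covariates capturing latent structure such as cellular heterogeneity.
#'
#' @param x Numeric matrix, subjects x features.
#' @param primary Phenotype vector (non-constant).
#' @param nPerm Number of permutations (default 100).
#' @param quantile Retention quantile (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return List: `sv` (subjects x k, orthonormal), `k`, `eigenShare`,
#'   `singularValues`, `thresholds`.
#' @export
referenceFreeSVs <- function(x, primary, nPerm = 100L, quantile = 0.95,
                             seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("need at least 10 subjects")
  if (stats::var(primary) == 0) stop("constant primary variable")
  if (ncol(x) < nrow(x))
    warning("fewer features than subjects; surrogate variables may be weak")
  X <- cbind(1, primary)
  beta <- solve(crossprod(X), crossprod(X, x))
  R <- x - X %*% beta
  sv <- svd(R)
  d <- sv$d
  nk <- length(d)
  withLocalSeed(seed, {
    permD <- matrix(NA_real_, nPerm, nk)
    for (b in seq_len(nPerm)) {
      Rp <- apply(R, 2L, sample)
      permD[b, ] <- svd(Rp, nu = 0, nv = 0)$d
    }
  })
  thresholds <- apply(permD, 2L, stats::quantile, probs = quantile)
  keep <- d > thresholds
  k <- if (all(keep)) nk else which.min(keep) - 1L
  list(sv = sv$u[, seq_len(k), drop = FALSE], k = as.integer(k),
       eigenShare = d^2 / sum(d^2), singularValues = d,
       thresholds = thresholds)
}

#' Reference-based cell-type proportions
#'
#' Least squares of a sample's methylation over reference CpGs on a panel
#' of cell-type-specific methylation profiles, constrained to proportions
#' >= 0 with sum <= 1 (the remainder absorbs unprofiled cell types). The
#' small quadratic program is solved exactly by enumerating active sets of
#' the constraints and checking feasibility, which is cheap for panel sizes
#' used in practice (<= 12 cell types).
#'
#' @param sample Numeric vector of methylation over the reference CpGs.
#' @param panel Matrix, cell types x reference CpGs, rows linearly
#'   independent, CpG order matching `sample`.
#' @return List: `proportions` (named), `remainder` (1 - sum),
#'   `residualNorm`.
#' @export
referenceBasedProportions <- function(sample, panel) {
  panel <- as.matrix(panel)
  K <- nrow(panel)
  if (K > 12L) stop("panel too large for exact enumeration (max 12 types)")
  A <- t(panel)                       # CpGs x types
  if (qr(A)$rank < K) stop("rank-deficient panel")
  if (length(sample) != ncol(panel))
    stop("sample and panel must cover the same CpGs")

  best <- NULL; bestRss <- Inf
  for (zmask in 0:(2^K - 1)) {
    zero <- as.logical(bitwAnd(zmask, 2^(seq_len(K) - 1L)))
    free <- which(!zero)
    for (sumActive in c(FALSE, TRUE)) {
      p <- numeric(K)
      if (length(free) == 0L) {
        if (sumActive) next
      } else {
        Af <- A[, free, drop = FALSE]
        if (sumActive) {
          # KKT system for min ||s - Af p|| s.t. 1'p = 1
          nf <- length(free)
          M <- rbind(cbind(2 * crossprod(Af), rep(1, nf)),
                     c(rep(1, nf), 0))
          rhs <- c(2 * crossprod(Af, sample), 1)
          sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
          if (is.null(sol)) next
          p[free] <- sol[seq_len(nf)]
        } else {
          p[free] <- as.vector(solve(crossprod(Af), crossprod(Af, sample)))
        }
      }
      if (any(p < -1e-9) || sum(p) > 1 + 1e-9) next
      rss <- sum((sample - as.vector(A %*% p))^2)
      if (rss < bestRss - 1e-12) { bestRss <- rss; best <- p }
    }
  }
  p <- pmax(best, 0)
  names(p) <- rownames(panel)
  list(proportions = p, remainder = 1 - sum(p),
       residualNorm = sqrt(bestRss))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing covariate j on
#' the remaining covariates (with intercept). Exact collinearity is
#' reported as `Inf`. Factor columns are expanded to dummy variables first.
#'
#' @param covariates Numeric matrix or data.frame of covariates (>= 2
#'   columns after expansion; more rows than columns).
#' @return Named numeric vector of VIFs.
#' @export
vifReport <- function(covariates) {
  X <- asDesignMatrix(covariates)
  if (ncol(X) < 2L) stop("need at least 2 covariates")
  if (nrow(X) <= ncol(X)) stop("fewer subjects than covariates")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' Collinearity guard for candidate adjusters
#'
#' Appends candidate adjusters (e.g. cell proportions) to the covariate set
#' only if every VIF in the augmented design - including the outcome, so
#' that adjuster-outcome collinearity is caught - stays at or below the
#' threshold. Otherwise the candidates are excluded, `blocked = TRUE`, and
#' the offending VIFs are reported; the model is then fitted without them,
#' never silently with them.
#'
#' @param covariates data.frame/matrix of always-included covariates.
#' @param candidates data.frame/matrix of candidate adjusters.
#' @param outcome Numeric outcome vector included in the VIF design.
#' @param threshold VIF threshold (> 1; default 10; `Inf` always admits).
#' @return List: `covariates` (the admissible set), `blocked`, `report`
#'   (list with `vif`, `threshold`, `offending`).
#' @export
collinearityGuard <- function(covariates, candidates, outcome,
                              threshold = 10) {
  if (threshold <= 1) stop("threshold must exceed 1")
  Xc <- asDesignMatrix(covariates)
  Xa <- asDesignMatrix(candidates)
  design <- cbind(Xc, Xa, outcome = outcome)
  vif <- vifReport(design)
  offending <- vif[vif > threshold]
  blocked <- length(offending) > 0L
  admitted <- if (blocked) Xc else cbind(Xc, Xa)
  list(covariates = admitted, blocked = blocked,
       report = list(vif = vif, threshold = threshold,
                     offending = offending))
}
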