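# Internal numeric helpers shared across modules.

#' Moment skewness of a sample
#'
#' Biased moment estimator \eqn{g_1 = m_3 / m_2^{3/2}}, computed on finite
#' values only. Used to decide whether a skewed adiposity outcome is
#' log-transformed before Z-scoring.
#'
#' @param x Numeric vector.
#' @return Scalar skewness; `NA` with fewer than 3 finite values.
#' @export
momentSkewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

## latent Gaussian correlation giving a target Spearman rho under a
## Gaussian copula: rho_S = (6/pi) asin(r/2)  =>  r = 2 sin(pi rho_S / 6)
spearmanToLatent <- function(rho) 2 * sin(pi * rho / 6)

## Beta(a, b) parameters from a mean and sd on the (0, 1) scale; the sd is
## shrunk if it exceeds what the mean admits.
betaFromMoments <- function(mu, sd) {
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  vmax <- mu * (1 - mu)
  v <- pmin(sd^2, 0.9 * vmax)
  phi <- vmax / v - 1
  list(a = mu * phi, b = (1 - mu) * phi)
}

## run code with a locally-seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## 0-based start / end of a GRanges (BED convention)
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

## midpoint of a probe on the 0-based scale
mid0 <- function(gr) (start0(gr) + end0(gr)) / 2

## single 0-based position of CpG ranges (width-1 intervals)
cpgPos0 <- function(gr) start0(gr)

asDesignMatrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    mm <- stats::model.matrix(~., data = x)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    return(mm)
  }
  as.matrix(x)
}
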