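# Validation-stage statistics: outcome standardization (log_e for skewed
# adiposity measures, then Z-scores so regression coefficients read as SD
# change in outcome per % methylation), conditional growth velocities,
# covariate-adjusted linear association models, and qPCR delta-Ct
# normalization. All models are complete-case, so n varies per model.

#' Standardize an outcome for association models
#'
#' Applies a natural-log transform when the moment skewness exceeds
#' `skewThreshold` (default 1; requires strictly positive values), then
#' Z-scores the (transformed) values on complete cases.
#'
#' @param values Numeric outcome vector (>= 3 non-missing).
#' @param skewThreshold Skewness above which log_e is applied.
#' @return Object of class `StandardizedOutcome`: list with `z`,
#'   `transform` ("identity" or "log_e"), `mean`, `sd`,
#'   `skewnessBefore`, `skewnessAfter`.
#' @export
standardizeOutcome <- function(values, skewThreshold = 1.0) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  sk <- momentSkewness(values)
  transform <- "identity"
  x <- values
  if (sk > skewThreshold) {
    if (any(values[ok] <= 0))
      stop("log_e transform requires strictly positive values")
    x <- log(values)
    transform <- "log_e"
  }
  mu <- mean(x[ok]); sdv <- stats::sd(x[ok])
  z <- (x - mu) / sdv
  structure(list(z = z, transform = transform, mean = mu, sd = sdv,
                 skewnessBefore = sk, skewnessAfter = momentSkewness(x)),
            class = "StandardizedOutcome")
}

#' @export
print.StandardizedOutcome <- function(x, ...) {
  cat(sprintf("StandardizedOutcome: transform = %s, n = %d, skewness %.3f -> %.3f\n",
              x$transform, sum(is.finite(x$z)), x$skewnessBefore,
              x$skewnessAfter))
  invisible(x)
}

#' Conditional growth velocity
#'
#' OLS of later body size on earlier size plus adjusters (e.g. gestational
#' age); the conditional velocity is the Z-scored residual - growth
#' relative to expectation given earlier size. With `sexSpecific = TRUE`
#' and a `sex` factor supplied, models are fitted separately per sex and
#' residuals Z-scored within sex.
#'
#' @param earlier,later Numeric size vectors over the same subjects.
#' @param adjusters Optional matrix/data.frame of adjusters.
#' @param sex Optional factor for sex-specific fitting.
#' @param sexSpecific Fit separately per sex (default FALSE).
#' @return Numeric Z-scored residual vector (`NA` for incomplete cases).
#' @export
conditionalVelocity <- function(earlier, later, adjusters = NULL,
                                sex = NULL, sexSpecific = FALSE) {
  X <- cbind(earlier = earlier, asDesignMatrix(adjusters))
  ok <- is.finite(later) & apply(is.finite(X), 1L, all)
  if (sexSpecific && !is.null(sex)) ok <- ok & !is.na(sex)
  if (sum(ok) < 10L) stop("need at least 10 complete cases")
  res <- rep(NA_real_, length(later))
  fitGroup <- function(sel) {
    Z <- cbind(1, X[sel, , drop = FALSE])
    if (qr(Z)$rank < ncol(Z)) stop("singular design")
    r <- stats::lm.fit(Z, later[sel])$residuals
    as.numeric(scale(r))
  }
  if (sexSpecific && !is.null(sex)) {
    for (lv in levels(factor(sex))) {
      sel <- ok & sex == lv
      if (sum(sel) >= 10L) res[sel] <- fitGroup(sel)
    }
  } else {
    res[ok] <- fitGroup(ok)
  }
  res
}

#' Covariate-adjusted methylation-outcome association
#'
#' OLS with intercept of the (standardized) outcome on percent methylation
#' plus covariates, complete-case. The coefficient is reported per 1%
#' methylation: with a Z-scored outcome it reads as the SD change in
#' outcome per percent methylation. The 95% CI uses the t distribution.
#'
#' @param outcome `StandardizedOutcome` or numeric vector.
#' @param methylation Percent methylation vector (the representative CpG).
#' @param covariates Optional matrix/data.frame of covariates.
#' @param level Confidence level (default 0.95).
#' @return Object of class `AssociationResult`: list with `beta`, `se`,
#'   `ci`, `p_value`, `n`, `covariates`.
#' @export
fitAssociation <- function(outcome, methylation, covariates = NULL,
                           level = 0.95) {
  y <- if (inherits(outcome, "StandardizedOutcome")) outcome$z else outcome
  X <- asDesignMatrix(covariates)
  df <- data.frame(y = y, methylation = methylation)
  if (!is.null(X)) df <- cbind(df, as.data.frame(X))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p <- ncol(df) - 1L
  if (nrow(df) < p + 3L) stop("too few complete cases")
  if (stats::var(df$methylation) == 0) stop("constant methylation vector")
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  beta <- sm["methylation", "Estimate"]
  se <- sm["methylation", "Std. Error"]
  dfres <- fit$df.residual
  tq <- stats::qt(1 - (1 - level) / 2, dfres)
  structure(list(beta = unname(beta), se = unname(se),
                 ci = unname(c(beta - tq * se, beta + tq * se)),
                 p_value = unname(sm["methylation", "Pr(>|t|)"]),
                 n = nrow(df),
                 covariates = if (is.null(X)) character(0) else colnames(X)),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("AssociationResult: beta = %.4g (95%% CI %.4g, %.4g), p = %.3g, n = %d\n",
              x$beta, x$ci[1], x$ci[2], x$p_value, x$n))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' qPCR delta-Ct normalization
#'
#' `dCt = Ct_target - mean(Ct_ref1, Ct_ref2)`, with the reference summary
#' taken literally as the geometric mean of the two reference Ct values
#' (default). `method = "arithmetic"` instead averages the Cts
#' arithmetically, which equals the geometric mean of the linearized
#' abundances. Lower dCt means higher expression.
#'
#' @param ctTarget Target-gene Ct value(s).
#' @param ctRef1,ctRef2 Reference-gene Ct values.
#' @param method `"geometric"` (of Cts; default) or `"arithmetic"`.
#' @return Numeric dCt value(s).
#' @export
deltaCt <- function(ctTarget, ctRef1, ctRef2,
                    method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (anyNA(c(ctRef1, ctRef2))) stop("missing reference Ct")
  if (any(c(ctTarget, ctRef1, ctRef2) <= 0, na.rm = TRUE))
    stop("Ct values must be positive")
  ref <- switch(method,
    geometric = sqrt(ctRef1 * ctRef2),
    arithmetic = (ctRef1 + ctRef2) / 2)
  ctTarget - ref
}

#' Methylation-expression association
#'
#' OLS of dCt on percent methylation plus covariates (include batch when
#' available). Sign convention: lower dCt = higher expression, so a
#' negative beta on the dCt scale means expression rises with methylation.
#'
#' @param dct Normalized dCt vector (see [deltaCt()]).
#' @param methylation Percent methylation vector.
#' @param covariates Optional matrix/data.frame (e.g. sex, ethnicity,
#'   batch).
#' @param level Confidence level.
#' @return An `AssociationResult` (beta on the dCt scale).
#' @export
expressionAssociation <- function(dct, methylation, covariates = NULL,
                                  level = 0.95) {
  fitAssociation(dct, methylation, covariates = covariates, level = level)
}

#' Covariate preset column sets
#'
#' Named covariate presets used by the cohort analyses; presets only select
#' cohort columns, they impose no additional processing. `"sws"` follows
#' the fuller adjustment (sex, age, maternal age, mode of delivery);
#' `"sws_minimal"` is sex and age only; `"gusto"` adds ethnicity and cell
#' proportions; `"raine"` is age and sex.
#'
#' @param cohort Cohort data.frame.
#' @param preset One of `"sws"`, `"sws_minimal"`, `"gusto"`, `"raine"`.
#' @return data.frame of the selected covariate columns.
#' @export
presetCovariates <- function(cohort,
                             preset = c("sws", "sws_minimal", "gusto",
                                        "raine")) {
  preset <- match.arg(preset)
  cols <- switch(preset,
    sws = c("sex", "age", "maternal_age", "mode_of_delivery"),
    sws_minimal = c("sex", "age"),
    gusto = c("sex", "ethnicity", "maternal_age", "mode_of_delivery",
              grep("^cell_", names(cohort), value = TRUE)),
    raine = c("age", "sex"))
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) stop("cohort lacks columns: ",
                            paste(missing, collapse = ", "))
  cohort[, cols, drop = FALSE]
}
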