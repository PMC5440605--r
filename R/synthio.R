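# Synthetic cohort / methylome / array / expression generators.
#
# These emulate the study conditions of a mother-offspring methylation
# cohort: block-correlated CpG methylation, planted linear
# methylation-phenotype effects, skewed adiposity outcomes, Dirichlet cell
# mixtures (optionally collinear with the outcome), failed array probes and
# methylation-linked qPCR expression. Every generator is deterministic for
# a fixed integer seed.

#' Default outcome specification for simulated cohorts
#'
#' Adiposity-style outcomes: percent fat mass roughly spanning the 5th-95th
#' percentile range of children at age 6 (normal, mean 25, sd 7), total fat
#' in grams and triceps skinfold as right-skewed lognormals, and BMI as a
#' mildly skewed lognormal.
#'
#' @return Named list of `list(family=, ...)` outcome specifications.
#' @export
defaultOutcomeSpec <- function() {
  list(
    pct_fat = list(family = "normal", mean = 25, sd = 7),
    total_fat_g = list(family = "lognormal", meanlog = 8.9, sdlog = 0.35),
    triceps_skinfold_mm = list(family = "lognormal", meanlog = log(10), sdlog = 0.3),
    bmi = list(family = "lognormal", meanlog = log(16), sdlog = 0.12)
  )
}

simCellNames <- c("granulocytes", "monocytes", "lymphocytes", "nucleated_rbc")

#' Simulate a cohort table
#'
#' Generates subject identifiers, demographic covariates (sex, age,
#' ethnicity, mode of delivery, maternal age, batch), cell-type proportions
#' and named outcomes. Cell proportions are Dirichlet; with
#' `collinearCells = TRUE` the Dirichlet location is a linear function of
#' the standardized primary outcome at high concentration, so that each
#' cell fraction regresses on the outcome with R-squared >= 0.9 - the
#' construction that makes cell-type adjustment collinear with the outcome.
#'
#' @param n Number of subjects (>= 2).
#' @param outcomeSpec Named list of outcome specifications, each
#'   `list(family = "normal", mean=, sd=)` or
#'   `list(family = "lognormal", meanlog=, sdlog=)`.
#' @param collinearCells Couple cell proportions to the primary outcome.
#' @param primaryOutcome Name of the outcome driving the cell coupling
#'   (first outcome by default).
#' @param seed Integer seed.
#' @return `data.frame` with one row per subject: `subject_id`, `sex`,
#'   `age`, `ethnicity`, `mode_of_delivery`, `maternal_age`, `batch`,
#'   `cell_*` fraction columns summing to 1, and one column per outcome.
#' @export
simulateCohort <- function(n, outcomeSpec = defaultOutcomeSpec(),
                           collinearCells = FALSE,
                           primaryOutcome = names(outcomeSpec)[1],
                           seed = 1L) {
  if (!is.numeric(n) || n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  fams <- vapply(outcomeSpec, function(s) s$family, character(1))
  bad <- setdiff(fams, c("normal", "lognormal"))
  if (length(bad)) stop("unknown distribution family: ", bad[1])

  withLocalSeed(seed, {
    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      age = round(stats::rnorm(n, 6, 0.2), 2),
      ethnicity = factor(sample(c("chinese", "malay", "indian"), n,
                                replace = TRUE, prob = c(0.56, 0.26, 0.18))),
      mode_of_delivery = factor(sample(c("vaginal", "caesarean"), n,
                                       replace = TRUE, prob = c(0.7, 0.3))),
      maternal_age = round(stats::rnorm(n, 30, 5), 1),
      batch = factor(sample(paste0("B", 1:3), n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    for (nm in names(outcomeSpec)) {
      s <- outcomeSpec[[nm]]
      out[[nm]] <- switch(s$family,
        normal = stats::rnorm(n, s$mean, s$sd),
        lognormal = stats::rlnorm(n, s$meanlog, s$sdlog))
    }

    base <- c(0.4, 0.3, 0.2, 0.1)
    if (collinearCells) {
      y <- out[[primaryOutcome]]
      z <- as.numeric(scale(y))
      coupl <- c(0.06, -0.02, -0.02, -0.02)
      conc <- 20000
      alpha <- pmax(outer(z, coupl) + rep(base, each = n), 1e-3) * conc
    } else {
      alpha <- matrix(base * 100, nrow = n, ncol = 4, byrow = TRUE)
    }
    g <- matrix(stats::rgamma(n * 4L, shape = alpha), nrow = n)
    props <- g / rowSums(g)
    colnames(props) <- paste0("cell_", simCellNames)
    cbind(out, as.data.frame(props))
  })
}

#' Simulate block-correlated CpG methylation
#'
#' Percent methylation per subject and CpG via a Gaussian copula: a latent
#' multivariate normal with exchangeable within-block correlation (chosen
#' so that the within-block Spearman rho hits its target), mapped through
#' per-CpG Beta marginals with the given baseline mean and noise sd. Planted
#' phenotype effects are added as `slope * (outcome - mean(outcome))` on the
#' stated CpGs; optional batch shifts model technical structure. Values are
#' clipped to [0, 100]; the clip fraction is reported in the ground truth
#' and a warning is raised if it exceeds 5%.
#'
#' @param cohort Cohort `data.frame` from [simulateCohort()].
#' @param nCpg Number of CpGs; defaults to the positions' length.
#' @param blockSpec List of `list(cpgs = <indices>, rho = <target Spearman>)`
#'   blocks that partition `1:nCpg` into contiguous runs.
#' @param effects Optional list of `list(cpgs=, slope=)` planted effects
#'   (slope in percent methylation per unit outcome).
#' @param baselines Per-CpG baseline percent methylation; default drawn
#'   uniformly in 35-65.
#' @param noiseSd Marginal sd of the Beta noise, in percent (default 5).
#' @param outcome Name of the cohort column driving the planted effects.
#' @param batchEffects Optional `list(cpgs=, shifts=)` with one shift (in
#'   percent) per level of `cohort$batch`.
#' @param positions Optional `GRanges` of CpG positions (width 1).
#' @param seed Integer seed.
#' @return A [CpGMethylationMatrix-class]; `groundTruth()` carries the
#'   baselines, block spec, effects and clip fraction.
#' @export
simulateMethylation <- function(cohort, nCpg = NULL, blockSpec = NULL,
                                effects = NULL, baselines = NULL,
                                noiseSd = 5, outcome = "pct_fat",
                                batchEffects = NULL, positions = NULL,
                                seed = 1L) {
  if (is.null(nCpg)) {
    if (is.null(positions)) stop("give nCpg or positions")
    nCpg <- length(positions)
  }
  nCpg <- as.integer(nCpg)
  n <- nrow(cohort)
  if (is.null(blockSpec)) blockSpec <- list(list(cpgs = seq_len(nCpg), rho = 0.85))
  covered <- sort(unlist(lapply(blockSpec, `[[`, "cpgs")))
  if (!identical(covered, seq_len(nCpg)))
    stop("blockSpec must partition 1..nCpg without overlap")
  if (is.null(positions)) {
    positions <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(start = seq_len(nCpg) * 10L, width = 1L))
  }

  withLocalSeed(seed, {
    if (is.null(baselines)) baselines <- stats::runif(nCpg, 35, 65)
    z <- matrix(NA_real_, n, nCpg)
    for (b in blockSpec) {
      idx <- b$cpgs
      if (length(idx) == 1L) {
        z[, idx] <- stats::rnorm(n)
      } else {
        r <- spearmanToLatent(b$rho)
        shared <- stats::rnorm(n)
        eps <- matrix(stats::rnorm(n * length(idx)), n)
        z[, idx] <- sqrt(r) * shared + sqrt(1 - r) * eps
      }
    }
    vals <- matrix(NA_real_, n, nCpg)
    for (j in seq_len(nCpg)) {
      p <- betaFromMoments(baselines[j] / 100, noiseSd / 100)
      vals[, j] <- 100 * stats::qbeta(stats::pnorm(z[, j]), p$a, p$b)
    }
    if (!is.null(effects)) {
      y <- cohort[[outcome]]
      yc <- y - mean(y)
      for (e in effects) vals[, e$cpgs] <- vals[, e$cpgs] + e$slope * yc
    }
    if (!is.null(batchEffects)) {
      shift <- batchEffects$shifts[as.integer(cohort$batch)]
      vals[, batchEffects$cpgs] <- vals[, batchEffects$cpgs] + shift
    }
    clipped <- mean(vals < 0 | vals > 100)
    if (clipped > 0.05)
      warning(sprintf("clipping affected %.1f%% of entries", 100 * clipped))
    vals <- pmin(pmax(vals, 0), 100)
    rownames(vals) <- cohort$subject_id
    CpGMethylationMatrix(vals, positions, truth = list(
      baselines = baselines, blockSpec = blockSpec, effects = effects,
      batchEffects = batchEffects, clipFraction = clipped,
      outcome = outcome, seed = seed))
  })
}

#' Promoter-style array design
#'
#' A tiled design mimicking a custom promoter array: segments of contiguous
#' 100-nt windows separated by untiled gaps, a fixed number of CpGs placed
#' in the central part of each window, and probes whose coupling footprint
#' (range `dMax`) stays within their window, so the window-level signal
#' model is exact for this platform.
#'
#' @param nSegments Number of tiled segments (promoter regions).
#' @param windowsPerSegment Contiguous 100-nt windows per segment.
#' @param windowSize Window width in nt.
#' @param gap Untiled gap between segments in nt (must exceed the span-
#'   breaking gap used by the DMR scan, default 400).
#' @param cpgsPerWindow CpGs per window, evenly spaced around the centre.
#' @param probesPerWindow Probes per window (1 or 2).
#' @param probeLength Probe length in nt.
#' @param dMax Coupling range of the platform in nt.
#' @param chrom Chromosome name.
#' @param origin 0-based start coordinate of the first window.
#' @return List with `windows`, `cpgs`, `probes` (`GRanges`) and `dMax`.
#' @export
arrayDesign <- function(nSegments = 41, windowsPerSegment = 5,
                        windowSize = 100, gap = 400, cpgsPerWindow = 5,
                        probesPerWindow = 3, probeLength = 50, dMax = 40,
                        chrom = "chr9", origin = 10000) {
  segStart <- origin + (seq_len(nSegments) - 1) * (windowsPerSegment * windowSize + gap)
  winStart0 <- as.vector(outer((seq_len(windowsPerSegment) - 1) * windowSize,
                               segStart, `+`))
  winStart0 <- sort(winStart0)
  windows <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = winStart0 + 1L, width = windowSize))

  cpgOff <- round(windowSize * (seq_len(cpgsPerWindow) + 0.5) /
                    (cpgsPerWindow + 2))
  cpg0 <- as.vector(outer(cpgOff, winStart0, `+`))
  cpg0 <- sort(cpg0)
  cpgs <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = cpg0 + 1L, width = 1L))

  probeOff <- if (probesPerWindow == 1L) windowSize / 2 else
    windowSize * seq_len(probesPerWindow) / (probesPerWindow + 1)
  probeMid0 <- as.vector(outer(probeOff, winStart0, `+`))
  probeMid0 <- sort(probeMid0)
  probes <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = round(probeMid0 - probeLength / 2) + 1L,
                     width = probeLength))
  names(probes) <- sprintf("P%05d", seq_along(probes))
  list(windows = windows, cpgs = cpgs, probes = probes, dMax = dMax)
}

#' Simulate MBD-array probe signal
#'
#' For each sample, the log2 signal of probe p is
#' `baseline + gain * sum_c C_pc * m_c + N(0, noiseSd^2)` where `m_c` is
#' the methylation fraction of CpG c and `C_pc` the triangular coupling
#' weight from [buildCoupling()]. A fraction `failedRate` of probes (drawn
#' per probe, shared across samples) is replaced by near-zero values
#' uniform on (-0.02, 0.02), emulating failed probes.
#'
#' @param meth [CpGMethylationMatrix-class] (values in percent).
#' @param probes `GRanges` of probe locations, named by probe id.
#' @param gain,baseline Linear signal model parameters (`gain > 0`).
#' @param noiseSd Gaussian noise sd on the log2 scale.
#' @param failedRate Expected fraction of failed probes.
#' @param dMax Coupling range in nt used to generate the signal.
#' @param seed Integer seed.
#' @return An [ArraySignals-class] with the planted failed set, the clean
#'   signal and the model parameters in `groundTruth()`.
#' @export
simulateArray <- function(meth, probes, gain = 1, baseline = 0.5,
                          noiseSd = 0.15, failedRate = 0.05, dMax = 40,
                          seed = 1L) {
  if (length(probes) == 0L) stop("empty probe layout")
  if (gain <= 0) stop("gain must be positive")
  coupling <- buildCoupling(probes, cpgPositions(meth), dMax = dMax)
  m <- t(methValues(meth)) / 100                    # CpGs x subjects
  mu <- baseline + gain * as.matrix(couplingWeights(coupling) %*% m)
  withLocalSeed(seed, {
    sig <- mu + matrix(stats::rnorm(length(mu), 0, noiseSd), nrow(mu))
    failed <- stats::runif(length(probes)) < failedRate
    if (any(failed)) {
      sig[failed, ] <- matrix(
        stats::runif(sum(failed) * ncol(sig), -0.02, 0.02), sum(failed))
    }
    colnames(sig) <- rownames(methValues(meth))
    ArraySignals(probes, sig, failed = rep(FALSE, length(probes)),
                 truth = list(plantedFailed = which(failed), clean = mu,
                              gain = gain, baseline = baseline,
                              noiseSd = noiseSd, dMax = dMax, seed = seed))
  })
}

#' Simulate qPCR expression linked to methylation
#'
#' Generates per-subject Ct values for target transcripts and two reference
#' amplicons. The planted model acts on the delta-Ct scale:
#' `dCt = 5 + sign * magnitude * (mean methylation of the driving CpGs,
#' centred) + noise`, and target Cts are reconstructed as
#' `dCt + geometric mean of the two reference Cts`, so that re-normalizing
#' recovers the planted dCt exactly.
#'
#' @param meth [CpGMethylationMatrix-class].
#' @param links Named list per transcript:
#'   `list(cpgs=, sign = +1/-1, magnitude=)`.
#' @param refCt Length-2 numeric: mean Ct of the two reference amplicons.
#' @param noiseSd Residual sd on the dCt scale.
#' @param seed Integer seed.
#' @return `data.frame` with `subject_id`, `ct_ref1`, `ct_ref2`, and per
#'   transcript `ct_<name>` and `dct_<name>` columns.
#' @export
simulateExpression <- function(meth, links, refCt = c(20, 21),
                               noiseSd = 0.5, seed = 1L) {
  vals <- methValues(meth)
  n <- nrow(vals)
  for (l in links) {
    if (!(all(l$sign %in% c(-1, 1)))) stop("link signs must be +1 or -1")
    if (any(l$cpgs < 1 | l$cpgs > ncol(vals)))
      stop("link references CpG outside matrix")
  }
  withLocalSeed(seed, {
    ref1 <- stats::rnorm(n, refCt[1], 0.3)
    ref2 <- stats::rnorm(n, refCt[2], 0.3)
    gm <- sqrt(ref1 * ref2)
    out <- data.frame(subject_id = rownames(vals), ct_ref1 = ref1,
                      ct_ref2 = ref2, stringsAsFactors = FALSE)
    for (nm in names(links)) {
      l <- links[[nm]]
      drv <- rowMeans(vals[, l$cpgs, drop = FALSE])
      dct <- 5 + l$sign * l$magnitude * (drv - mean(drv)) +
        stats::rnorm(n, 0, noiseSd)
      out[[paste0("ct_", nm)]] <- dct + gm
      out[[paste0("dct_", nm)]] <- dct
    }
    out
  })
}
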