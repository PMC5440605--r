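# End-to-end orchestration: simulate -> estimate -> scan -> reduce ->
# adjust -> associate, with every intermediate persisted, a manifest of
# outputs and the resolved configuration echoed verbatim. All randomness
# flows from the single config seed; per-stage sub-seeds are derived as
# fixed small offsets.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. Unknown keys passed to
#' [runPipeline()] are rejected before any stage runs.
#'
#' @return Named list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    # synthetic study conditions
    n_discovery = 24L,        # discovery arrays (cohort of ~21 children)
    n_validation = 250L,      # pyrosequencing validation cohort
    n_raine = 500L,           # adolescent cohort with collinear cell counts
    outcome = "pct_fat",
    n_segments = 41L,         # tiled promoter segments (5 windows each)
    windows_per_segment = 5L,
    dmr_segment = 21L,        # segment carrying the planted DMR
    dmr_slope = -3,           # % methylation per unit outcome (discovery)
    validation_slope = -0.07, # % methylation per unit outcome (validation)
    expression_magnitude = 0.08,
    # array signal model
    gain = 1, baseline = 0.5, noise_sd = 0.15, failed_rate = 0.05,
    d_max = 40, grid_step = 0.01, prior = "flat", epsilon = 0.05,
    # DMR scan thresholds
    p_threshold = 0.01, diff_threshold = 20, span_threshold = 0.01,
    max_gap = 100,
    # reduction / adjustment / association
    rho_min = 0.68, vif_threshold = 10, skew_threshold = 1,
    n_perm_sv = 50L
  )
}

resolveConfig <- function(config) {
  defaults <- defaultPipelineConfig()
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(config)] <- config
  defaults
}

## canonical block spec of the 9-CpG validation amplicon
validationBlockSpec <- function(rho = 0.9) {
  list(list(cpgs = 1:2, rho = rho), list(cpgs = 3L, rho = NA),
       list(cpgs = 4:8, rho = rho), list(cpgs = 9L, rho = NA))
}

#' Run the full pipeline
#'
#' Executes simulate, estimate, scan, reduce, adjust and associate in
#' order, persisting each stage's outputs under `outDir` and writing a
#' manifest (resolved config, seed, md5 per output). Reproducible: the same
#' config and seed give byte-identical outputs. A stage failure aborts with
#' the stage name; earlier outputs are preserved.
#'
#' @param config Partial configuration list (see
#'   [defaultPipelineConfig()]); unknown keys are rejected.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the resolved config, the DMR calls, the
#'   partition/representatives, the collinearity report and the
#'   association tables.
#' @export
runPipeline <- function(config = NULL, outDir) {
  cfg <- resolveConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c("mbdDMR pipeline", paste0("seed: ", cfg$seed),
                "resolved config:", yaml::as.yaml(cfg))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  fp <- function(...) file.path(outDir, ...)

  ## -- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    design <- arrayDesign(nSegments = cfg$n_segments,
                          windowsPerSegment = cfg$windows_per_segment,
                          dMax = cfg$d_max)
    disc <- simulateCohort(cfg$n_discovery, seed = cfg$seed + 1L)
    nCpg <- length(design$cpgs)
    perSeg <- nCpg / cfg$n_segments
    blocks <- lapply(seq_len(cfg$n_segments), function(s)
      list(cpgs = ((s - 1L) * perSeg + 1L):(s * perSeg), rho = 0.85))
    dmrCpgs <- ((cfg$dmr_segment - 1L) * perSeg + 1L):(cfg$dmr_segment * perSeg)
    baselines <- withLocalSeed(cfg$seed + 1L, stats::runif(nCpg, 35, 65))
    baselines[dmrCpgs] <- 50
    methDisc <- simulateMethylation(disc, nCpg = nCpg, blockSpec = blocks,
      effects = list(list(cpgs = dmrCpgs, slope = cfg$dmr_slope)),
      baselines = baselines, outcome = cfg$outcome,
      positions = design$cpgs, seed = cfg$seed + 2L)
    signals <- simulateArray(methDisc, design$probes, gain = cfg$gain,
      baseline = cfg$baseline, noiseSd = cfg$noise_sd,
      failedRate = cfg$failed_rate, dMax = cfg$d_max, seed = cfg$seed + 3L)

    val <- simulateCohort(cfg$n_validation, seed = cfg$seed + 4L)
    methVal <- simulateMethylation(val, nCpg = 9L,
      blockSpec = validationBlockSpec(),
      effects = list(list(cpgs = 1:9, slope = cfg$validation_slope)),
      baselines = rep(50, 9), outcome = cfg$outcome, seed = cfg$seed + 5L)
    links <- list(
      anril_linear = list(cpgs = 4:8, sign = 1, magnitude = cfg$expression_magnitude),
      anril_unspliced = list(cpgs = 9L, sign = 1, magnitude = cfg$expression_magnitude),
      p14arf = list(cpgs = 9L, sign = -1, magnitude = cfg$expression_magnitude),
      p16ink4a = list(cpgs = 9L, sign = -1, magnitude = cfg$expression_magnitude))
    expr <- simulateExpression(methVal, links, seed = cfg$seed + 6L)

    raine <- simulateCohort(cfg$n_raine, collinearCells = TRUE,
                            primaryOutcome = "bmi", seed = cfg$seed + 7L)

    writeCohort(disc, fp("cohort_discovery.csv"))
    writeCohort(val, fp("cohort_validation.csv"))
    writeCohort(raine, fp("cohort_raine.csv"))
    writeMethylationMatrix(methDisc, fp("methylation_discovery.csv"),
                           fp("cpg_positions_discovery.bed"))
    writeMethylationMatrix(methVal, fp("methylation_validation.csv"),
                           fp("cpg_positions_validation.bed"))
    writeProbeTable(signals, fp("probes.tsv"))
    writeBed(design$windows, fp("windows.bed"))
    write.csv(expr, fp("expression.csv"), row.names = FALSE, quote = FALSE)
    list(design = design, disc = disc, methDisc = methDisc,
         signals = signals, val = val, methVal = methVal, expr = expr,
         raine = raine, links = links)
  })

  ## -- estimate ---------------------------------------------------------
  profile <- stage("estimate", {
    coupling <- buildCoupling(sim$signals, sim$design$cpgs, dMax = cfg$d_max)
    sigClean <- detectFailedProbes(sim$signals, epsilon = cfg$epsilon)
    prof <- estimateWindowMethylation(sigClean, coupling, sim$design$windows,
      gain = cfg$gain, baseline = cfg$baseline, noiseSd = cfg$noise_sd,
      gridStep = cfg$grid_step, prior = cfg$prior)
    tab <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(sim$design$windows)),
      start = start0(sim$design$windows), end = end0(sim$design$windows),
      m_mean = sprintf("%.6f", rowMeans(methMean(prof))),
      n_probes = probesUsed(prof))
    write.table(tab, fp("profile.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    prof
  })

  ## -- scan -------------------------------------------------------------
  calls <- stage("scan", {
    calls <- callDMRs(sim$signals, sim$design$cpgs, sim$design$windows,
      phenotype = sim$disc[[cfg$outcome]], gain = cfg$gain,
      baseline = cfg$baseline, noiseSd = cfg$noise_sd, dMax = cfg$d_max,
      epsilon = cfg$epsilon, pThreshold = cfg$p_threshold,
      diffThreshold = cfg$diff_threshold, spanThreshold = cfg$span_threshold,
      maxGap = cfg$max_gap, gridStep = cfg$grid_step, prior = cfg$prior)
    write.table(format(calls, digits = 10), fp("dmr_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    calls
  })

  ## -- reduce -----------------------------------------------------------
  reduction <- stage("reduce", {
    rho <- spearmanMatrix(sim$methVal)
    part <- contiguousClusters(rho, rhoMin = cfg$rho_min)
    mads <- madScores(sim$methVal)
    reps <- selectRepresentatives(part, mads)
    writeLines(c(paste0("partition: ",
                        paste(formatPartition(part), collapse = ",")),
                 paste0("representatives: ", paste(reps, collapse = ","))),
               fp("reduction.txt"))
    list(partition = part, mad = mads, representatives = reps)
  })

  ## -- adjust -----------------------------------------------------------
  adjust <- stage("adjust", {
    svs <- referenceFreeSVs(t(methMean(profile)),
                            primary = sim$disc[[cfg$outcome]],
                            nPerm = cfg$n_perm_sv, seed = cfg$seed + 8L)
    guard <- collinearityGuard(
      covariates = sim$raine[, c("age", "sex")],
      candidates = sim$raine[, paste0("cell_", simCellNames[1:3])],
      outcome = standardizeOutcome(sim$raine$bmi, cfg$skew_threshold)$z,
      threshold = cfg$vif_threshold)
    writeLines(c(sprintf("surrogate variables retained: %d", svs$k),
                 sprintf("cell-type adjustment blocked: %s", guard$blocked),
                 sprintf("vif: %s",
                         paste(sprintf("%s=%.2f", names(guard$report$vif),
                                       guard$report$vif), collapse = ", "))),
               fp("adjustment.txt"))
    list(svs = svs, guard = guard)
  })

  ## -- associate --------------------------------------------------------
  assoc <- stage("associate", {
    out <- standardizeOutcome(sim$val[[cfg$outcome]], cfg$skew_threshold)
    covs <- sim$val[, c("sex", "age")]
    vals <- methValues(sim$methVal)
    rows <- lapply(seq_along(reduction$representatives), function(i) {
      r <- reduction$representatives[i]
      fit <- fitAssociation(out, vals[, r], covariates = covs)
      data.frame(cluster = formatPartition(reduction$partition)[i],
                 representative = r, n = fit$n, beta = fit$beta,
                 ci_lo = fit$ci[1], ci_hi = fit$ci[2], p_value = fit$p_value)
    })
    assocTab <- do.call(rbind, rows)
    write.table(format(assocTab, digits = 10), fp("associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    erow <- lapply(names(sim$links), function(nm) {
      l <- sim$links[[nm]]
      blk <- which(vapply(reduction$partition,
                          function(b) any(l$cpgs %in% b), logical(1)))[1]
      r <- reduction$representatives[blk]
      fit <- expressionAssociation(sim$expr[[paste0("dct_", nm)]], vals[, r],
        covariates = cbind(sim$val[, c("sex", "ethnicity")],
                           batch = sim$val$batch))
      data.frame(transcript = nm, representative = r, n = fit$n,
                 beta = fit$beta, p_value = fit$p_value,
                 planted_sign = l$sign)
    })
    exprTab <- do.call(rbind, erow)
    write.table(format(exprTab, digits = 10),
                fp("expression_associations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(methylation = assocTab, expression = exprTab)
  })

  ## -- manifest ---------------------------------------------------------
  outputs <- sort(setdiff(list.files(outDir), c("manifest.json", "run.log")))
  manifest <- list(config = cfg,
                   outputs = as.list(tools::md5sum(file.path(outDir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  logLines <- c(logLines,
                paste0("config md5: ",
                       unname(tools::md5sum(fp("manifest.json")))))
  writeLines(logLines, fp("run.log"))

  invisible(list(config = cfg, calls = calls, reduction = reduction,
                 adjust = adjust, associations = assoc, profile = profile,
                 sim = sim))
}
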