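# mbdDMR

Discovery-to-validation analysis of DNA methylation from MBD-enrichment
promoter tiling arrays, for epigenetic-epidemiology studies that relate
perinatal methylation to later phenotypes (e.g. childhood adiposity).

Cohort data of this kind are typically private, so the package also ships a
synthetic-data module that generates every input — cohorts, methylomes,
array signal, qPCR expression — with known ground truth, making the entire
pipeline testable offline.

## What it computes

**Window methylation from array signal.** A probe's log2 enrichment ratio is
modelled as linear in the methylation level *m* of its window, weighted by a
CpG-density coupling factor `C_pc = max(0, 1 − d/d_max)` (d = probe-midpoint
to CpG distance):

    y_p ~ Normal(baseline + gain · m · Σ_{c∈window} C_pc,  σ²)

The posterior over `m` is evaluated on a grid, giving a posterior mean, mode
and central 95% credible interval per 100-nt window. Probes with |log2| ≈ 0
are flagged as failed and removable.

**DMR calling.** Per-window Huber robust regression of % methylation on the
phenotype (IRLS, c = 1.345), a stringent joint filter (window p < 0.01 and
absolute methylation difference between the top and bottom phenotype
tertiles strictly > 20%), one-sided Fisher-exact enrichment of flagged
windows within contiguous spans, and an intersection requiring every call to
survive removal of failed probes.

**CpG reduction.** Spearman correlation of validation-cohort CpGs,
contiguous clustering of adjacent CpGs (rho ≥ 0.68 by default), unscaled-MAD
ranking, one representative CpG per cluster, and cross-cohort harmonization
by finest common refinement.

**Heterogeneity handling.** Reference-free surrogate variables
(residual SVD + permutation parallel analysis), reference-based cell
proportions (exact constrained least squares), and a VIF collinearity guard
(`1/(1−R²)`, threshold 10) that refuses cell-type adjustment when cell
composition tracks the outcome.

**Association models.** Outcomes are log_e-transformed when skewed and
Z-scored, so a regression coefficient reads as SD change in outcome per 1%
methylation (−0.02 ⇒ −0.2 SD per 10% methylation). Expression is analysed as
dCt = Ct_target − geometric mean of two reference-gene Cts.

## Worked example

```r
library(mbdDMR)

## --- discovery: simulate a tiled promoter array and scan for DMRs -------
des    <- arrayDesign(nSegments = 10)            # 50 windows, 150 probes
cohort <- simulateCohort(24, seed = 1)
blocks <- lapply(1:10, function(s) list(cpgs = ((s-1)*25+1):(s*25), rho = 0.85))
meth   <- simulateMethylation(cohort, nCpg = length(des$cpgs),
            blockSpec = blocks,
            effects = list(list(cpgs = 76:100, slope = -3)),  # segment 4
            baselines = rep(50, 250), positions = des$cpgs, seed = 2)
signals <- simulateArray(meth, des$probes, dMax = des$dMax, seed = 3)

calls <- callDMRs(signals, des$cpgs, des$windows, cohort$pct_fat,
                  gain = 1, baseline = 0.5, noiseSd = 0.15, dMax = des$dMax)
calls[, c("span", "chrom", "start", "end", "n_windows", "fisher_p")]
#>  span chrom start   end n_windows     fisher_p
#>     4  chr9 12700 13200         5 2.171081e-05
```

The one called span is exactly the segment carrying the planted effect: all
5 of its windows pass the joint filter, in both the full and the
failed-probe-cleaned runs, and nothing else is called.

```r
## --- validation: reduce 9 pyrosequenced CpGs and fit the association ----
val     <- simulateCohort(250, seed = 4)
methVal <- simulateMethylation(val, nCpg = 9,
             blockSpec = list(list(cpgs = 1:2, rho = 0.9), list(cpgs = 3, rho = NA),
                              list(cpgs = 4:8, rho = 0.9), list(cpgs = 9, rho = NA)),
             effects = list(list(cpgs = 1:9, slope = -0.07)),
             baselines = rep(50, 9), seed = 5)

part <- contiguousClusters(spearmanMatrix(methVal), rhoMin = 0.68)
formatPartition(part)
#> [1] "1-2" "3"   "4-8" "9"
reps <- selectRepresentatives(part, madScores(methVal))
reps
#> [1] 2 3 7 9

outcome <- standardizeOutcome(val$pct_fat)
fitAssociation(outcome, methValues(methVal)[, reps[3]],
               covariates = val[, c("sex", "age")])
#> AssociationResult: beta = -0.01938 (95% CI -0.0443, 0.005548), p = 0.127, n = 250
#>   adjusted for: sexM, age
```

The 9 CpGs collapse into the four contiguous clusters 1–2, 3, 4–8 and 9,
represented by CpGs 2, 3, 7 and 9 (max MAD per cluster). The fitted
coefficient for the cluster-4–8 representative, −0.019 SD of %fat per 1%
methylation, recovers the planted effect (≈ −0.02 SD/% at these generator
settings; the per-cohort sampling error on this coefficient is about 0.011).

`runPipeline(config, outDir)` chains all stages (simulate → estimate → scan
→ reduce → adjust → associate), persists every intermediate as
CSV/TSV/BED, and writes a manifest with the resolved configuration; a fixed
seed gives byte-identical outputs. A thin command-line wrapper is available
as `inst/scripts/run_pipeline.R`.

## Vignette

`vignettes/mbdDMR-methods.Rmd` documents the signal model, the scan
statistics, the reduction and adjustment procedures, every default and why
it was chosen, what the synthetic generator does and does not emulate, and
the package's known limitations.
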