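---
title: "Methods: from MBD-array signal to methylation-adiposity associations"
author: "mbdDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MBD-array signal to methylation-adiposity associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdDMR)
```

# Overview

mbdDMR implements a discovery-to-validation analysis for methylation studies
built on MBD (methyl-CpG-binding domain) capture and promoter tiling arrays.
The stages are:

1. **estimate** — invert probe-level log2 enrichment ratios into absolute
   fractional methylation per 100-nt window, adjusting for CpG density;
2. **scan** — call phenotype-associated differentially methylated regions
   (DMRs) with a robust per-window regression, a tertile-difference filter,
   Fisher-exact span enrichment and a failed-probe robustness intersection;
3. **reduce** — collapse correlated CpGs (as measured by pyrosequencing in a
   validation cohort) to one representative per contiguous cluster;
4. **adjust** — handle cellular heterogeneity with reference-free surrogate
   variables, reference-based cell proportions and a collinearity guard;
5. **associate** — fit covariate-adjusted methylation-outcome and
   methylation-expression regressions.

Because cohort data of this kind are private, the package ships a
synthetic-data module that generates every input with known ground truth;
all quantitative claims in the test suite are recovery properties against
that truth, not re-derivations of any cohort's numbers.

# The window methylation estimator

## Signal model

MBD capture enriches methylated fragments, so a probe's log2 ratio
(enriched/input) reflects the methylation of nearby CpGs, weighted by CpG
density. We encode this with a triangular *coupling factor*

$$C_{pc} = \max\left(0,\, 1 - d(p, c)/d_{\max}\right),$$

where $d(p,c)$ is the distance from the probe midpoint to CpG $c$. Within a
100-nt window we assume a single shared methylation level $m \in [0,1]$ and a
linear Gaussian signal model for each contributing, non-failed probe $p$:

$$y_p \sim \mathcal{N}\!\left(\beta_0 + \gamma\, m \sum_{c \in \text{window}}
C_{pc},\ \sigma^2\right).$$

The posterior over $m$ is evaluated on a grid (default step 0.01) under a
flat prior (a Jeffreys-type Beta(0.5, 0.5) prior is available by name; its
grid weights are Beta *cell masses*, which keeps the boundary cells finite).
We report the posterior mean, mode, and a central 95% credible interval from
the discrete cumulative distribution. With very concentrated discrete mass
the grid quantiles can exclude the mean; the interval is then widened to
include it, a deliberately conservative convention. Windows with no usable
probes are reported as missing and never imputed.

This estimator is a closed-form, fully testable Bayesian inversion in the
spirit of coupling-factor methods for MBD/MeDIP data. It is *not* an MCMC
reimplementation of any published tool: the published analyses of this kind
do not document their settings (coupling range, prior), so those are design
decisions here, with defaults $d_{\max} = 500$ nt, grid step 0.01, flat
prior, and failed-probe band $\varepsilon = 0.05$.

## Calibration

$\gamma$ (gain), $\beta_0$ (baseline) and $\sigma$ are platform properties.
`calibrateSignalModel()` estimates them by OLS of signal on the
coupling-weighted CpG count over user-designated calibration windows of
assumed full and zero methylation. There are no silent defaults: without a
calibration set the parameters must be passed explicitly.

## Failed probes

Probes whose log2 ratio sits at ~0 carry no enrichment information and are
flagged when $|y_p| < \varepsilon$ in every sample. The DMR caller runs the
whole scan twice — once on the data as supplied, once after flagging and
removing failed probes and re-estimating — and only calls spans that pass in
both runs.

# The DMR scan

Per window, percent methylation is regressed on the phenotype with a Huber
M-estimator (tuning constant 1.345, IRLS with the residual scale
re-estimated each iteration as $\mathrm{median}|r|/0.6745$, coefficient
tolerance $10^{-8}$, at most 50 iterations), guarding the screen against
heteroscedastic window estimates. Standard errors use the large-sample
sandwich $s^2 \sum \psi^2/(n-p) \,/\, \overline{\psi'}^2 (X'X)^{-1}$ and
p-values the normal approximation; with fewer than 8 complete cases a window
is reported untestable rather than erroring.

A window is *flagged* when its p-value is below the window threshold
(default 0.01) **and** the absolute percent-methylation difference between
the top and bottom phenotype tertiles strictly exceeds 20%. Tertiles are
formed by a stable sort on (phenotype, subject order) with group sizes
differing by at most one (extras to the lower groups first).

Flagged windows are then tested for enrichment within *spans* — maximal runs
of consecutively tiled windows, broken where the gap exceeds 100 nt — with a
one-sided Fisher exact (hypergeometric upper-tail) test against the
background of all tested windows. No genome-wide multiple-testing correction
is applied: the joint filter (window p, group difference, span enrichment in
two datasets) is intentionally a stringent prioritisation screen rather than
an FDR-controlled discovery procedure. The window p cutoff, the span cutoff
(default 0.01) and the span construction are configuration-exposed because
they cannot be pinned to a published value.

# CpG reduction

Validation-cohort pyrosequencing yields a subjects × CpGs percent
methylation matrix. Reduction proceeds as:

- **Spearman matrix** (mid-rank ties, pairwise complete);
- **contiguous clustering**: CpG $i{+}1$ joins CpG $i$'s block iff their
  adjacent correlation is at least `rhoMin` (default 0.68). Adjacent-pair
  single linkage was chosen over full-matrix linkage because the clusters
  of interest are contiguous runs in genomic order; a missing adjacent
  correlation forces a boundary;
- **MAD scores**: unscaled $\mathrm{median}|x - \mathrm{median}(x)|$. The
  1.4826 consistency factor is deliberately omitted — MAD is used only to
  *rank* CpGs within a block, where scaling is irrelevant;
- **representatives**: the max-MAD CpG per block, ties to the lowest
  genomic position;
- **harmonization** across cohorts as the *finest common refinement* (a
  boundary wherever any cohort has one). This is the partition-lattice
  meet: the only commutative, associative, idempotent rule, and it
  reproduces the canonical two-cohort resolution in which a trailing CpG
  that clusters with its neighbours in one cohort but not the other is
  kept separate.

# Cellular heterogeneity

Three complementary tools:

- `referenceFreeSVs()` residualizes each window on the primary phenotype,
  takes the SVD of the residual matrix, and retains components whose
  singular values beat the 95th percentile of column-permuted matrices
  (parallel analysis). This deterministic-given-a-seed variant was chosen
  over iteratively reweighted surrogate-variable estimation because it is
  directly testable: on pure noise it retains nothing ~95% of the time, and
  it recovers a planted batch component with |correlation| ≥ 0.9. By
  default the SVs are used as a sensitivity check rather than forced into
  the model.
- `referenceBasedProportions()` solves the constrained least-squares
  deconvolution (proportions ≥ 0, sum ≤ 1 — the slack tolerates unprofiled
  cell types) exactly, by enumerating the active sets of the small
  quadratic program. Panels are user- or generator-supplied matrices;
  published reference panels are not bundled.
- `collinearityGuard()` computes variance inflation factors
  $1/(1 - R^2_j)$ over the augmented design **including the outcome**, and
  refuses to append candidate adjusters (e.g. cell proportions) when any
  VIF exceeds the threshold (default 10, the usual convention). The outcome
  is included because the failure mode being guarded against is cell
  composition tracking the outcome itself, in which case "adjusting" for
  cells removes the signal under study; the model is then fitted without
  the candidates, never silently with them.

# Association models

Skewed adiposity outcomes (moment skewness > 1, a configurable
operationalisation of "skewed") are log_e-transformed, then Z-scored, so a
regression coefficient reads as *SD change in outcome per 1% methylation* —
e.g. a coefficient of −0.02 is −0.2 SD per 10% methylation. Conditional
growth velocities are Z-scored residuals of later size on earlier size plus
adjusters, optionally sex-specific. All fits are OLS with intercept,
complete-case (so n varies per model), with t-based 95% CIs.

qPCR expression is analysed on the delta-Ct scale,
$\mathrm{dCt} = Ct_\text{target} - \sqrt{Ct_\text{ref1} \cdot Ct_\text{ref2}}$,
taking "geometric mean of the reference amplicons" literally on the Ct scale
(the alternative reading — arithmetic mean of Cts, i.e. geometric mean of
linear abundances — is available as `method = "arithmetic"`; neither reading
can be ruled out, so the literal one is the default). Lower dCt means higher
expression.

Covariate presets (`"sws"`, `"sws_minimal"`, `"gusto"`, `"raine"`) only
select cohort columns. Two SWS presets exist because the fuller set (sex,
age, maternal age, mode of delivery) and the minimal set (sex, age) are both
defensible adjustments for the childhood-adiposity models; the discrepancy
is surfaced rather than resolved.

# The synthetic-data generator

`simulateCohort()`, `simulateMethylation()`, `simulateArray()` and
`simulateExpression()` emulate, with one integer seed feeding deterministic
sub-streams:

- **cohorts**: sex, age (~6 y), ethnicity, mode of delivery, maternal age,
  batch; percent fat mass Normal(25, 7) — roughly the 5th–95th percentile
  range of 6-year-olds — and right-skewed lognormal total fat, skinfold and
  BMI; Dirichlet cell proportions. With `collinearCells = TRUE` the
  Dirichlet location is a linear function of the standardized outcome at
  high concentration (20000), so each cell fraction regresses on the
  outcome with $R^2 \ge 0.9$ — the construction that triggers the
  collinearity guard.
- **methylation**: a Gaussian copula — latent exchangeable-correlation
  normals per contiguous block, mapped through per-CpG Beta marginals
  (baseline mean, sd 5%) — which gives controllable within-block Spearman
  correlation (the latent correlation is set to $2\sin(\pi\rho_S/6)$) and
  bounded values. Planted effects add `slope × (outcome − mean)`; values
  are clipped to [0, 100] (clipping rather than resampling, for
  transparency; the clip fraction is reported and a warning is raised above
  5%).
- **array signal**: the linear coupling model above plus Gaussian noise
  (sd 0.15, representative tiling-array noise), with a fraction (default
  5%) of probes replaced by near-zero values, |x| < 0.02, matching the
  failed-probe detection band.
- **expression**: dCt values generated with planted signed links to the
  driving CpG cluster and reconstructed target Cts around two reference
  amplicons, so re-normalization recovers the planted dCt exactly.

`arrayDesign()` produces the simulated platform: 41 promoter-like segments
of five 100-nt windows (205 windows) separated by 400-nt untiled gaps, five
CpGs per window placed centrally, three probes per window, and a coupling
range of 40 nt chosen so every probe's coupling footprint stays inside its
window — making the window-level likelihood exactly the generative model for
this platform. The planted discovery DMR uses slope −3% methylation per unit
%fat, which guarantees the planted condition the recovery tests assume (a
tertile difference comfortably above 20% at n = 24). The planted validation
effect (−0.07% methylation per unit %fat, noise sd 5%) corresponds to an
association of about −0.02 SD per % methylation, i.e. the −0.2 SD per 10%
effect scale the association models are designed to report.

**What the generator does not emulate:** scanner physics, dye bias, spatial
artifacts, sequence context, probe cross-hybridisation, genotype effects, or
non-linear methylation-outcome relationships. Passing recovery tests
therefore demonstrates the *statistical machinery* is correct and calibrated
under the stated model, not that any biological conclusion transfers to real
cohorts.

# Problem sizes and numerical choices

The test suite and the acceptance script run the Monte Carlo checks at
deliberately modest sizes chosen as the package's own verification budget:
50 seeds for planted-DMR sensitivity (25 in the script), 15–20 fully-null
replicates, 100 seeds for cluster recovery (50 in the script), 500 cohorts
of n = 215 for CI coverage, and 1000 permuted spans of 20 windows for
type-I control. The span size of 20 matters: Fisher exact p-values are
discrete, and small spans make the rejection fraction collapse far below
nominal; 20-window spans at a 10% flag rate give a rejection step close
enough to 0.05 for a meaningful two-sided band.

Other numerical conventions: probe records are sorted before calling DMRs so
results are invariant to input order; Huber scale collapse (exact fits) is
detected and returns zero SEs rather than dividing by zero; tertile ties are
broken by stable subject order; grid posterior computations are done in log
space with per-column max subtraction.

# Known limitations

- The estimator assumes one methylation level per window; sub-window
  deconvolution is out of scope, and probes coupling CpGs across window
  boundaries are handled correctly only insofar as neighbouring windows
  have similar methylation (exact for the bundled platform design).
- The Huber p-values are large-sample normal approximations; at n = 24 they
  are slightly anti-conservative in the extreme tail, which the joint
  filter (tertile difference > 20%) absorbs in practice.
- The surrogate-variable retention rule tests each component against the
  permutation distribution of the *corresponding* singular value, which is
  conservative for trailing components.
- `referenceBasedProportions()` enumerates active sets and is exact but
  exponential in the number of cell types; it is capped at 12 types.
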