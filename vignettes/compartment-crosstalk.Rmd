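---
title: "Compartmental deconvolution and relative crosstalk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental deconvolution and relative crosstalk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromatalk)
```

## The model

A bulk tumor RNA-seq sample is a mixture of malignant cells and everything
else — fibroblasts, immune cells, endothelium — here collapsed into two
expression pools, the *tumor* and *stroma* compartments. If sample $i$ has
tumor purity $p_i$ (the fraction of malignant cells), the observed bulk
expression of a gene is modeled as the purity-weighted mixture

$$ e_{\mathrm{bulk},i} \;=\; p_i\,\bar e_T + (1-p_i)\,\bar e_S , $$

where $\bar e_T$ and $\bar e_S$ are the gene's mean expression in the tumor
and stroma compartments, assumed constant across the samples of a cohort.
Given purities for $n \ge 2$ samples with at least two distinct values, the
two compartment means are estimated per gene by least squares under
nonnegativity constraints ($\bar e_T, \bar e_S \ge 0$ — expression means
cannot be negative). With two coefficients the constrained optimum has a
closed form: the unconstrained normal-equation solution when it is
feasible, otherwise the better of the two single-compartment boundary fits
(the objective is convex, so the optimum sits on an active constraint
whenever the interior solution is infeasible). Uncertainty is quantified by
a percentile bootstrap: samples are resampled with replacement, every gene
is refitted, and the 2.5th/97.5th percentiles of the replicate estimates
form the 95% interval. The percentile method was chosen over BCa as the
simplest defensible default; the method name is recorded in the output
metadata.

Deconvolution operates on **linear TPM**, because the mixture is additive
in expression; the log2(x + 1) transform is applied only where rank-based
purity estimation needs it. Cohorts (primary and metastatic lesions) are
deconvolved separately: compartment means are reported per lesion type, and
the constancy assumption is less strained within one lesion type than
across both.

## Purity estimation

Purity enters the model as a known covariate. The package estimates it the
way the ESTIMATE family of methods does: single-sample, rank-based
enrichment of a stromal and an immune signature. Per sample, genes are
ranked ascending by expression (average ranks for ties) and the score is
the running-sum difference between the weighted cumulative distribution of
in-set genes (weights $\mathrm{rank}^{0.25}$) and the uniform cumulative
distribution of out-of-set genes. The stromal and immune scores are summed
and converted to purity by the published cosine calibration
$p = \cos(0.6049872018 + 0.0001467884\,s)$; the two constants are external
calibration inputs carried in configuration. Because $\cos$ is decreasing
only on $[0, \pi]$, the argument is clamped to that interval, keeping the
conversion monotone non-increasing everywhere; the resulting purity is then
clamped into $[0.01, 0.99]$ so that both columns of the deconvolution
design stay informative.

Purity estimation is deliberately pluggable: every downstream function
consumes a `purity_set`, whether estimated or read from a file
(`read_purity()`). Consensus-purity estimates from copy number or
methylation can be substituted without touching the rest of the pipeline.

## Relative crosstalk

For a ligand gene $L$ and receptor gene $R$ with compartment means
$\bar e_{L,T}, \bar e_{L,S}, \bar e_{R,T}, \bar e_{R,S}$, mass-action
kinetics make the abundance of each directional complex proportional to
the product of the corresponding means divided by the dissociation
constant. Assuming constant kinetics across samples, the constant cancels
from the ratio of one complex to the sum of all four, giving the relative
crosstalk score, e.g. for tumor ligand signaling to stroma receptor:

$$ RC_{T,S} = \frac{\bar e_{L,T}\,\bar e_{R,S}}
 {\bar e_{L,T}\bar e_{R,S} + \bar e_{L,T}\bar e_{R,T}
 + \bar e_{L,S}\bar e_{R,S} + \bar e_{L,S}\bar e_{R,T}} . $$

The denominator is the sum of the four numerators, so the quadruple
$(RC_{T,T}, RC_{T,S}, RC_{S,T}, RC_{S,S})$ sums to one, and each score
factorizes into (ligand compartment fraction) × (receptor compartment
fraction) — both identities are enforced to $10^{-12}$ in the test suite.
When a ligand or receptor total is zero the quadruple is *undefined*, not
zero: 0/0 expresses no directional preference. Scores are computed from
bootstrap point estimates only; the intervals are not propagated to RC.

Rankings per direction take the top $k$ (default 15) pairs by a pooling
key over the two cohorts — `max_over_cohorts` by default, reading "top
pairs in either lesion type"; per-cohort and mean keys are available
because the pooling rule is genuinely a reporting choice. Ties break
alphabetically by ligand then receptor. A direction is flagged *decisive*
for a cohort when its RC exceeds 0.5, i.e. it outweighs the other three
directions combined; 0.5 is the only threshold with that interpretation,
which is why it operationalizes "decisively predominates".

## The synthetic-data generator

`simulate_cohort()` / `simulate_study()` emulate exactly the assumptions
above: fixed compartment means, Beta-distributed purities, linear mixing,
plus one addition — multiplicative mean-one log-normal noise
($\epsilon \sim N(-\sigma^2/2, \sigma^2)$, $\sigma$ set so the factor's CV
equals `noise_cv`) so bulk values stay nonnegative while mimicking
RNA-seq dispersion. Defaults are the benchmark study conditions: 470
samples, 2000 genes, purity Beta(5, 2) (melanoma cohorts skew pure, mean
5/7), noise CV 0.2, 100 ligand-receptor pairs of which 10 are planted
dominant per direction at 9:1 compartment skew (true RC
$0.9 \times 0.9 = 0.81$ in the planted direction).

Generator choices not dictated by those conditions, fixed once:

* **Background genes** draw lognormal(meanlog 3, sdlog 1) compartment
  means in which the two compartments share a per-gene base abundance with
  log-scale correlation 0.75 (each marginal remains exactly
  lognormal(3, 1)). Background genes are thereby non-directional apart
  from typical ~2-fold compartment differences — the realistic situation,
  since most genes are not strongly compartment-specific. With fully
  independent compartments the log tumor/stroma ratio would have sd
  $\sqrt 2$, and "background" pairs would routinely carry true RC above
  0.8, i.e. they would be planted directional signals in all but name.
* **Planted pair totals** draw lognormal(4, 0.3), placing them among
  well-expressed genes so the planted signal is attributable to skew, not
  abundance.
* **Signature genes** (50 stromal + 50 immune by default) are
  stroma-skewed — lognormal(4.5, 0.3) in stroma vs lognormal(1, 0.3) in
  tumor — and disjoint from all pair genes, so purity estimation and
  crosstalk recovery are tested without coupling.

What the generator does **not** emulate: count-level sampling noise,
gene-gene correlation, batch effects, spatial heterogeneity of the
microenvironment, or purity-estimation error feeding back into
deconvolution (the recovery benchmarks use the generator's true purities;
estimation quality is assessed separately by a Spearman > 0.8 requirement
against truth). Passing tests therefore demonstrate correctness of the
computation under the model's own assumptions, not robustness to their
violation in real tumors.

## Numerical choices and degenerate inputs

* All-identical purities make the design rank-1; the fit errors rather
  than returning an arbitrary point. Bootstrap replicates that resample
  into this state are skipped and counted; more than 10% skipped aborts.
* An all-zero gene fits (0, 0); a tumor-exclusive gene fits
  $\bar e_S = 0$ exactly.
* Boundary fits follow the convexity argument above; the
  solver-vs-grid-search comparison in the tests restricts to designs with
  purity spread ≥ 0.3, because near-collinear designs have a flat SSE
  valley along which the argmin is numerically undetermined — a property
  of the problem, not of either solver.
* Bootstrap CIs use `quantile()` type 7 on the replicate estimates; the
  bootstrap seed is an explicit argument, recorded in the JSON sidecar,
  and the RNG state of the caller is always restored.
* Duplicate gene symbols at load collapse to the highest-total row
  (deterministic, logged per collapse); symbols are uppercased so pair
  tables and signatures match on text.

## Problem sizes used in the checks

The packaged verification runs at: 10,000 random quadruples for the RC
identities; 500 random small instances ($n \le 6$) against the grid
oracle; noiseless recovery on 300 genes × 12 samples; study-scale recovery
at 470 samples × 2000 genes (median relative error of tumor means,
observed ≈ 1.6%, required < 5%); bootstrap coverage pooled over 200
simulation replicates × B = 200 at $n = 100$ and 10 genes (observed ≈
93–94% against the nominal 95%, accepted within [90%, 98.5%] — percentile
intervals at B = 200 are expected to undercover slightly); and planted-pair
ranking recovery at 470 + 470 samples.

## Known limitations

Compartment means are cohort constants: the model cannot express
sample-to-sample microenvironmental variation, and spatially uneven
tumor-stroma admixture is invisible to it. Two compartments only; immune
subpopulations are folded into stroma. RC scores carry no significance
measure — they are descriptive fractions of mass-action complex formation
— and receptor complexes with multiple subunits are not modeled. The
signature-based purity path is a reimplementation of the rank-scoring
contract, not a validated clone of any published tool; for production use
on real cohorts, supplying consensus purities via `read_purity()` is
recommended.
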