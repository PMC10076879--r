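---
title: "Methods: integrated differential methylation and expression analysis"
author: "methexint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated differential methylation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexint)
```

# The analysis problem

Paired-tissue designs in which a lesion (case) and matched normal tissue
(control) from the same patients are profiled on both a 450K-style DNA
methylation array and by RNA-seq — as in studies of ectopic versus eutopic
endometrium in endometriosis — pose an integration problem: which genes show
a methylation change at a regulatory locus *and* a concordant expression
change? `methexint` implements that workflow end to end:

1. **Differential methylation (DM).** Per-probe beta values
   ($\beta = M/(M+U+100)$, the standard Illumina offset form) are compared
   between groups with the two-sided Wilcoxon rank-sum test. A locus is a
   DML when the raw $p < 0.05$ **and** $|\Delta\beta| \ge 0.2$, where
   $\Delta\beta$ is the case-minus-control difference of group-mean betas.
   BH FDR is computed and reported but is deliberately not part of the
   gate: the effect-size criterion, not the multiplicity correction, is
   what controls the call rate at genome scale.
2. **Probe annotation.** Each probe maps to one of six gene-region groups
   (promoter = TSS1500 ∪ TSS200, 5'UTR, 1st exon, gene body, 3'UTR,
   multiple locations) or intergenic, and one CpG-island relation
   (island / shore / shelf / open sea, with N/S denoting the lower/higher
   coordinate flank; shores are the 2 kb flanks, shelves the next 2 kb).
3. **Differential expression (DE).** A deliberately transparent
   negative-binomial Wald stage: median-of-ratios size factors, per-gene
   method-of-moments dispersion, $\log_2$ fold change on pseudo-count-
   stabilised group means, Wald statistic with a delta-method standard
   error. DEGs satisfy $|\log_2 FC| \ge 1$ and adjusted $p < 0.05$.
4. **Integration.** Significant DMLs are joined to DE results at gene
   level; genes partition into promoter-related and enhancer-related DMGs
   (the latter simply "not promoter" — no chromatin evidence is used), and
   into four quadrants of the $(\Delta\beta, \log_2 FC)$ plane. Candidate
   tables are the top genes by $|\Delta\beta|$ in the two anti-correlated
   quadrants, additionally gated by the DE criteria.
5. **Enrichment** of any resulting gene list by the hypergeometric upper
   tail against a user-supplied GMT collection, and **qPCR validation**
   via the $2^{-\Delta\Delta Ct}$ method with normality-driven test
   selection (Welch t when both groups pass a Lilliefors-style KS check,
   Mann–Whitney otherwise).

# Statistical choices and their rationale

## Wilcoxon p-values

The rank-sum p-value is exact (full enumeration semantics, via the null
distribution of the U statistic) when the combined sample size is at most
`exactThreshold` (default 12) and there are no ties; otherwise the normal
approximation with tie-corrected variance is used. The **continuity
correction is off by default**. This is a deliberate calibration choice:
at the group sizes this pipeline targets (5–10 per group) the two-sided
p-value of a discrete rank statistic is already conservative near 1, and
adding the continuity correction makes the null distribution of p
measurably less uniform (sup-distance from uniform ≈ 0.058 at $n = 10$
per group, versus ≈ 0.034 uncorrected — the exact test itself sits at
≈ 0.059 because of discreteness). Since downstream calling uses raw
p-values, calibration matters more than textbook convention; `correct =
TRUE` restores the correction.

The test is unpaired by default even though samples are matched pairs:
the reported quantities (group-mean betas, $\Delta\beta$) are group-wise
summaries, and an unpaired test keeps the calling criteria interpretable
in their terms. `paired = TRUE` switches to the signed-rank test on
matched pairs.

## The simplified NB Wald stage

The DE stage is intentionally *not* a reimplementation of a
shrinkage-based fitter: there is no information sharing across genes, no
outlier refitting, and no GLM machinery. Per gene,

$$\hat\alpha = \max\!\left(10^{-8},
  \frac{s^2_{\text{pooled}} - \bar\mu}{\bar\mu^2}\right), \qquad
  \widehat{\log_2 FC} = \log_2\frac{\hat\mu_{case} + 0.5}
  {\hat\mu_{ctrl} + 0.5},$$

with $s^2_{\text{pooled}}$ the df-weighted within-group variance of
normalized counts and the Wald standard error from
$\mathrm{Var}(\hat\mu_k) = (\mu_k + \alpha\mu_k^2)/n_k$. The pseudo-mean
0.5 stabilises fold changes of low-count genes. The Wald statistic is
referred to a **t distribution with the pooled within-group df** rather
than a normal: the variance is estimated from few replicates (8 df at 5
per group), and a normal reference is anti-conservative exactly in
proportion to those missing df ($P(|t_8| > 1.96) \approx 0.086$). With
the t reference the null false-positive fraction at raw $p < 0.05$ sits
at 0.04–0.06 in the package's own null simulations. The trade-off is a
small power loss at tiny group sizes, which the planted-effect recovery
suite shows to be immaterial at $|\log_2 FC| = 2$.

## Integration conventions

Genes with several significant loci are represented by the locus with the
largest $|\Delta\beta|$ (ties: smaller p, then lexicographic probe id).
Quadrants follow the convention part 1 = hypomethylated–upregulated,
part 2 = hyper–up, part 3 = hypo–down, part 4 =
hypermethylated–downregulated, so parts 1 and 4 are the quadrants
expected under repressive promoter methylation; a value exactly on an
axis is "boundary" and excluded from quadrant counts. Quadrant
percentages are rounded to one decimal with round-half-even. Candidate
tables report `beta_change` as the *absolute* $\Delta\beta$ with the
direction carried by the table identity (hyper-down vs hypo-up), matching
how such tables are conventionally printed.

## Enrichment background

The default universe is the set of measured genes of the relevant
platform (count-matrix genes for expression lists); this single choice
changes enrichment results more than any other setting, so it is exposed
(`enrichUniverse`). Gene sets arrive as GMT files; no pathway database is
bundled.

## ddCt

$\Delta Ct = Ct_{target} - Ct_{reference}$ per sample;
$\Delta\Delta Ct$ subtracts the *arithmetic mean* control $\Delta Ct$,
so per-sample fold changes $2^{-\Delta\Delta Ct}$ are reported and the
control group has geometric-mean fold 1 by construction. Fold changes are
invariant to any constant shift applied to all Ct values.

# The synthetic-data generator

Every downstream stage is validated against data with planted truth,
generated by `simulateStudy()`:

- **Design.** `nPairs` matched case/control pairs (default 6, a typical
  methylation-array design for this tissue setting) profiled on
  `nProbes` probes and `nGenes` genes.
- **Methylation.** Baseline probe means are bimodal
  (Beta(0.4, 0.4) squeezed to [0.03, 0.97]), per-sample noise is
  Beta$(\mu\phi, (1-\mu)\phi)$ with precision $\phi = 40$. A fraction
  `fracDml` of probes receives a signed case-group shift of
  `deltaBetaEffect` (default 0.3); planted baselines are drawn so the
  shifted mean stays inside the unit interval.
- **Expression.** Log-normal gene abundances scaled to `baseDepth`
  expected counts per library, log-normal library factors
  ($\sigma_{\log} = 0.2$), NB counts with dispersion `nbDispersion`
  (default 0.05). A fraction `fracDeg` of genes gets a signed
  `lfcEffect` (default 2).
- **Coupling.** Every gene whose promoter carries a planted DML gets
  $\log_2 FC = c \cdot \Delta\beta \cdot \text{lfcEffect} /
  \text{deltaBetaEffect}$ with `couplingStrength` $c \in [-1, 0]$
  (default −1), i.e. full repressive coupling: promoter hypermethylation
  of the planted size exactly cancels or induces the planted fold
  change, anti-correlated in sign. Coupling is restricted to promoter
  probes because promoter-level integration is the analysis headline.

What the generator does **not** emulate: probe-level spatial correlation
along the genome, type I/II probe chemistry differences, cell-type
mixture, batch structure, count outliers, and gene–gene correlation.
Passing recovery suites therefore demonstrates correctness of the
*computations*, not robustness to every artefact of real array or
sequencing data.

# Validation design and problem sizes

The test suite checks, at fixed seeds:

- primitive-level oracle equivalence (exact Wilcoxon vs full enumeration
  for all designs with $n_1+n_2 \le 10$; BH vs brute-force step-up;
  hypergeometric tail vs one-sided Fisher exact on random tables);
- null calibration — with nothing planted, DM p-values are approximately
  uniform (KS < 0.05 on 10,000 probes, 10 pairs) and essentially no DML
  passes the double gate; the DE null false-positive fraction at raw
  $p<0.05$ lies in [0.02, 0.09] (2,000 genes, 5 pairs);
- planted-truth recovery — DML recall ≥ 90% at $|\Delta\beta| = 0.3$
  (10 pairs); DEG recall ≥ 80% with observed FDP ≤ 0.15 at
  $|\log_2 FC| = 2$, dispersion 0.05, 5 pairs, baseline mean ≥ 100;
  with full coupling the promoter-group Pearson r is negative with
  $p < 0.05$ and ≥ 80% of recovered coupled genes fall in quadrants
  1/4;
- worked-example agreement on the two bundled 15-row candidate tables
  (group-mean arithmetic re-derives the printed `beta_change` within
  5e-9; the gates retain all rows; ranking by `beta_change` reproduces
  the printed order).

These problem sizes (10,000 probes, 2,000 genes, 6,000-probe integrated
runs) keep the whole suite under a minute while leaving every estimate's
Monte-Carlo error far from the asserted margins.

# Known limitations

- The DE stage's dispersion estimate is per-gene method-of-moments; at
  2–3 replicates per group it is noisy and the stage should not be used
  as a production DE tool — it exists to make the integration testable
  and self-contained.
- "Enhancer-related" means only "significant DML outside TSS1500/TSS200";
  no enhancer annotation is consulted.
- Normalization is limited to quantile normalization of beta matrices
  and median-of-ratios size factors; background correction, dye-bias and
  batch adjustment are out of scope.
- The KS normality check uses the Lilliefors correction for $n \ge 5$
  and falls back to the plain (conservative) KS p-value for $n$ of 3–4.
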