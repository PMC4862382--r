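---
title: "Weakest-link pleiotropy scanning: models, parameters and design choices"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakest-link pleiotropy scanning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

# The statistical model

## Reciprocal polygenic prediction

For a source trait with per-variant effect estimates $w_j$ (log odds
ratios for a binary trait, linear betas otherwise) and P-values $p_j$, the
risk score of individual $i$ at inclusion threshold $T$ is

$$\mathrm{score}_i(T) \;=\; \frac{\sum_{j:\,p_j \le T} d_{ij}\,w_j}{2\,M_i},$$

where $d_{ij}\in\{0,1,2\}$ counts effect alleles and $M_i$ is the number
of non-missing scored markers. The $1/(2M_i)$ factor is the
average-per-allele convention used by standard scoring software. It is an
affine rescaling: regression test statistics, P-values and $R^2$ are
invariant to it, so the choice is inferentially neutral (and tested to be
so). The five default thresholds are $5\times10^{-5}$ through
$5\times10^{-1}$ in decade steps; the informative output is the *profile*
of prediction strength across thresholds, not any single row.

Prediction models are `phenotype ~ score + sex + age + factor(study)`:
ordinary linear regression for quantitative phenotypes, reporting the
score term's $t$ and the incremental $R^2$ over the covariates-only
model; logistic regression for binary phenotypes, reporting the Wald $Z$
and Nagelkerke's $R^2$ of the full model relative to the covariates-only
model,

$$R^2_N \;=\; \frac{1-(L_0/L_1)^{2/n}}{1-L_0^{2/n}}.$$

Whether a reported PRS $R^2$ should be incremental over covariates or
absolute is a genuinely open convention; this package implements the
incremental reading for the linear case and the covariates-referenced
Nagelkerke form for the logistic case, and states so here rather than
hiding it. Complete separation in the logistic fit is detected from
saturated fitted probabilities; the result row is then flagged
(`reliable = FALSE`) with $R^2 = 1$, since the likelihood ratio is
degenerate and the Wald P-value meaningless.

## The weakest-link overlap test

At each harmonized variant let $P_1,\dots,P_m$ be the per-trait
background-adjusted P-values. The overlap statistic is the weakest link

$$R = \max_j P_j,$$

small only when *every* trait supports the variant. Assuming independent
trait tests and uniform nulls,

$$P(R \le r) = r^m,$$

evaluated in log space. Two consequences shape the test's behaviour:

* At overall level $\alpha$ each trait must individually reach
  $\alpha^{1/m}$ — for $m = 2$ and $\alpha = 5\times10^{-8}$, both
  P-values must fall below $\sqrt{5\times10^{-8}} \approx
  2.2\times10^{-4}$ (`perTraitThreshold()`).
* Even when one trait carries an arbitrarily extreme signal, the overlap
  test's per-variant false-positive rate is bounded by the same
  $\alpha^{1/m}$ (`worstCaseFpr()`), because rejection still requires the
  null trait's uniform P-value to fall below it. This bound is verified
  by a $10^7$-draw simulation in the test suite.

A variant that is genome-wide significant in one trait but has, say,
$P = 0.2$ in the other gets $R = 0.2$ and overlap P-value $0.04$ — never
selected after multiplicity adjustment. This "balanced contribution"
requirement is intrinsic to the max statistic; no explicit pre-filter is
needed. The alternative min-based statistic is exposed behind
`statistic = "min"` for comparison but is not part of the default
analysis.

The `empirical` null option replaces each uniform term with the trait's
genome-wide empirical CDF evaluated at $r$, for use when the adjusted
P-values are visibly non-uniform.

## Background adjustment

The per-trait "background enrichment" adjustment is genomic control:
$\lambda = \mathrm{median}(z^2)/0.4549$ (the $\chi^2_1$ median), adjusted
statistics $z^2/\max(\lambda, 1)$, P-values from the $\chi^2_1$ tail.
Deflation ($\lambda < 1$) is never applied, and with fewer than 100
variants the adjustment is skipped with a warning because the median is
too unstable. Genomic control is one of several defensible readings of
"background adjustment"; it is isolated behind `backgroundAdjust()` so an
alternative can be swapped in without touching the scan.

## Multiplicity, tiers and loci

Overlap P-values receive Benjamini–Hochberg step-up q-values
(`stats::p.adjust`, verified in tests against a hand-computed step-up and
a five-value worked example). Two tiers are used: loci at $q \le 0.05$,
and a relaxed candidate tier at $q \le 0.16$ for pathway work. The 0.16
comes from equating the q cutoff to an AIC penalty factor of 2 in a 1-df
likelihood-ratio test: $P(\chi^2_1 > 2) = 0.157 \approx 0.16$
(`aicQvalueCutoff()`). A BH step-up is the default reading of "an FDR
method"; a $\pi_0$-estimating q-value variant would be a drop-in
replacement but is not bundled.

Significant variants are chained into loci: consecutive $q$-significant
variants on one chromosome within 250 kb (configurable; no canonical
value exists, 250 kb is a common clumping radius) join one locus, led by
the smallest overlap P-value with position as tie-break.

## Genes, pathways, crosstalk

Candidate markers map to genes by containment, else to the nearest gene
boundary within a 50-kb flank on either side (inclusive at exactly 50 kb);
equidistant ties break toward the smaller start coordinate — a documented
arbitrary choice, exercised in tests. Genes are counted once per trait
list however many markers hit them; lists merge by requiring presence in
at least 2 of the quantitative-trait lists; the seven classical HLA
symbols are removed by exact match (long-range LD makes their joint
appearance uninformative).

Enrichment is the one-sided hypergeometric upper tail
$P(X \ge k)$ with $K$ pathway genes in an $N$-gene reference universe and
$n$ list genes, inclusive at $k$ (the standard convention). The reference
universe is *all genes in the supplied annotation*, never a hardcoded
genome count. Pathways need $k \ge 3$ and $K \le 300$ *before* BH
adjustment; significance is adjusted $P < 0.05$.

Crosstalk between two enriched pathways is scored as the number of PPI
edges with one endpoint in each pathway's observed gene set (shared genes
contribute via their incident edges; a pathway is never paired with
itself). The null redraws, `nPerm = 1000` times, two gene sets of the
same sizes (after intersecting the observed sets with the PPI node
universe — genes absent from the network cannot contribute edges, so
matching the intersected size keeps the null comparable) uniformly from
the PPI nodes, and

$$p_{\mathrm{perm}} = \frac{1 + \#\{\mathrm{null} \ge \mathrm{obs}\}}{n_{\mathrm{perm}} + 1}.$$

Pairs with $p_{\mathrm{perm}} < 0.05$ are retained. This
between-set-edge-count score with a size-matched permutation null is this
package's own, deliberately simple, crosstalk definition occupying the
usual interface of sub-pathway network methods; it is exchangeable
without touching the rest of the pipeline.

# The synthetic-data generator

`simulateArchitecture()` draws, from the seed alone, a single linear
pseudo-chromosome of independent variants (15-kb spacing, MAF uniform on
[0.05, 0.5], non-palindromic allele pairs so two scans over one simulated
universe harmonize losslessly), causal sets for the two traits with a
configurable overlap, and effect sizes: shared causal variants get
bivariate-normal effect pairs with correlation `sharedEffectCorr`,
others independent $N(0, \sigma^2)$ effects.

`simulateCohort()` then draws genotypes binomially under Hardy–Weinberg,
a quantitative trait as centered-dosage genetic value + sex/age/study
covariate terms + unit-variance noise, and a binary trait from a
liability-threshold model: liability = genetic value + $N(0,1)$, case
when liability exceeds the theoretical $(1-\mathrm{prevalence})$ quantile.
Several cohorts can share one architecture (`cohortId` offsets the data
RNG only), which is how the pipeline emulates genetically correlated
nicotine-dependence-style traits measured in disjoint samples, and how
the PRS harness guarantees weight and target cohorts never share
individuals.

Default study conditions: 2,000 individuals, 1,000 variants, 60 causal
variants per trait with 30 shared at effect correlation 0.8, effect SD
0.12 (per-allele, phenotype-SD units), covariate effects 0.2 (sex), 0.01
per year (age), 0.15 (study). Binary-trait prevalence defaults to 0.25:
a realistic population prevalence of ~1% would leave a desk-scale
population sample with almost no cases, so the generator emulates the
enriched case fractions of case–control GWAS while keeping a calibrated
liability-threshold null; per-variant scans use plain logistic regression
on that sample (a case–control ascertainment option was deliberately not
added — downstream tests need calibrated nulls, not realistic
ascertainment).

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
(variants are independent; locus chaining is exercised by proximity, not
LD structure), population structure and relatedness, imputation dosages
(hard calls only), sample overlap between GWAS (the overlap test assumes
independent trait tests, as stated; no overlap correction is
implemented), and real pathway/PPI topology (Erdős–Rényi with optional
within-pathway edge bonus).

`simulateAnnotation()` tiles non-overlapping genes left-to-right with
uniform lengths (10–50 kb) and gaps (0–150 kb), so under the defaults
some variants fall in genes, some within the 50-kb flank and some beyond;
it errors if more genes are requested than fit. Pathway membership can be
weighted toward genes containing shared causal variants
(`causalEnrichment`) to give downstream enrichment a recoverable truth.

# Numerical choices

* P-values from Z statistics are computed in log space,
  $p = 2\Phi(-|z|)$, because the naive tail underflows beyond
  $|z| \approx 37$ while joint analyses of strong loci need P-values down
  to $10^{-24}$ and beyond. All P-values are floored at $10^{-300}$.
* z/p consistency (1e-6 relative through the normal tail), $p \in (0,1]$,
  $se > 0$ (a monomorphic record carries $se = \infty$, $z = 0$, $p = 1$,
  and a flag; a residual-free fit has its $se$ floored at $10^{-300}$),
  distinct alleles and unique ids are enforced by the `SummaryStats`
  validity method at construction, not downstream.
* Coordinates are 1-based inclusive everywhere; BED input/output converts
  at the boundary. Chromosome labels are normalized ("chr" stripped, X
  → 23) for sortable numeric order.
* Strand-ambiguous palindromic variants (A/T, C/G) are dropped during
  harmonization rather than frequency-resolved: no downstream stage needs
  allele frequencies, so the simplest safe policy wins. Irreconcilable
  allele pairs are dropped with a logged reason, not a fatal error.
  How multiple GWAS should be allele-aligned is generally unstated in
  summary-level analyses; this explicit policy is the package's own.
* The quantitative scan residualizes phenotype and dosages on the
  covariates once (QR) and computes all slopes vectorized — exact OLS,
  oracle-tested against `lm`-equivalent algebra; the logistic scan uses
  `glm.fit` per variant and is oracle-tested against `glm()`.

# Problem sizes

The bundled tests and the acceptance script run at desk scale, chosen so
each property is measured with useful precision: Monte-Carlo null
calibration at $10^6$ variant pairs, the worst-case false-positive bound
at $10^7$ draws, FDR control over 20 seeded scans of 20,000 variants with
5% planted shared signals, planted-signal recovery over 20 scans of
5,000 variants, heritability calibration at 20,000 individuals × 10
seeds, and PRS parameter recovery at 2,000 individuals × 500 variants ×
10 seeds per correlation value. The end-to-end pipeline demo (four
cohorts of 1,500 × 600 variants, three quantitative traits) completes in
a few seconds.

# Known limitations

* Independence between trait tests is assumed throughout the overlap
  machinery; overlapping GWAS samples inflate the joint test and must be
  handled upstream (the synthetic harness simply never reuses
  individuals).
* Genomic control is a blunt instrument for polygenic "background
  enrichment"; heavily polygenic traits deflate true signals.
* No LD awareness anywhere: locus chaining is purely positional, marker
  counts in loci are not independent-signal counts, and no clumping is
  performed before scoring (none is part of the method).
* The crosstalk score is a deliberate simplification of sub-pathway
  network algorithms; its permutation null ignores degree structure.
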