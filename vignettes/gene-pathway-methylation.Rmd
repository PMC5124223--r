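---
title: "From CpGs to genes to pathways: the methscore model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CpGs to genes to pathways: the methscore model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscore)
```

## The problem

Epigenome-wide association studies regress the methylation fraction
(beta value, $\beta = M/(M+U+100)$) of each CpG on an exposure and keep the
survivors of a genome-wide Bonferroni threshold. That single-locus view
discards moderate, coordinated effects spread across the several CpGs of a
gene, and across the genes of a biological pathway. `methscore` implements
the complementary multi-level analysis: CpGs collapse into **gene scores**
via a variance-component kernel score test, gene scores collapse into
**pathway scores** via a correlated Lancaster p-value combination, and the
self-contained form of the pathway null makes the whole construction
**replicable** in a second, smaller cohort — only genes inside
discovery-significant pathways need to be rescored.

The motivating application is prenatal tobacco-smoke exposure: maternal
plasma cotinine (continuous, zero for most mothers) against newborn cord
blood methylation, adjusted for leukocyte composition, with a categorical
smoking report standing in for cotinine in the replication cohort.

## The gene-level model

For one gene let $G$ be the $n \times k$ matrix of its CpG beta values. The
exposure $y$ is regressed on the adjustment design $X$ (intercept, selected
covariates, forced cell fractions) to give residuals $r$, residual variance
$\hat\sigma^2 = r^\top r/(n-p)$ and hat matrix $H$. The score statistic of
the variance-component test with an unweighted linear kernel $K = GG^\top$
is

$$Q = r^\top G G^\top r,$$

and under the null $Q/\hat\sigma^2 \sim \sum_j \lambda_j \chi^2_1$ with
$\lambda_j$ the eigenvalues of $G^\top (I-H) G$. Orienting the regression
with the exposure as outcome and the CpG matrix in the variant-set role is
deliberate: it is the orientation in which a single null model serves every
gene, and it is why the package fits the null once and reuses its residuals.
Because $(I-H)$ contains the intercept projection, the test is invariant to
column mean shifts of $G$; columns are used raw (no per-CpG weights, no
centering or variance standardization), so a one-CpG gene reduces exactly to
the familiar $\chi^2_1$ score test.

### The mixture tail

The tail probability of $\sum_j \lambda_j \chi^2_1$ is computed by exact
numerical inversion of the characteristic function (the Gil-Pelaez/Imhof
integral), implemented in compiled code as an alternating series of
half-period Gauss-Legendre panels accelerated by iterated averaging. Its
absolute accuracy is limited to roughly $10^{-12}$ by floating-point
cancellation in $\tfrac12 + \pi^{-1}\int$; when the inversion fails to
converge or lands below that resolution, the Liu-Tang-Zhang four-moment
(noncentral chi-square) approximation takes over, and every p-value is
floored at $10^{-16}$. On random spectra the two routes agree to within
about 10% relative error in the main range ($p > 0.05$); near
$p \approx 10^{-4}$ the moment approximation can deviate by ~30% relative,
which is why it is the fallback and not the default. Eigenvalues below
$10^{-10}\lambda_{\max}$ are truncated.

### The permutation null

Pathway combination needs the *joint* null distribution of all gene scores,
with their correlation (shared CpGs, co-methylation) intact. The package
therefore builds a $B \times G$ matrix of null gene p-values: for each of
$B$ permutations (default 1000), one uniform permutation is applied jointly
to the exposure and all covariate rows — methylation untouched — the null
model is refit, and every gene is rescored. Joint shuffling preserves the
exposure–covariate dependence inside the null model while severing all
links to methylation; because the permuted design satisfies
$X_b^\top X_b = X^\top X$, the refit residuals are exactly the permuted
residuals, and only the per-gene eigenvalues need recomputation.

## The pathway-level model

Gene p-values $p_i$ in a set combine by the Lancaster transform
$T = \sum_i F^{-1}_{w_i}(p_i)$, the upper-tail chi-square quantile with
$w_i$ degrees of freedom. The weights are a genuinely open choice — nothing
in the construction dictates them — so the default is the canonical
$w_i = 2$ (making $T$ Fisher's $-2\sum\log p_i$), with an optional
`marker_proportional` scheme ($w_i \propto$ CpG count, normalized to mean
2) for users who want large genes up-weighted.

Under dependence $T$ is *not* $\chi^2_{\sum w_i}$. The identical transform
applied to each row of the permutation matrix (restricted to the same
overlap genes) yields null statistics $T_1,\dots,T_B$ whose first two
moments calibrate a scaled chi-square: with $m = \bar T$ and $v$ the
Bessel-corrected variance,

$$\hat c = \frac{v}{2m}, \qquad \hat f = \frac{2m^2}{v}, \qquad
p = P\!\left(\chi^2_{\hat f} > T_{\rm obs}/\hat c\right).$$

For independent genes at $w_i=2$ this recovers Fisher's tail
($\hat c \to 1$, $\hat f \to 2k$); perfect correlation collapses it to
$\hat f \to 2$, $\hat c \to k$. The moment route (rather than the empirical
rank of $T_{\rm obs}$) extrapolates smoothly beyond $1/B$, which matters
because discovery significance is Bonferroni over thousands of sets.

The null is **self-contained**: a pathway is called when its genes show any
association, against the global null — not against a background gene
competition. That is what allows replication with a small second cohort:
the replication family is exactly the set of testable discovery hits, never
the full collection. Replication uses BH $q < 0.05$ over that family (a
Bonferroni column is reported alongside).

## Thresholds and their defaults

| stage | quantity | default |
|---|---|---|
| per-CpG | Bonferroni family-wise $\alpha$ | 0.05 / CpGs tested |
| covariate screen | BH $q$ | 0.1 |
| gene scores | BH $q$ | 0.25 |
| pathway discovery | Bonferroni-corrected $p$ | 0.05 / sets tested |
| replication | BH $q$ | 0.05 |
| probe QC | missing fraction | 0.10 |
| gene sets | max size | 250 genes |
| permutations | $B$ | 1000 |

The per-CpG threshold uses the number of CpGs actually tested after QC; on
a 450K-scale study this is the familiar $p < 1.06\times10^{-7}$ order of
magnitude, and on 5836 pathway sets the Bonferroni cut is
$8.6\times10^{-6}$. Gene-set inclusion applies four filters: human
organism, at most 250 genes, at least one scored member, and exclusion of
positional (C1), motif (C3) and computational (C4) collections.

Two printed-convention ambiguities are resolved as follows. The
sample-level detection rule removes samples whose **mean detection p-value
is high** (poor signal); the literal low-side reading is available as
`detection_direction = "flag_low"` because published descriptions of this
filter are not always internally consistent. And with an intercept the six
cell fractions are collinear (they sum to 1), so the granulocyte
compartment — the largest — is dropped from design matrices; which
compartment is dropped is configurable and does not change the span.

## The synthetic cohort generator

No real cohort ships with the package, so `generate_cohort()` draws data
with the statistical structure the analysis assumes:

* **Methylation.** Per CpG, a baseline mean beta drawn uniformly (default
  0.2–0.8) is mapped to the logit scale; a one-factor Gaussian copula per
  gene adds latent correlation $\rho$ (default 0.3) between the CpGs of a
  gene; logit-scale noise (SD 0.4) passes through the inverse logit to give
  betas strictly inside $[0,1]$.
* **Exposure.** Zero-inflated continuous: probability of an undetectable
  (zero) value 736/1062 ≈ 0.69, positive part lognormal with mean 191 and
  SD ≈ 199 — the scale of plasma cotinine in ng/ml, with the SD recovered
  from a reported standard error of 11 over 326 detected samples.
  Alternatively a three-category smoking report (none / stopped /
  throughout, probabilities 512/103/70 over 685) encoded as an ordinal dose
  0/1/2 — the kernel test needs one numeric outcome, and the categories are
  dose-ordered.
* **Effects.** `effect_genes` shifts the affected gene's CpGs by
  $\delta \times$ exposure on the beta scale, clipped to
  $[10^{-6}, 1-10^{-6}]$ (keeping logits finite). $\delta$ is *per
  exposure unit*: simulations probing a given beta-scale effect (e.g.
  $\delta = 0.15$) pair it with a unit-scale positive exposure
  (`mean_pos = 1`), since on the raw cotinine scale the same $\delta$
  would saturate the clip. No effect-size scale is empirically anchored;
  $\delta$ is a free simulation parameter.
* **Nuisance.** Dirichlet cell fractions around typical cord-blood means
  (granulocytes ≈ 0.57), candidate covariates (age, education, parity,
  folate, asthma, sex) drawn independently of the exposure, clean QC
  fields, optional missingness. A single master seed fans out to fixed
  per-stage substreams, so cohorts are bit-reproducible.

The generator deliberately does **not** emulate array chemistry (type I/II
probe designs and their intensity distributions), batch structure, probe
cross-reactivity, genomic clustering of CpG effects, or exposure-correlated
cell-composition shifts. Passing calibration and power tests on these
cohorts therefore demonstrates that the statistical machinery is correct
under its stated assumptions — not that a real 450K study would be free of
the normalization and batch artifacts that dedicated preprocessing tools
exist to remove (intra-array normalization and batch correction are
accepted as already done on the input betas).

## Numerical choices

* Missing betas are mean-imputed per CpG **at fit time only** (the stored
  matrix keeps its `NA`s); a complete-case mode exists for the per-CpG
  stage.
* Probe-removal precedence is fixed (control → X → Y → missingness) so QC
  counts are deterministic and sum exactly to the dimension change.
* The p-value clip into $[10^{-16}, 1-10^{-16}]$ before the Lancaster
  quantile keeps the transform finite; a floored gene contributes
  $F^{-1}_2(10^{-16}) \approx 73.7$ to $T$.
* Moment matching uses the Bessel-corrected variance (small-$B$ bias).
* Ward clustering uses the Ward.D2 dialect (squared Euclidean updates) by
  default; the classic Ward.D is available since published method names
  rarely distinguish the two.
* `q`-values at the gene level are plain BH across tested genes; the
  permutation matrix enters only the pathway null. A permutation-aware
  gene-level FDR would be a coherent alternative, but BH is the
  conventional reading of an unqualified "FDR".

## Problem sizes in the test suite

The packaged checks run cohorts of 100–500 samples, 6–1250 genes (up to
5000 CpGs), permutation depths of 80–500 (20,000 for the direct
permutation-vs-analytic comparison of the kernel test), 100–200 replicate
simulations for calibration/power claims, and the bundled analysis
workflow uses 600 + 400 samples with $B = 400$. These sizes were chosen so
the whole suite exercises every asymptotic claim at cohort-realistic $n$
while remaining comfortable to run on a laptop; all of them are plain
function arguments, and the acceptance script rescales the same checks from
a single seed.

## Known limitations

* The kernel test is asymptotic in $n$; no small-sample variance
  adjustment is implemented, and binary outcomes are out of scope.
* Only the unweighted linear kernel is provided (no beta-distribution CpG
  weights, no nonlinear kernels).
* The moment-matched pathway tail assumes the null $T$ distribution is
  well summarized by two moments; extremely heavy correlation plus tiny
  $B$ will strain it (hence `B >= 30` is enforced).
* Genomic-control inflation correction and robust standard errors are not
  implemented at the per-CpG stage.
* Multi-gene CpGs contribute to every annotated gene, so gene scores are
  not independent even under the null — which is precisely why the
  pathway null is permutation-based.
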