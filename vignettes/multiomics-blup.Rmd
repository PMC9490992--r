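---
title: "Multi-omics kernel BLUP: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics kernel BLUP: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection predicts the additive genetic merit (GEBV) of animals
from genome-wide SNP genotypes via a relationship matrix. When a small
subset of a genotyped population also has transcriptome data — the typical
situation, since RNA sequencing of the target tissue is expensive and often
terminal — the question is whether, and how, gene-expression profiles can
be folded into the prediction machinery so that *every* animal benefits,
not only the transcribed ones.

`omixblup` implements a family of five kernel-based BLUP models around one
idea: map each omics layer to an $n \times n$ sample-similarity matrix with
the Cosine kernel, and combine the genomic and transcriptomic matrices
either by convex blending (when everyone is transcribed) or by a
single-step-style hybrid construction (when only a subset is).

## Models

All models share the two-stage structure. Stage one removes fixed effects
by ordinary least squares,

$$y = X\beta + y^{*},$$

where $X$ holds an intercept plus the covariates (in the motivating beef
cattle design: birth year, birth weight, fattening duration and slaughter
batch). Stage two fits the single-random-effect mixed model on the
residuals,

$$y^{*} = Z\gamma + e,\qquad
  \gamma \sim N(0, K\sigma_g^2),\quad e \sim N(0, I\sigma_e^2),$$

with $Z = I$ (one record per animal) and $K$ a relationship matrix.
Heritability is $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$. The models
differ only in $K$:

* **GBLUP** — genomic kernel over all samples. Either VanRaden's
  $G = ZZ'/(2\sum_i p_i(1-p_i))$ from centered dosages (the default
  benchmark) or the Cosine kernel of raw dosages.
* **TBLUP** — Cosine kernel $T$ of the raw FPKM expression profiles.
* **MBLUP** — $M = \mathrm{ratio}\cdot G + (1-\mathrm{ratio})\cdot T$, a
  convex blend; requires expression for all samples. `ratio = 1` is
  cosine-GBLUP, `ratio = 0` is TBLUP.
* **mssBLUP** — the hybrid $H_m$ that embeds $T$ (built on the transcribed
  block, indexed 2) into the genome-wide $G$:
  $$H_{m,22} = T,\quad H_{m,12} = G_{12}G_{22}^{-1}T,\quad
    H_{m,11} = G_{11} + G_{12}G_{22}^{-1}(T - G_{22})G_{22}^{-1}G_{21},$$
  with the closed-form inverse
  $$H_m^{-1} = G^{-1} +
    \begin{bmatrix} 0 & 0 \\ 0 & T^{-1} - G_{22}^{-1} \end{bmatrix}.$$
* **wmssBLUP** — the same construction with
  $T_w = (1-w)T + wG_{22}$ in place of $T$; $w$ is the proportion of
  genetic relationships not explained by expression, and $w = 1$ reduces
  the model to GBLUP on the cosine kernel exactly.

The $H_{m,11}$ block deserves a note. Published block displays of this
family are not always internally consistent; the form above is the unique
one that (i) agrees with the closed-form inverse, and (ii) satisfies the
sanity check $T = G_{22} \Rightarrow H_m = G$. The test suite verifies
both properties on random instances, and `build_hybrid()` short-circuits
to `G` bitwise when `T == G22`. Similarly, with $T$ occupying the (2,2)
block, the transcribed animals must be block 2; `align_samples()`
therefore orders non-transcribed samples first, transcribed last, and the
hybrid constructors enforce that convention.

## The Cosine kernel and its regularization

$$K(x_i, x_j) = \frac{\langle x_i, x_j\rangle}{\lVert x_i\rVert\,
  \lVert x_j\rVert}$$

applied to raw 0/1/2 dosage vectors (genomic layer) or raw FPKM profiles
(transcriptomic layer). Per-sample normalization makes the kernel
scale-invariant in each sample's feature vector; the pre-regularization
matrix is a Gram matrix of unit vectors, hence PSD with unit diagonal.
A diagonal regularization $K + C I$ with default $C = 0.05$ (a
grid-searched value in the work this builds on) is added to every cosine
kernel. The placement of $C$ as additive jitter is a design choice of this
package: it guarantees the invertibility of $G$, $G_{22}$ and $T_w$ that
the hybrid formulas require, while leaving off-diagonal similarities
untouched. Expression features may optionally be `log1p`-transformed
before kernelization; this is off by default since the raw-FPKM kernel is
the reference behavior.

Missing genotype calls are preserved in storage and mean-imputed
(to $2p_i$) only when a kernel is built, keeping allele-frequency
expectations intact.

## Quality control

`filter_snps()` mirrors PLINK-era semantics with strict inequalities:
samples with missing rate $> 10\%$ first, then markers with call rate
$< 90\%$, MAF $< 0.05$ (computed on non-missing calls after sample
removal), or Hardy–Weinberg $\chi^2$ p-value $< 10^{-6}$. Boundary values
survive: a marker at MAF exactly 0.05 is retained. The HWE test is the
asymptotic one-degree-of-freedom chi-square against $(p^2, 2pq, q^2)$;
at a $10^{-6}$ threshold the difference from the exact test is immaterial
for the marker counts involved, and monomorphic markers return $p = 1$ by
convention. `filter_genes()` discards a gene iff its FPKM is below 0.1 in
strictly more than 95% of samples — low in *exactly* 95% is kept. Both
filters are idempotent, and each removed feature is attributed to exactly
one rule (call rate, then MAF, then HWE) in the report.

## REML

Variance components are estimated by restricted maximum likelihood with a
single intercept as the fixed effect (the input $y^{*}$ is already
OLS-adjusted, so the intercept is essentially zero; keeping it makes the
restricted likelihood well-defined). Writing $\delta = \sigma_e^2 /
\sigma_g^2$, the restricted likelihood is profiled on the spectrum of the
intercept-projected kernel $SKS$: one eigendecomposition, then a 1-D
search over $\log\delta$ (61-point log-spaced bracket on $[-12, 12]$
followed by Brent refinement to $10^{-8}$). Standard errors come from the
inverse REML Fisher information, with the SE of $h^2$ by the delta
method. Estimates at the boundary ($h^2 \to 0$ or $1$, or $\log\delta$ at
the search limits) are *flagged*, not errored, and their SEs are omitted
because the asymptotics do not hold there. A kernel whose projected
spectrum is flat (e.g. $K = I$) makes $\sigma_g^2$ and $\sigma_e^2$
unidentifiable and is rejected explicitly.

Two caveats are documented rather than hidden. First, the two-stage
scheme (OLS adjustment, then REML on residuals) follows the reference
workflow exactly; it induces a small downward bias in $\sigma_e^2$
relative to a joint fixed-plus-random REML because the residuals have
already lost the fixed-effect degrees of freedom. Second, when the same
eigendecomposition is reused across many traits or simulation replicates
(`reml_eigen()`), the cache is only valid for the identical sample set
and order.

## Cross-validation and experiment drivers

Accuracy is always the Pearson correlation $r(y^{*}, \mathrm{GEBV})$ on
held-out samples. Two schemes:

* **LOO** for small, fully transcribed sets: each sample predicted from
  the other $n-1$; accuracy is the single correlation over all $n$
  held-out predictions. Variance components are fitted once on the full
  data by default (`refit-per-fold` is available and is tested against a
  naive per-sample loop).
* **Replicated k-fold** (default $5\times 5$, giving 25 fold-level
  correlations) for the full population; folds are seed-deterministic
  random partitions with sizes differing by at most one, variance
  components are refitted on each fold's training set, and the summary is
  the mean of the 25 fold correlations (not a pooled correlation).

`grid_search_ratio()` sweeps the MBLUP blend over 0.01–0.99 in steps of
0.01 (99 points; the step is this package's reading of the printed grid
range) under LOO; `grid_search_w()` sweeps $w$ over 0–1 in steps of 0.1
(11 points; reported optima in this model family are expressed at that
resolution) under k-fold CV with a shared seed, so the $w = 1$ column is
exactly the cosine-GBLUP accuracy under identical folds. Grid argmax ties
break toward the smaller parameter for determinism.

`proportion_experiment()` reproduces the transcribed-proportion design:
random subsets of the genotype-only pool of growing size are combined with
the always-included transcribed block; wmssBLUP and the GBLUP benchmark
are scored on each reduced population with shared folds, and both the
absolute and the relative (percent) improvement are reported, since
published "average improvement" figures are ambiguous between the two.
Kernels are built once on the full population and indexed per subset —
allele frequencies and cosine normalizations come from the whole panel,
as when a production relationship matrix is computed once and subset
during validation. The default sizes are 7 evenly spaced values from 25%
to 100% of the pool, a desk-scale analogue (with a wider transcribed
fraction range) of the 600–1320-of-1358 design that motivates the driver.

## The simulator

`make_study_bundle()` emulates the motivating study's structure at desk
scale: a genotyped population (default $n = 300$, standing in for 1478)
of which a small random subset (default 60, standing in for 120) is
transcribed; markers (default $m = 2000$) in linkage equilibrium and
Hardy–Weinberg proportions with allele frequencies uniform on
$[0.05, 0.5]$; expression (default $g = 500$ genes) with log-normal
abundances under partial cis-genetic control (default `expr_h2 = 0.5`,
3 cis markers per gene); and a phenotype with low heritability (default
$h^2 = 0.2$, at the top of the 0.06–0.18 range typical of the carcass
traits this design emulates) whose genetic value is an even split
(default `mediation_share = 0.5`) between a direct polygenic part and a
part acting through the genetic components of transcript abundance. The
mediated part is a random linear combination of the *FPKM-scale* genetic
expression values, so highly expressed genes carry proportionally more
weight — the same weighting an abundance-based kernel sees, reflecting a
trait that responds to absolute transcript abundance. Four fixed-effect
covariates with known coefficients (two categorical, two continuous) are
planted so the adjustment stage is genuinely exercised.

What the simulator deliberately does **not** model: linkage
disequilibrium and demography (markers are independent; every formula is
still fully exercised), trans-regulatory co-expression modules,
tissue/time dependence of expression, shared environmental covariance
between the measured trait and the transcriptome of the measured tissue,
and read-level RNA-seq artifacts. Passing tests on these bundles
therefore demonstrate the correctness and the qualitative behavior of the
machinery — not the accuracy levels attainable on real cattle data, where
LD, co-expression structure and trait–tissue environmental covariance can
make the transcriptomic kernel substantially more (or less) informative.

Every generator is a pure function of its parameters and seed; a single
pipeline seed fans out into fixed per-stage sub-seeds.

## Numerical choices and degenerate inputs

* Relationship matrices are symmetrized as $(K + K')/2$ on construction
  and must be symmetric to $10^{-8}$ on input.
* Cosine values are clamped to $[-1, 1]$ against floating-point overshoot
  before the jitter is added; zero-norm feature rows are an error naming
  the sample.
* Fixed markers (allele frequency 0 or 1) are rejected by
  `allele_frequencies()` with a pointer to QC rather than silently
  dropped, because their handling belongs to the QC policy, not to the
  kernel.
* `blup_predict()` solves $(K_{tt} + \delta I)\alpha = y^{*}_t$ directly;
  at $\delta = 0$ with a rank-deficient training block this fails with a
  suggestion to add jitter. $\sigma_g^2 = 0$ returns all-zero GEBVs.
* LOO on a signal-free kernel is biased toward *negative* correlations
  (each held-out prediction is anchored on a training mean that excludes
  the held-out value); tests of null behavior therefore bound the
  accuracy from above instead of asserting symmetry around zero.
* Grid argmax ties break toward the smaller parameter; fold assignment,
  subsampling and all simulation are reproducible bitwise from seeds.

## Problem sizes used by the test-suite and acceptance runs

Module tests run on bundles of 12–200 samples and a few hundred markers.
The deeper scientific checks use: REML recovery at $n = 500$, $m = 2000$,
200 replicates per heritability in $\{0.1, 0.3, 0.5\}$; hybrid-algebra
identities on 50 random instances up to $n = 40$; and the directional
multi-omics comparison on 20 independent bundles at the default study
scale ($300/60$ with $m = 2000$, $g = 500$). These sizes were chosen so
the whole suite completes in minutes on one CPU while keeping Monte Carlo
error well inside the asserted bounds.

## Known limitations

* The cosine kernel on raw FPKM is dominated by high-abundance genes; a
  trait mediated by low-abundance transcripts will be nearly invisible to
  TBLUP/mssBLUP under this kernel. The optional `log1p` transform
  mitigates this at the cost of departing from the reference behavior.
* Two-stage adjustment, single trait, identity incidence: no repeated
  records, no multi-trait models, no dominance/epistasis, no pedigree
  matrix.
* The REML SEs are asymptotic; at desk-scale $n$ they are indicative
  only, and they are omitted at boundary estimates.
* Whether the original GBLUP benchmark of the motivating design used the
  VanRaden or the cosine genomic kernel is ambiguous; both are available,
  VanRaden being the default benchmark, and reduction identities
  (`wmssBLUP(w = 1)`, `MBLUP(ratio = 1)`) hold against the cosine form.
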