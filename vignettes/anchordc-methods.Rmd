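---
title: "Anchor-gene differential co-expression: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene differential co-expression: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchordc)
```

This vignette documents the statistical models behind `anchordc`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design decisions taken where the
methodology left genuine choices open.

## The analysis model

### Purity-adjusted co-expression

Bulk tumor expression mixes tumor and non-tumor cells, and the tumor
cell fraction (purity) loads on essentially every transcript. Two genes
that both track purity therefore correlate marginally without any
biological co-regulation. All anchor correlations in this package are
partial Pearson correlations controlling for a single purity covariate
$u$:

$$ r_{ga \mid u} = \frac{r_{ga} - r_{gu}\,r_{au}}
  {\sqrt{(1 - r_{gu}^2)(1 - r_{au}^2)}}. $$

This closed form is algebraically identical to regressing both
variables on intercept + $u$ (ordinary least squares) and correlating
the residuals, **provided both are computed on the same sample set**.
With missing protein values we therefore define the estimate per gene
pair on the pairwise-complete samples of (gene, anchor, purity), and
record that count as `n_used`. Missing values are never imputed —
imputation would manufacture correlation structure, which is the very
quantity under study. The test of $H_0: r_{ga\mid u} = 0$ uses
$t = r\sqrt{(n-3)/(1-r^2)}$ with $n - 2 - k$ degrees of freedom and
$k = 1$ covariate. Correlations undefined because of zero variance
propagate as missing and are excluded from the Benjamini–Hochberg
adjustment, which otherwise runs over the whole scan.

### Differential correlation between outcome groups

For each gene the anchor correlation is computed separately within the
platinum-sensitive and platinum-resistant groups (purity
residualization is performed *within* group) and compared on the
Fisher z scale:

$$ z_{\mathrm{diff}} = \frac{\operatorname{atanh} r_1 -
   \operatorname{atanh} r_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}}. $$

Significance is assessed by permutation of the outcome labels. Each
permutation keeps every sample's expression and purity attached (so the
confounding structure is preserved under the null) and recomputes the
within-group residualization before the per-gene $|z_{\mathrm{diff}}|$.
One shared set of permuted label vectors serves all genes; the
empirical p-value per gene is

$$ p = \frac{1 + \#\{\,|z^{*}| \ge |z_{\mathrm{obs}}|\,\}}{1 + B}, $$

with $B$ permutations. The add-one correction keeps p-values strictly
positive; ties are counted with $\ge$, the conservative direction. When
the number of distinct label assignments $\binom{n}{n_1}$ does not
exceed the permutation budget, the implementation switches to exhaustive
enumeration and reports the exact p-value
$\#\{|z^{*}| \ge |z_{\mathrm{obs}}|\}/N$ with the observed assignment
included among the $N$; the two conventions agree, and the test suite
verifies exactness against an independent enumeration oracle. Groups
need at least 4 samples for the statistic (the z variance needs
$n > 3$); the scan functions require 5 per group as a practical floor.

Each gene receives a sign-pair class label "s/r" from its per-group
correlations at level $\alpha$ (default 0.05): e.g. `+/0` means
significantly positive in sensitive tumors, not significant in
resistant tumors. The *exclusive networks* collect genes with
permutation p below $\alpha$ **and** a single-group class (`+/0`,
`-/0` versus `0/+`, `0/-`). Requiring both conditions is deliberate:
the permutation p alone flags any change in correlation (including
sign flips significant in both groups), while the class pattern alone
ignores whether the difference itself is surprising.

### The modifier-gene screen

Whether the anchor's association with treatment response depends on
another gene is asked directly with an interaction model per gene $g$:

$$ \operatorname{logit} P(\text{resistant}) =
   \beta_0 + \beta_a a + \beta_g g + \beta_{\mathrm{int}}(a \cdot g)
   + \boldsymbol{\gamma}^\top \mathbf{c}, $$

with covariates $\mathbf{c}$ defaulting to purity, residual disease and
molecular subtype — the same adjustment set as the response-to-therapy
model of the anchor itself; a flag changes it. Two flagging rules are
provided, a p-value threshold (default $p < 0.02$) and a top-fraction
rule (e.g. the smallest 1% of interaction p-values); they describe the
same kind of cut and the threshold rule is the default. A flagged
modifier is *negative* when $\operatorname{sign}(\beta_{\mathrm{int}})
\neq \operatorname{sign}(\beta_a)$ in its own model — the interaction
pulls the anchor's effect toward zero, i.e. attenuates its prognostic
significance — and *positive* otherwise. This sign-opposition rule is
an explicit operationalization of "decreasing/increasing the
prognostic significance"; it reduces to the intuitive cases and is
testable. Wald p-values are used throughout (a likelihood-ratio variant
would be a drop-in change); gene fits that fail to converge are
recorded as missing, excluded from flagging, and counted.

### Planar filtered network and modules

Significant differentially correlated pairs are assembled into a planar
filtered network: edges are sorted by ascending p (ties: descending
$|z_{\mathrm{diff}}|$, then lexicographic pair) and inserted greedily,
keeping an edge only if the graph remains planar. Planarity is decided
by the left–right criterion, implemented iteratively in R and validated
against an independent planarity oracle on random graphs;
the $|E| \le 3|V| - 6$ bound is additionally enforced per component as
a cheap rejection. The full multiscale embedding machinery of published
planar-network module tools is deliberately simplified here: modules
are found by recursive bipartition of each connected component using
the leading eigenvector of the component's modularity matrix, stopping
when the modularity gain is non-positive or the component is smaller
than `min_size` (default 10). Labels encode the split path
(`"2.1.2"`), giving a hierarchy without the original tools' embedding
and significance permutations. The sign of the leading eigenvector is
fixed deterministically and split ties are resolved by node order, so
module assignment is reproducible.

### Clinical association layer

Group comparisons use the Wilcoxon rank-sum test (normal approximation
with tie correction and no continuity correction, so identical groups
give exactly p = 1), Welch t-tests, or Pearson chi-square without the
Yates correction (matching the textbook $\sum (O-E)^2/E$). Response
models are maximum-likelihood logistic fits with Wald 95% CIs; perfect
separation is detected (vanishing deviance with saturated fitted
probabilities) and raised as an error rather than reported as an
absurd odds ratio. Survival uses Cox partial likelihood with Efron tie
handling. Forward stepwise selection adds, at each step, the candidate
with the smallest Wald p among those below the entrance criterion
(default 0.10), breaking ties by candidate order. Stratified analyses
fit the full feature × stratum interaction model (two-sided Wald
p, invariant to reference recoding) alongside per-stratum models. The
cytolytic activity metric is
$\sqrt{(\mathrm{GZMA}+\delta)(\mathrm{PRF1}+\delta)}$ with
$\delta = 0.01$, a small offset keeping the geometric mean defined at
zero expression.

### Expression preprocessing

FPKM is computed as $10^9 c_{gs} / (L_g N_s)$ with the naive
total-count library size by default; an option accepts external size
factors (e.g. median-of-ratios), replacing $N_s$ by
$\mathrm{sf}_s \times \overline{N}$, for workflows whose FPKM derives
from size-factor-normalized counts. The abundance filter keeps genes
whose median expression strictly exceeds a quantile (default the 30th
percentile) of the per-gene median distribution; the quantile uses
linear interpolation between order statistics (type 7), the common
default, since no convention is canonical. The filter is applied to
whatever layer is passed — FPKM by default in the pipeline, log2 if the
user prefers, as the ranking of medians differs only through the
monotone transform's interaction with the interpolated cut. Protein
matrices are filtered by quantification rate with an inclusive bound
(a gene observed in exactly 30% of samples is kept). The log2
transform uses offset 1.0.

### H-scores

The immunohistochemistry H-score of a core is
$\sum_{i \in \{1,2,3\}} i \cdot 100 \cdot \text{count}_i / \text{total}$,
bounded in [0, 300]; cores of a sample are averaged. The same weighted
formula serves manual and digital (algorithm-derived) bins — it reduces
to the classical "percentage × intensity" product when a single
positive bin is occupied, and the well-known scale difference between
manual and digital scores is a property of the data, not the formula,
so no rescaling is applied.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
at the scale of the motivating cohort: 336 samples with a 29% resistant
fraction, a latent tumor purity drawn from Beta(5, 2) (mean 0.71),
an anchor mRNA–protein cross-layer correlation of 0.29, 30% protein
missingness, and a desk-scale default of 2,000 genes.

* **Differential-correlation cohorts.** Group labels first; anchor
  standard normal; a gene planted in a group-specific set follows
  $r \cdot a + \sqrt{1 - r^2}\,\varepsilon$ (default $r = 0.4$) within
  its active group and independent noise in the other. Purity is then
  added to *every* gene (anchor included) with gene-specific Gaussian
  loadings (sd 0.5), the simplest mechanism that biases marginal
  correlations while leaving partial correlations unbiased — asserted
  as a property test.
* **Modifier cohorts.** Expression first, then the outcome from the
  logistic model with the anchor main effect (−0.5) and planted
  interactions. The planted modifiers are generated as readouts of one
  latent co-expression program (pairwise correlation 0.8, one shared
  interaction sign of +1.5, opposite to the anchor effect, hence an
  attenuating program). This choice is deliberate: ten mutually
  independent strong interactions acting simultaneously in one outcome
  would mask each other — each single-gene fit would face logit-scale
  omitted-variable noise several units wide — whereas empirical
  modifier genes travel in correlated regulatory modules and
  predominantly share the attenuating direction, the way
  chromatin-remodeling partners of an anchor tend to be co-expressed.
  The intercept $\beta_0$ is calibrated
  numerically so that the mean resistance probability equals the
  configured fraction, making the realized resistant fraction a tested
  calibration target rather than an accident of the coefficients.
* **Protein layer.** Each protein is a scaled copy of its transcript
  plus unit Gaussian noise; the per-gene scale is solved so the
  expected cross-layer correlation equals the target (0.29), and
  missingness is completely at random at the configured rate.
* **IHC tables.** A true H-score per sample from Beta(2, 2) scaled to
  [0, 300] (median 150, matching the scale of manual scoring); per-core
  multinomial bin counts whose expected H-score equals the truth —
  below H = 200 the three positive bins share mass equally, above it
  the zero bin empties and mass shifts to 3+, a continuous scheme that
  reaches "all cells 3+" exactly at H = 300.
* **Survival.** Weibull baseline (shape 1.5, scale 60 months, median
  ≈ 4.1 years) with a resistant-vs-sensitive hazard ratio of 3.3 and
  independent uniform censoring on 24–120 months.

Every generator is deterministic given its seed, restores the caller's
RNG state, and returns a truth ledger (planted roles, modifier
coefficients, purity, loadings) that recovery tests consume without
re-reading the configuration.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: RNA-seq count noise (values are Gaussian
on the log scale; no negative-binomial layer), informative protein
missingness (real proteomics is missing-not-at-random at low
abundance), batch structure, correlated null genes (pathway
co-expression among non-planted genes), non-linear purity effects, and
annotation noise in outcome labels. Recovery rates on synthetic cohorts
are therefore upper bounds on what identical settings would achieve on
real cohorts.

## Numerical choices and degenerate inputs

* Pairwise moments are accumulated with masked matrix products, so
  scans are vectorized over genes including under missingness; results
  match per-pair `lm` residualization to ~1e-10.
* Correlations of magnitude exactly 1 are clamped by machine epsilon
  only where the Fisher transform would overflow inside permutation
  machinery; the exported `fisher_z`/`diffcorr_zstat` enforce their
  $|r| < 1$, $n > 3$ domains instead.
* Zero-variance rows, constant covariates, empty groups, zero library
  sizes, absent anchors, perfect separation and no-event survival data
  all raise typed, early errors; the all-genes-filtered case warns and
  returns an empty matrix since downstream code can handle it.
* Problem sizes in the test and acceptance suites (500–2,000 genes,
  60–200 samples per group, 200–1,000 permutations) are chosen as the
  smallest scales at which the calibration and recovery properties are
  statistically sharp; they are the package's own desk-scale choice and
  run in minutes.

## Known limitations

Anchor-centric only (no all-pairs differential correlation); module
detection is a simplification of multiscale planar-network clustering;
gene-set testing is unconditional (no ontology-hierarchy conditioning);
no penalized models, time-dependent covariates or competing risks; the
permutation scheme assumes exchangeability of outcome labels given the
preserved per-sample covariates.
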