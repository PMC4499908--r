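---
title: "Partitioning genomic variance by gene sets: model, null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning genomic variance by gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Complex traits are influenced by many variants of small effect scattered
across the genome. Given dense SNP genotypes, a phenotype, and a gene set
(say, a KEGG pathway), one can ask: do the markers *inside* that gene set
account for more of the genomic variance than an arbitrary collection of
genes of the same size would? This is a *competitive* question — the
comparison is against random gene sets, not against zero — and it is the
question `pathpart` is built to answer.

## The two-component linear mixed model

Markers are split into a set $\mathcal{S}$ (the markers falling inside the
genes of the pathway, counted once per pathway) and its complement
$\neg\mathcal{S}$. The phenotype model is

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{g}_{\mathcal{S}} +
  \mathbf{g}_{\neg\mathcal{S}} + \mathbf{e},$$

with $\mathbf{g}_{\mathcal{S}} \sim N(\mathbf{0},
\mathbf{G}_{\mathcal{S}}\sigma^2_{\mathcal{S}})$,
$\mathbf{g}_{\neg\mathcal{S}} \sim N(\mathbf{0},
\mathbf{G}_{\neg\mathcal{S}}\sigma^2_{\neg\mathcal{S}})$ and
$\mathbf{e} \sim N(\mathbf{0}, \mathbf{D}\sigma^2_e)$. Each genomic
relationship matrix is $\mathbf{G}_{\mathcal{S}} =
\mathbf{W}_{\mathcal{S}}\mathbf{W}_{\mathcal{S}}'/m_{\mathcal{S}}$ on
centered, per-marker-standardized dosages
$W_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$.

The per-marker standardization is a deliberate choice: with it, the
all-marker GRM decomposes *exactly* as

$$\mathbf{G} = \frac{m_{\mathcal{S}}\,\mathbf{G}_{\mathcal{S}} +
  m_{\neg\mathcal{S}}\,\mathbf{G}_{\neg\mathcal{S}}}{m},$$

so the one-component ("simple") model $\mathbf{y} = \mathbf{1}\mu +
\mathbf{g} + \mathbf{e}$, $\mathbf{g} \sim N(\mathbf{0},
\mathbf{G}\sigma^2_g)$, is nested inside the two-component model via the
parameter mapping $(\sigma^2_{\mathcal{S}}, \sigma^2_{\neg\mathcal{S}}) =
(\sigma^2_g m_{\mathcal{S}}/m,\; \sigma^2_g m_{\neg\mathcal{S}}/m)$. A
global denominator $\sum_j 2p_j(1-p_j)$ would break this identity, which
is why it is not offered. `verify_partition_identity()` checks the
decomposition to 1e-8 and is exercised over random partitions in the test
suite.

The null hypothesis is therefore *not* $\sigma^2_{\mathcal{S}} = 0$; it is
that the set explains its marker share $m_{\mathcal{S}}/m$ of the genomic
variance (`expected_h2()`). The statistic of interest is

$$H^2_{\text{set}} = \frac{\sigma^2_{\mathcal{S}}}
  {\sigma^2_{\mathcal{S}} + \sigma^2_{\neg\mathcal{S}}},$$

together with the REML likelihood ratio between the two models.

### Residual weights

Deregressed-proof records carry reliabilities $r$. The stored weight is
$w = r^2/(1-r^2)$ and the residual covariance contribution is
$\sigma^2_e\,\mathrm{diag}(1/w)$: reliable records get small residual
variance. This is the standard weighted-analysis convention and the one
the synthetic generator uses; with no reliabilities, $\mathbf{D}$ is the
identity and both readings coincide. A reliability floor (default 0.01)
keeps the weights positive and finite.

## Estimation: AI-REML with guarded ascent

Variance components are estimated by restricted maximum likelihood with
intercept-only fixed effects; because both models share that fixed
structure, their REML likelihoods are directly comparable in a likelihood
ratio. The optimizer uses average-information (AI) updates with:

* **step halving** (1, 1/2, 1/4, 1/10 of the AI step) when a full step
  would leave the admissible region or decrease the likelihood;
* **EM-REML fallback** when no AI fraction ascends — EM steps are ascent
  steps by construction;
* **boundary kicks**: a component parked at the zero boundary whose
  gradient points inward is probed at a few interior values
  ($10^{-2}$–$10^{-4}\,V_p$) and moved only if the likelihood improves.
  Without this, the zero boundary is an absorbing state for EM;
* a boundary clamp at $\varepsilon = 10^{-10}\,V_p$, convergence when the
  relative log-likelihood change is below $10^{-8}$ or the
  Karush-Kuhn-Tucker condition holds (gradient below $10^{-6}$ for
  interior components, non-positive for boundary components), and a cap
  of 100 iterations;
* a final quasi-Newton polish (L-BFGS-B on log-variances with analytic
  gradients) when the main loop stalls or runs out of iterations without
  meeting the KKT condition — this rescues the occasional slow crawl
  along a near-boundary ridge, and is itself accepted only if it does
  not decrease the likelihood.

Starting values follow the null hypothesis. When the simple-model fit is
available — the pipeline computes it once per trait, since it does not
depend on the set — the partitioned fit starts at the simple fit's image
under the nested mapping. Combined with ascent-only steps this makes the
likelihood ratio non-negative *by construction* rather than by hope; small
negatives (above $-10^{-4}$, numerical noise) are truncated to zero and
anything worse is flagged. When no simple fit is supplied, the start is
$\sigma^2_e = 0.5\,V_p$ with $0.5\,V_p$ of genetic variance split across
components in proportion to marker counts — the same null logic.

The test suite checks the optimizer against a brute-force grid-plus-polish
maximizer of the same restricted likelihood on small instances, against
the closed-form i.i.d. Gaussian REML likelihood, and for translation
invariance and $c^2$ scale equivariance.

### Fit quality control

AI-REML occasionally converges to a meaningless point. A fit is flagged
and excluded from downstream empirical-distribution fitting when:

* the residual variance or the **total** genetic variance collapses below
  $10^{-6}\,V_p$ (`near_zero_component`). A *single* genetic component at
  its zero boundary is deliberately not flagged: under the competitive
  null, $\hat\sigma^2_{\mathcal{S}} = 0$ is an ordinary outcome for small
  groups and such fits are legitimate data points with
  $H^2_{\text{set}} = 0$;
* the summed variance components exceed $4 V_p$ (`variance_inflation`);
* the likelihood ratio is materially negative (`negative_lr`);
* the optimizer did not converge (tracked on the fit itself).

## The competitive empirical null

Random gene groups emulate "what would a pathway of this size look like if
biology played no role": a target marker count is drawn uniformly from 1
to `max_target`, then genes with at least one mapped marker are sampled
uniformly without replacement until the union of unique markers first
reaches the target. The group inherits every property that makes gene
sets awkward — LD within genes, heterogeneous gene sizes, markers shared
between overlapping genes — without modelling any of it explicitly. Each
group is fitted with the two-component model and contributes
(size, $H^2_{\text{set}}$, LR, focal flag) to the null table. Group
sampling is driven by per-group child seeds derived deterministically
from the master seed, so batches are bit-for-bit reproducible and
order-independent.

### Threshold curves

The 50th and 95th percentiles of LR and $H^2_{\text{set}}$ as functions of
group size are estimated by *monotone quantile regression*: the
non-decreasing function minimizing pinball loss, computed exactly by
pooled adjacent violators with weighted-quantile block solutions, with
piecewise-linear interpolation between knots and clamping outside the
observed size range. Monotonicity is the scientifically load-bearing
constraint — larger groups cannot be expected to explain less. An
optional Gaussian-kernel smoothing pass (monotonicity restored by a
running maximum) is controlled by a bandwidth chosen by 5-fold
cross-validated pinball loss by default; the raw isotonic fit
(`lambda = 0`) is always available. The PAVA solver is verified in the
tests against a dynamic-programming enumeration oracle.

A pathway is called on the dual criterion: its LR reaches the
size-adjusted 95th-percentile LR curve (better fit than 95 % of random
groups) *and* its $H^2_{\text{set}}$ reaches the matching explained-
variance curve. Both comparisons are inclusive. When a focal gene is
configured the curves are fitted separately for focal-containing and
focal-free groups (each stratum needs at least 50 clean groups, otherwise
a single pooled stratum is used), and each pathway is compared against
the curve of its own stratum; unstratified behaviour is available by
switching `stratify_focal` off.

### Reference distribution and FDR

For a classical test alongside the empirical criteria, the zero-truncated
null LR values are compared against $\chi^2_1$, $\chi^2_2$ and an
equal-weight mixture of the two by Kolmogorov-Smirnov distance (the
mixture weight is configurable; equal weights are the neutral choice in
the absence of a stated alternative). Ties break toward the lower df.
Pathway p-values are upper-tail probabilities under the selected
reference (LR of exactly zero maps to $p = 1$) and are adjusted by
Benjamini-Hochberg, with significance called at 10 % FDR by default.

## The synthetic generator

The real data this method was designed for — dense bull genotypes with
deregressed proofs — are not distributable, so the package ships a
generator that reproduces the *statistical structure* the method relies
on, at desk scale. Defaults, chosen once:

| quantity | default | rationale |
|---|---|---|
| individuals / markers | 500 / 5000 | large enough for stable REML, small enough for hundreds of fits in minutes |
| chromosomes, LD | 5; blocks of 10 markers, latent $\rho = 0.5$ | block-equicorrelated latent Gaussians thresholded to Hardy-Weinberg genotypes |
| allele frequencies | U(0.05, 0.95) | post-MAF-filter spectrum |
| genes | ~300, covering 40 % of markers | mirrors the ~39 % in-gene fraction of a dense cattle panel |
| pathways | 20, 3–60 genes, log-uniform | heterogeneous sizes, genome-scattered |
| heritability | 0.3 | mid-range production/health trait |
| reliabilities | Beta(9, 1) in [0.05, 0.99] | proven-bull DRP scale, mean ≈ 0.9 |
| random-group `max_target` | 20 % of mapped markers | same ratio of maximum target to mapped markers as a dense-panel analysis |
| focal locus | one marker carrying 30 % of genetic variance | a DGAT1-scale effect for fat-yield-like traits |

Trait architectures: `infinitesimal_null` (every marker
$\sigma^2_g/m$ — the competitive null), `pathway_enriched` (a designated
set carries a share $\rho_S$ of the genetic variance; $\rho_S = m_S/m$
degenerates to the null), and `focal_locus`. In the focal scenario the
synthetic neighbourhood window used to flag focal groups is best matched
to the simulated LD range (one 10-kb block) rather than the 500-kb
default that reflects the long-range LD of real cattle genomes — with
block LD there is simply no signal beyond one block, and a wider window
would dilute the focal stratum with unaffected genes.

What the generator does **not** emulate: pedigree/family structure and
selection (in real data the all-marker GRM absorbs much of this),
long-range LD and LD decay within blocks, imputation error, multi-trait
correlations, and non-Gaussian residuals. Passing tests on synthetic data
therefore demonstrate the estimator's and the null procedure's internal
correctness and calibration under the assumed structure — not robustness
to every property of real livestock data.

## Numerical and degenerate-input choices

* MAF filtering is strict (`> threshold`); a marker at exactly 0.01 is
  removed. The boundary behaviour is configurable via the threshold.
* Coordinates are 1-based, fully closed, GFF3-style; the marker-in-gene
  rule is inclusive at both ends, ignores strand, and admits a marker
  into several overlapping genes; within one pathway a marker counts
  once. The gene-side `flank` defaults to 0 (inside-gene only).
* The focal neighbourhood is interval-overlap against the focal gene's
  padded interval (gap-based, not midpoint distance).
* Random-group sampling stops at the first crossing (union ≥ target);
  with gene sizes of many markers, "≥" versus ">" is immaterial, and the
  minimality of the stopping gene is tested.
* Degenerate threshold-curve inputs (all-equal statistics) yield a
  constant curve; curves require at least 50 clean samples per stratum.
* An all-zero LR sample refuses reference selection rather than
  silently choosing.
* Complement GRMs are formed through the exact partition identity
  $(m\mathbf{G} - m_{\mathcal{S}}\mathbf{G}_{\mathcal{S}})/
  m_{\neg\mathcal{S}}$, which is both faster than rebuilding from the
  marker matrix and exact by construction.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run the full machinery at
n = 500 individuals and m = 5000 markers: 800 random gene groups for
calibration (400 to fit the 95th-percentile LR curve, 400 held out to
measure its coverage), 25 replicates per true value for
explained-variance recovery at $H^2_{\text{set}} \in \{0.1, 0.3, 0.5\}$,
and 200 groups for the focal-locus contrast. These sizes give stable
medians and coverage estimates while keeping a full run in the
minutes range on a single core.

## Known limitations

* Single trait, intercept-only fixed effects, two genetic components;
  multi-trait models and additional fixed effects are out of scope.
* No BLUP backsolving to marker or individual effects — the package
  quantifies variance, it does not predict.
* Positional marker-to-gene assignment only; no LD-aware or
  eQTL-informed mapping.
* Dense GRMs: memory and time scale with $n^2$; the package targets
  thousands of individuals, not hundreds of thousands.
* The empirical null is trait-specific and must be re-sampled per trait;
  thresholds are not transferable.
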