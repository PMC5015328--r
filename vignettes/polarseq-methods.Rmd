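---
title: "Methods: models, rules and design choices in polarseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in polarseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarseq)
```

`polarseq` analyses a bulk RNA-seq time course sampled on the two sides of
a bisected animal: the oral half and the physal (aboral) half, each
regenerating the missing end. The canonical design is 2 sides × 4 time
points (0, 8, 24, 72 h post-amputation) × 2 replicates = 16 libraries.
This vignette documents the statistical models, the decision rules, the
tunable parameters, and the choices made where the design was genuinely
open.

## 1. Normalization

Size factors use the classical median-of-ratios estimator: for sample $j$,
$s_j = \mathrm{median}_i\, K_{ij} / (\prod_v K_{iv})^{1/m}$, with the
median over genes that have strictly positive counts in every sample and
no pseudocount. The estimator is defined only when at least one such gene
exists; otherwise `size_factors()` fails with advice to filter or add a
pseudocount rather than silently changing the estimator.

One property worth stating precisely, because it is easy to over-claim:
multiplying one column by $c$ does **not** multiply that column's size
factor by exactly $c$ while leaving the others untouched — every gene's
geometric mean moves by $c^{1/m}$, so the scaled column's factor grows by
$c^{1-1/m}$ and all others shrink by $c^{-1/m}$. What is exactly true (and
what the test suite asserts to $10^{-12}$) is the scale law above, and its
corollary that every size-factor *ratio* against the scaled column grows by
exactly $c$. Normalized counts are $q_{ij} = K_{ij}/s_j$.

Per-side expression profiles are arithmetic means of normalized counts over
replicates within each (side, time) cell, on the linear scale — the trend
rules below are stated on that scale.

## 2. The time-effect screen

Counts are modelled as negative binomial, $\mathrm{Var} = \mu + \alpha\mu^2$.

**Dispersion.** $\alpha$ is estimated per gene by method of moments on
normalized counts, pooling the within-cell sums of squares over all
replicated (side, time) cells:
$\alpha_{\text{raw}} = \max\{0, (\hat v - \hat\mu)/\hat\mu^2\}$. A
mean-dispersion trend $\alpha_{\text{fit}}(\mu) = a_0 + a_1/\mu$ is fitted
across genes by least squares, and the working value is the per-gene
maximum $\max(\alpha_{\text{raw}}, \alpha_{\text{fit}})$. With only eight
replicated cells the raw estimate is noisy; taking the maximum borrows
strength from the trend and errs on the conservative side, which shows up
as a type-I error slightly below nominal (≈ 0.03–0.04 at the 0.05 level on
all-null simulations). The floor at zero means under-dispersed genes are
treated as Poisson.

**GLM fits and test.** For each gene two log-link NB GLMs with fixed
$\alpha_i$ and offsets $\log s_j$ are fitted by Fisher-scoring IRLS: a full
model (intercept + side + time-point factors) and a reduced model
(intercept + side). The likelihood-ratio statistic
$2(\ell_{\text{full}} - \ell_{\text{reduced}})$, clipped at zero, is
referred to $\chi^2$ with (#time points − 1) degrees of freedom — the full
model adds exactly the time-factor columns, 3 for the default grid. The
model is additive: it measures an average-over-sides time effect, so genes
whose two sides move in exactly mirrored directions (the simulator's
"complex" class) are weakly detected by design; the concordance stage, not
the screen, is the instrument for side differences.

Numerical choices: IRLS tolerance $10^{-8}$ on the largest coefficient
update, at most 100 iterations, linear predictor clamped to $[-30, 30]$,
fitted means floored at $10^{-10}$, coefficients initialized from
(side, time)-cell means of the raw counts plus a pseudocount of 0.5. With
$\alpha \to 0$ the fit reduces to the Poisson GLM, which the tests verify
against `stats::glm` to $10^{-6}$; at fixed positive $\alpha$ it matches
`glm` with the classical negative-binomial family.

Genes with zero counts in every sample have no defined likelihood; they are
excluded before testing and reported untested. Non-converged fits yield a
missing p-value and are excluded from the Benjamini–Hochberg $m$ (then
reinserted as missing), avoiding spurious significance. BH itself is the
classical step-up procedure via `stats::p.adjust`. The DE call is
`padj < alpha_level`, default 0.05.

## 3. Polarization

**Lin's CCC.** For each gene the oral and physal profiles (length-4
vectors) are compared with
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, moments with
the $n$ denominator per Lin's original definition — with $n = 4$ the
$n$ vs $n-1$ choice is material, so it is fixed and tested. Degenerate
cases: two equal constant profiles give 1 (perfect agreement); two unequal
constant profiles give 0; one constant profile falls out of the formula
(zero covariance). The CCC is computed on the linear replicate-mean
profiles by default — the quantity the analysis averages per time point —
with a `log2(x+1)` switch for sensitivity analysis.

A DE gene with $\rho_c < 0.6$ (strict) is flagged *low concordance*:
side-specific in its temporal behaviour. Non-DE genes carry their CCC but
no flag, since the definition operates on the DE set. Note the flag should
not be read as a calibrated test: a gene whose both sides are flat apart
from noise also has CCC near 0 — which is why low-concordance calls are
conditioned on the DE screen, and why validation of the CCC ranking
(AUC ≥ 0.9 for separating side-specific from shared/null classes) is
evaluated among DE genes.

**Trend taxonomy.** With $a = \text{value} + \text{pseudocount}$
(default 1, matching the zero-to-one convention used before log
transforms): a side is *always_up* when $a_t/a_0 \ge 1.6$ for every
$t > 0$, *always_down* when $a_0/a_t \ge 1.6$ for every $t > 0$, else
*other* ("always" thresholds inclusive). Consecutive-interval calls are
*up* when the ratio to the previous point reaches 1.6, *down* at
$1/1.6$, else *flat*. The side category is *both* when the same trend
holds on both sides and *oral_only* / *physa_only* when exactly one side
trends. The stated rule does not cover a gene always-up on one side and
always-down on the other; such discordant genes carry no category (like
both-other genes) — they are rare and are fully described by their two
per-side labels.

**Summaries.** The side of higher activity is the side larger at a strict
majority of time points, tie-broken by the larger profile sum, then
reported as a tie. The maximal change versus hour 0 is the argmax over
(side, $t>0$) of $|\log_2(a_t/a_0)|$, reported with its hour, side and
signed value; the consecutive-interval analogue reports the interval's end
hour. Argmax ties break deterministically: oral before physa, then the
earlier hour.

## 4. Clustering

Hierarchical clustering operates on log2-transformed (zeros first converted
to 1), gene-wise z-scored normalized counts, with Pearson dissimilarity
$1 - r$ and complete linkage; `cutree` extracts exactly $k$ clusters. Rows
constant after the transform have no z-score and are excluded with a
warning.

Model-profile clustering is a simplified short-time-series scheme: the
candidate profiles are all sign trajectories over consecutive intervals
($3^{T-1} = 27$ for 4 time points, values the cumulative sums). When more
than `max_profiles` (default 20) candidates exist, a maximally spread
subset is kept by greedy farthest-point selection on profile correlation,
seeded at the flat profile (which is always retained so constant genes have
a home). Genes are assigned to the candidate maximizing the Pearson
correlation with their standardized profile, ties to the lower profile id.
Assignment operates on `log2(x+1)` profiles by default: temporal expression
changes are multiplicative, and on the linear scale a geometrically
decaying gene correlates more with a step-shaped profile than with the
monotone-decline profile it represents; on the log scale a constant-fold
decline is exactly linear. Profile significance is a permutation test that
shuffles time labels within each gene (seeded, default 1,000 permutations;
the pipeline default is 200), compares observed assignment counts with the
permutation distribution with the add-one estimator, and BH-corrects across
profiles.

## 5. Enrichment

Category over-representation uses the exact hypergeometric upper tail
$P[X \ge k]$ for $k$ study hits of a term with $K$ background members, a
study set of $n$ from a background of $N$; fold enrichment is
$(k/n)/(K/N)$. Terms without study hits are reported untested. The default
background is the DE gene set — the low-concordance study set is drawn from
it, so this is the nested, conservative comparison — with the whole tested
universe available by option. One-sided over-representation only.

## 6. The synthetic-data generator

The generator emulates the canonical study design: 16 NB-distributed
libraries, ~tens of thousands of genes in real data (defaults here use
5,000 for tractable validation), baseline means log-uniform on
[50, 500] (keeping planted genes comfortably above the detection floor),
gene dispersions on the trend $\alpha = 0.05 + 1/\mu$ (typical bulk RNA-seq
magnitudes), and per-sample size factors log-uniform on [0.7, 1.4]
(realistic library-size spread, and enough signal to test normalization
recovery). Five planted classes with largest-remainder apportionment
(defaults 60% null, 20% shared, 8% + 8% side-specific, 4% complex):
temporal signal is a piecewise-constant log2 random walk with fixed step
magnitude (default 2), applied to both sides (shared), one side
(oral/physa-specific), or mirrored on the two sides (complex,
sign-crossing). Step direction is symmetric by default; a `down_bias`
knob makes predominantly-down programs reproducible. Identical
configurations (including the seed) give bit-identical output.

What the simulator does *not* emulate: read-level effects (GC/length bias,
mapping ambiguity), batch effects, correlated gene modules, smooth
trajectories, or outlier samples. Passing the validation suite therefore
shows that the pipeline recovers the model it assumes under the study's
design and realistic noise; it does not certify behaviour under
misspecification that real libraries may add.

The annotation generator plants enrichment by sampling a fraction of
terms' members with odds weighted (default 8:1) towards
side-specific-class genes, all other terms uniformly, and reports the
truly-enriched term ids for validation.

## 7. Problem sizes and reproducibility

The validation suite and the acceptance script run on: 5,000 genes for the
standard recovery dataset, 2,000 all-null genes for type-I calibration,
1,000 random pairs for the CCC oracle, 100 random matrices for
normalization properties, 100–600 genes for clustering recovery, and a
250-gene end-to-end determinism check — sizes chosen so the whole suite
completes in minutes on one CPU while leaving the binomial noise on each
estimate an order of magnitude below the margin it is tested against.
Every stochastic stage takes an explicit seed; the pipeline fans a single
global seed out to stage seeds by fixed offsets, and reruns with the same
configuration are byte-identical.

## 8. Known limitations

- The additive GLM deliberately has no side×time interaction term; genes
  with opposite-sign dynamics on the two sides are screened weakly (the
  concordance stage addresses them). Pairwise time-point contrasts are out
  of scope by design.
- The dispersion estimator is a transparent method-of-moments/trend
  maximum, not an empirical-Bayes shrinkage; it is mildly conservative at
  two replicates per cell.
- Model-profile clustering is a simplified scheme over sign-trajectory
  candidates, not a port of the original short-time-series miner; cluster
  numberings are not comparable to any external tool's.
- The enrichment test is the plain hypergeometric tail without ontology
  DAG propagation or term-term redundancy handling.
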