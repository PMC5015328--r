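# polarseq

Analysis of bulk RNA-seq time courses sampled on **two sides of a bisected
animal** — the oral ("head") and physal (aboral "foot") halves of a
regenerating cnidarian such as *Nematostella vectensis*. After bisection,
both wound sites remodel their transcriptomes over time; the scientific
questions are (i) which genes respond to regeneration time at all, and
(ii) which of those respond *differently* on the two sides — the polarized
component of the regeneration program.

`polarseq` implements the full analysis as a tested pipeline, plus a
negative-binomial count simulator with planted gene classes so that every
stage can be validated against known ground truth.

## The statistical core

**Time-responsive genes.** Counts `K_ij` for gene *i* in sample *j* are
modelled as negative binomial with mean `s_j q_ij` and variance
`mu + alpha_i mu^2`, where `s_j` are median-of-ratios size factors
(`s_j = median_i K_ij / (prod_v K_iv)^(1/m)` over genes positive in all
samples) and `alpha_i` is a gene-wise dispersion (method-of-moments
estimate pooled over replicated (side, time) cells, an `a0 + a1/mu` trend
fit, and the per-gene maximum of the two). Two log-link NB GLMs are fitted
per gene by IRLS with `log s_j` offsets:

    full:    log mu = intercept + side + time     (time as factors)
    reduced: log mu = intercept + side

and compared by the likelihood-ratio statistic `2(l_full - l_reduced)`,
referred to chi-square with (#time points − 1) degrees of freedom. P-values
are Benjamini–Hochberg adjusted; genes with adjusted p < 0.05 are the
differentially expressed (DE) set.

**Polarized genes.** For each DE gene, the per-side time profiles (replicate
means of normalized counts at each time point) are compared with **Lin's
concordance correlation coefficient**

    rho_c = 2 s_xy / (s_x^2 + s_y^2 + (x̄ − ȳ)^2)

(moments with the *n* denominator). `rho_c < 0.6` defines *low concordance*
— the operational definition of side-specific expression. Each gene also
receives a 1.6-fold trend taxonomy per side (always-up / always-down /
other vs. hour 0; up / down / flat between consecutive time points), the
side of higher activity, and the hour/side/magnitude of its strongest
log2 change.

**Structure and function.** DE genes are clustered hierarchically (Pearson
dissimilarity `1 − r`, complete linkage, on log2 z-scored profiles) and by
a simplified short-time-series model-profile method (sign trajectories over
consecutive intervals, assignment by correlation, permutation significance).
Low-concordance genes are tested for category (GO-style) over-representation
with the exact hypergeometric upper tail and BH correction.

## Worked example

```r
library(polarseq)
cfg <- pipeline_config(sim = list(n_genes = 1000), seed = 42)
run <- run_pipeline(cfg, "demo_run")
print(run)
#> polarseq pipeline run
#>   output: demo_run
#>   genes: 1000 (tested 1000, DE 371, low-concordance 168)
#>   enriched terms: 10
summary(run$de)
#> Time-effect LRT summary
#>   genes: 1000 (tested 1000, untested 0, non-converged 0)
#>   chi-square df: 3
#>   DE genes (padj < 0.05): 371
run$enrichment
#> Hypergeometric enrichment: 100 terms (100 tested), 10 significant at padj < 0.05
#>     term study_hits background_hits fold_enrichment   pvalue     padj
#>  term001         32              35            2.02 2.45e-09 2.45e-07
#>  term010         29              32            2.00 2.75e-08 1.37e-06
#>  ...
```

Of 1,000 simulated genes (60% null, 20% with a shared time trajectory, 16%
side-specific, 4% with crossing trajectories), 371 show a significant time
effect; 168 of those have oral/physal profiles with Lin's CCC < 0.6 and are
called polarized. The ten annotation terms that the simulator planted as
enriched among side-specific genes are exactly the ten significant terms.

Per-gene records (the combined DE + polarization table written to
`results.tsv` / `polarization.tsv`) carry the CCC, trend labels, and
max-change summaries:

```r
head(run$records[run$records$de_flag,
                 c("gene", "padj", "ccc", "low_concordance_flag")])
#>       gene         padj       ccc low_concordance_flag
#> 233 g00233 9.914398e-03 0.5625247                 TRUE
#> 395 g00395 1.382080e-02 0.9365808                FALSE
#> ...
```

A thin command-line front end covering the same stages
(`simulate | normalize | detest | polarize | cluster | enrich | run`) is
installed at `inst/scripts/polarseq.R`.

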