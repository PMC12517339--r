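# bts — Bayesian Tissue Score

Joint **fine-mapping** of GWAS variants and **context-mapping** of
functional annotations from summary statistics.

`bts` is for statistical geneticists who have full GWAS summary
statistics and a collection of functional annotation tracks (open
chromatin, enhancers, histone marks — one BED file per cell type/assay)
and want, without individual-level data:

1. which annotation tracks are enriched for causal variants
   (likelihood-ratio p-values and prior odds per track),
2. which genomic regions are prioritized in each functional context, and
3. context-specific per-variant causal posteriors and 90% credible sets,
   compared against an annotation-free null model.

## The model in brief

Per region with Z-scores $Z$ and signed LD correlation matrix $\Sigma$,
the likelihood of a causal configuration $C$ (at most `d` causal
variants) is $N(Z;\,0,\,\Sigma + W\Sigma I_C\Sigma)$, giving the log
Bayes factor via the matrix-inversion lemma

$$\log \mathrm{BF}_C = -\tfrac12\log\det(I + W\Sigma_{11})
 + \tfrac{W}{2} Z_1^\top (I + W\Sigma_{11})^{-1} Z_1$$

on the causal sub-block only — positive definite even for perfect-LD
proxies. Priors are logistic in the annotations,
$P(C_i=1) = \mathrm{logistic}(E \cdot A_i)$, so each configuration's
posterior factors into an annotation-independent Bayes factor (computed
**once** per region, cached, shared by every annotation model and EM
iteration) and an annotation-dependent prior (an O(d) incremental
update). Enrichment coefficients $E$ are estimated genome-wide by EM;
each track is scored by a $\chi^2_1$ likelihood-ratio test against the
intercept-only null. Defaults: `W = 1` (balances power against
LD-mismatch artifacts), `d = 2`, store pruning at `t = 12` orders of
magnitude. See `vignettes/bts-methods.Rmd` for the full account.

## Worked example

Simulate 60 regions with one truly enriched track (true $E_1 = 2$) and
three decoys, then scan:

```r
library(bts)
ds <- simulate_annotated_dataset(60, region_size = 10, E = c(-3, 2), W = 9,
                                 rho = 0.3, n_decoys = 3, seed = 42)
stores <- lapply(ds$regions, build_bf_store, params = model_config(W = 9))
scan <- scan_annotations(stores, ds$amats)
scan[, c("track", "E1", "prior_odds", "lrt_stat", "pvalue", "status")]
#>        track     E1 prior_odds lrt_stat   pvalue status
#> 1 true_track  2.331     10.292   15.176 9.79e-05     ok
#> 2    decoy_1  1.264      3.538    4.230 3.97e-02     ok
#> 3    decoy_2 -0.498      0.608    0.365 5.46e-01     ok
#> 4    decoy_3 -0.232      0.793    0.108 7.42e-01     ok
```

The enriched track is recovered first ($\hat E_1 = 2.33$, prior odds
10.3, $p = 9.8\times10^{-5}$); the decoys are not significant at the
0.01 convention. Context-specific posteriors for one region under that
track, against the null model:

```r
null_fit <- attr(scan, "null_fit")
ps_null <- variant_posteriors(stores[[1]], rep(plogis(null_fit$E[[1]]), 10))
ps_null
#> <posterior_set> sim_region_001 [null]: top posterior 0.9999, log rel lik 9.0283
row <- scan[scan$track == "true_track", ]
prior <- plogis(row$E0 + row$E1 * ds$amats[[1]][, "true_track"])
ps_tr <- variant_posteriors(stores[[1]], prior, context = "true_track")
credible_set(ps_tr, 0.9)$indices
#> [1]  1 10  2
```

Variant 1 is causal with posterior ~1 in both models; the in-track
variant 10 rises from 0.035 (null) to 0.138 in the enriched context, and
the 90% credible set holds three variants. The end-to-end path from raw
summary statistics is:

```sh
bts run --sumstats sumstats.tsv --panel panel.tsv \
        --tracks tracks.manifest.tsv --out results/ \
        --d 2 --W 1 --t 12 --seed 1
```

which writes `regions.tsv`, `annotations.tsv`, `region_by_context.tsv`,
`variants.tsv`, `credible_sets.tsv`, per-region bundles, and
`run_summary.json`. `bts simulate` emits a synthetic dataset in exactly
those input formats; `bts scan` analyzes prebuilt region bundles.

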