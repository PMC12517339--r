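---
title: "Fine-mapping and context-mapping with bts: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping and context-mapping with bts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A genome-wide association study reports, per variant, a Z-score for
association with a trait. Within an associated locus these Z-scores are
heavily correlated through linkage disequilibrium (LD), so the variant
with the smallest p-value is often not the causal one. Fine-mapping asks:
given the Z-scores and the LD structure, which variants are plausibly
causal? Context-mapping asks a complementary question: across many loci,
which functional annotation tracks (open chromatin, enhancers, histone
marks, per cell type) are enriched for causal variants — and, once an
enriched track is known, how does it redistribute the causal posterior
within each locus?

`bts` answers both questions with one factored Bayesian model, designed so
that the expensive part (likelihoods over causal configurations) is
computed once per locus and reused across thousands of annotation models.

## The model

For a region with $n$ variants, observed Z-scores $Z$, signed LD
correlation matrix $\Sigma$, latent causal indicator vector $C$ and latent
true effects $\Lambda$:

$$P(Z \mid C, \Lambda, \Sigma) = N(Z;\, \Sigma(\Lambda \circ C),\, \Sigma),
\qquad P(\Lambda \mid C) = N(\Lambda;\, 0,\, W I_C),$$

so that integrating out $\Lambda$ gives
$P(Z \mid C, \Sigma) = N(Z;\, 0,\, \Sigma + W \Sigma I_C \Sigma)$. The
Bayes factor of a configuration against the all-null configuration reduces
to the causal sub-block (non-causal variants drop out entirely) and, via
the matrix-inversion lemma, to

$$\log \mathrm{BF}_C = -\tfrac12 \log\det(I + W\Sigma_{11})
 + \tfrac{W}{2}\, Z_1^\top (I + W\Sigma_{11})^{-1} Z_1 ,$$

where $Z_1$, $\Sigma_{11}$ are restricted to the causal indices. The
matrix inverted is $I + W \Sigma_{11}$, strictly positive definite even
when variants are perfect proxies ($\Sigma_{11}$ singular), so duplicated
haplotypes need no regularization and are deliberately *not* collapsed.

The prior that variant $i$ is causal is logistic in its annotations:
$P(C_i = 1) = \mathrm{logistic}(E \cdot A_i)$, with coefficients $E$
shared genome-wide. Configuration priors multiply independent Bernoulli
terms; they are evaluated incrementally from the cached null-configuration
prior with one $O(1)$ update per causal index, which is exactly equal to
the direct product. The posterior of a configuration is then proportional
to $\mathrm{BF}_C \times P(C \mid E, A)$ — one factor that depends only on
GWAS data and LD, one that depends only on annotations. The first factor
is computed once per region (`build_bf_store()`) and shared, unchanged, by
the null model, every annotation model, and every EM iteration.

### Intercept column

As written, a variant with no annotations would get prior $1/2$. The
annotation matrix therefore carries a leading all-ones intercept column
whose coefficient $E_0$ is the baseline log-odds of causality; the
annotation-free "null" model is the intercept-only model. The default
initialization $E_0 = \mathrm{logit}(1/\tilde n)$ (median region size
$\tilde n$) encodes roughly one expected causal variant per region.

## Parameters that matter

* **`W` (default 1, unitless variance):** prior variance of a causal
  effect on the Z-score scale. This single parameter controls LD-mismatch
  robustness. For two perfect proxies with Z-scores $a, b$, the
  both-causal log Bayes factor has the closed form
  $-\tfrac12\log(1+2W) + \tfrac{W}{2(1+2W)}[(a^2+b^2) + W(a-b)^2]$
  (`pairwise_mismatch_bf()`). A correct LD matrix forces $a=b$; in
  meta-analyses one proxy's evidence is often missing and $a \ne b$, and
  the $W(a-b)^2$ term is then a pure artifact. Large $W$ lets that
  artifact dominate (the weak proxy gets prioritized); tiny $W$ lets the
  null configuration dominate everything. $W = 1$ is the shipped balance,
  and the simulator's `make_mismatch_region()` reproduces the scenario.
* **`d` (default 2, count):** maximum causal variants per configuration.
  The store holds $\sum_{l \le d} \binom{n}{l}$ entries; supported up to
  5, with a hard enumeration cap (default $5 \times 10^6$ configurations)
  that fails loudly with advice rather than thrashing memory.
* **`t` (default 12, orders of magnitude):** store pruning. After
  enumeration, configurations whose Bayes factor is more than $t$ orders
  of magnitude below the region maximum are dropped; the null is always
  kept so the posterior denominator stays proper. Because
  $\log\mathrm{BF} \ge -\tfrac12\log\det(I+W\Sigma_{11})$ is bounded
  below, pruning only engages when the top configuration is very strong
  (max $\log\mathrm{BF} \gtrsim t\ln 10$); in that regime the dropped mass
  is at most $\sim 10^{-t}$ of the denominator, which is why posteriors
  are unchanged through (at least) the first 5 significant digits.
* **Reporting thresholds:** genome-wide significance $5\times10^{-8}$;
  LD pruning/expansion at $r^2 > 0.7$; region bounds within 1 Mbp and
  1000 variants of the tag; annotation significance cut $p < 0.01$;
  region prioritization at top posterior $> 0.5$; null-comparison flag at
  a posterior increase $\ge 0.2$; 90% credible sets.

## Enrichment estimation

`em_fit()` maximizes the total relative likelihood
$\sum_j \log \sum_C \mathrm{BF}_C P(C \mid E, A_j)$ by EM. The E-step
computes each variant's marginal causal posterior under the current $E$
(reusing the stores); the M-step is a weighted Newton logistic regression
of those posteriors on the selected annotation columns — the standard
complete-data treatment for this model family; the M-step solves its
problem exactly, so the likelihood is provably non-decreasing (asserted at
tolerance, and tested). Convergence is declared when the total
log-likelihood moves by less than `tol` (default 1e-6, max 100
iterations).

Design choices the model family leaves open, decided here:

* **Separation.** An annotation that perfectly predicts posterior causal
  status sends its coefficient to infinity. Coefficients are capped at
  $|E| \le 20$ (logistic saturation beyond that is numerically
  indistinguishable) with a warning; because a capped M-step is no longer
  the exact maximizer, a likelihood decrease after capping stops the fit
  at the previous saturated point instead of aborting.
* **LRT degrees of freedom.** `scan_annotations()` tests one annotation
  coefficient at a time, so the likelihood-ratio test uses
  $\chi^2_1$; `df` equals the number of tested coefficients in general.
* **Reported prior odds** are $\exp(E_1)$. Under the single-annotation
  model this coincides with the in-track/out-of-track prior odds ratio.
* **Final multi-track model.** The scan reports every per-track fit;
  selecting top tracks and refitting jointly is left to the caller
  (`em_fit()` accepts any column subset), since the per-track scan is the
  reported artifact.

## Preprocessing pipeline

`run_pipeline()` goes from full summary statistics to reports: alleles are
resolved and Z-scores oriented to the alternative allele (sign-flipped
when the stated effect allele is the reference; strand-ambiguous A/T and
C/G variants are kept but flagged, since no frequency information is
required as input); LD comes from a user-supplied genotype dosage panel
(Pearson correlation of dosages — the signed matrix is the model's
$\Sigma$ and its square serves every $r^2$ threshold); genome-wide
significant variants are greedily pruned by ascending p-value into
pairwise-independent tags; tags are LD-expanded into candidate sets;
per-tag blocks are bounded by the outermost linked variant subject to the
1 Mbp / 1000-variant clips; overlapping blocks merge (touching blocks do
not — coordinates are 1-based inclusive); exclusion windows (e.g. the
shipped `hla_exclusion()` for the MHC) drop regions; and every variant
inside the final bounds joins the region, associated or not. BED tracks
are 0-based half-open; variants are 1-based; the conversion is centralized
in `build_annotation_matrix()` and tested at the boundaries.

## What the simulator emulates — and what it does not

`simulate_ld_panel()` draws haplotypes from a latent AR(1) Gaussian
(adjacent correlation `rho`), thresholds them at MAF-matched quantiles,
and sums pairs into diploid dosages. This gives controllable LD decay and
realistic attenuation (dosage correlation falls below the latent `rho`
when neighboring MAFs differ), but it does not reproduce real haplotype
block structure, recombination hotspots, or ancestry mixture.
`simulate_zscores()` draws directly from the summary-statistic likelihood
$N(\Sigma(\Lambda\circ C), \Sigma)$ — there is no individual-level
phenotype simulation. `simulate_annotated_dataset()` places causal status
by the logistic prior with known $(E_0, E_1)$, resamples any region
exceeding `d` causal variants (so the fitted configuration space contains
the truth), and lays one enriched track plus optional decoys. A green
recovery test therefore establishes that the estimator works *under the
model's own assumptions*; it says nothing about robustness to real-data
violations (confounded tracks, mis-specified LD panels) beyond the
explicit LD-mismatch scenario. Seeding is counter-based per region, so
changing the region count never shifts earlier regions' draws.

Two empirical facts about this stated world, found while validating (both
are re-computed by the test suite, not asserted from memory):

* With weak effects ($\Lambda \sim N(0,1)$) and strong LD, the enrichment
  MLE is boundary-degenerate — the profile likelihood keeps rising as
  $E_1$ grows — so no estimator recovers $E_1$ to $\pm 0.5$ there. The
  recovery test world uses effect SD 3 (`W = 9`, typical of genome-wide
  significant loci), 200 regions of 20 variants, `rho = 0.3`; a logistic
  fit on the *true* labels shows the same ~0.25 SD, i.e. the EM is
  information-efficient in this world.
* Calibration of the $\chi^2_1$ LRT under no enrichment needs enough
  causal "events": 500 replicate datasets of 200 regions each give a
  Kolmogorov–Smirnov statistic of ~0.03 against uniform; at 30 regions
  per replicate the test statistic is visibly inflated (mean ~1.2).

## Numerical choices

All posterior and likelihood arithmetic is in log space with
log-sum-exp; linear-space values appear only at output. Bayes factors use
Cholesky solves of $I + W\Sigma_{11}$ (analytic forms for singleton and
pair configurations). Configurations are ordered by size then
lexicographically, making stores, reports and serialization
deterministic; credible sets normalize marginals by their within-region
sum and break ties by genomic order. Degenerate inputs: priors exactly 0
or 1 are rejected (infinite log-odds); an all-zero posterior vector yields
an empty credible set with a warning; Z-score simulation accepts
correlation matrices with eigenvalues down to $-10^{-8}$ (clipped to 0)
and refuses worse.

## Known limitations

No epistatic or multi-SNP interaction modeling; annotations are tested
one at a time, so biologically similar tracks are co-prioritized rather
than disentangled (no cross-annotation correlation model); no in-sample
or ancestry-weighted LD; the pipeline's LD source is a dosage panel, not
PLINK/reference-panel retrieval; no genome-build liftover; p-values are
reported raw with the 0.01 convention, without multiplicity adjustment.
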