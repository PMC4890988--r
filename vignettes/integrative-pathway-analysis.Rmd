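---
title: "Integrative GWAS and expression pathway analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative GWAS and expression pathway analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathintegrate)
```

## The model

`pathintegrate` asks whether a biological pathway is associated with a
binary disease phenotype by pooling two kinds of gene-level evidence:
case-control allele-dose association and case-control differential
expression.

**Gene scores.** Each SNP is tested with the Cochran–Armitage trend test
(scores 0, 1, 2; the squared trend statistic is referred to a χ² with 1
df). A SNP belongs to a gene if it lies in the gene body or within 50 kb
on either side (inclusive; one SNP may belong to several genes). Because
nearby SNPs are correlated through linkage disequilibrium, the per-gene
summary is taken over *tagSNPs* only: a greedy cover that repeatedly
picks the SNP capturing the most still-uncaptured SNPs at r² ≥ 0.8 in a
reference haplotype panel (ties broken by genomic position, then id;
SNPs absent from or monomorphic in the panel tag themselves). The
gene-wise GWAS p-value \(P_{i1}\) is the *minimum* trend-test p over the
gene's tagSNPs. The expression p-value \(P_{i2}\) is a two-sided
two-sample *t*-test on a normalized expression matrix. The integrated
gene score is Fisher's combination

\[
g_i \;=\; -2\bigl(\ln P_{i1} + \ln P_{i2}\bigr),
\qquad P_i \;=\; \Pr\!\left(\chi^2_{4} > g_i\right),
\]

computed over the genes scored by both sources (genes with one source
are kept in the table, flagged, but excluded from integrated pathway
scoring).

**Pathway scores and their null.** A pathway's score is
\(S = -2\sum \ln P_i\) over its scored members. Its significance comes
from a gene-resampling null: each replicate draws the same number of
genes, without replacement, from the non-redundant union of scored genes
across all size-filtered pathways and recomputes the score. The
permutation p-value is the fraction of replicates whose score exceeds
the observed one (strict `>`), with 100,000 replicates by default.
Benjamini–Hochberg q-values are called significant at q < 0.05. The
identical machinery runs on \(P_{i1}\), \(P_{i2}\) and \(P_i\), giving
the GWAS-only, expression-only and integrated analyses whose significant
sets `compare_modes()` intersects.

### Assumptions

* The two evidence sources are treated as independent when combined;
  genotype and expression come from different cohorts, which is what
  makes Fisher's χ²₄ reference distribution appropriate.
* The trend test's χ² approximation is adequate (hundreds of samples,
  common variants after the MAF filter).
* The resampling null treats genes as exchangeable units within the
  scored universe; it conditions on the observed distribution of gene
  scores, not on gene-gene correlation (see limitations).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.01 | exclude SNPs with minor allele frequency below this |
| `hwe_p_min` | 0.001 | exclude SNPs violating Hardy–Weinberg at this p (tested in controls) |
| `call_rate_min` | 0.25 | exclude SNPs with per-SNP call rate below this |
| `window_bp` | 50000 | SNP-to-gene flanking window, bp |
| `r2_threshold` | 0.8 | tagSNP coverage threshold |
| `min_genes`, `max_genes` | 5, 200 | pathway size filter (full membership) |
| `n_perm` | 100000 | permutation replicates per pathway |
| `tie_rule` | `"strict"` | `>` counting; `"add_one"` gives \((\#\{S_{\mathrm{random}} \ge S\}+1)/(n+1)\) |
| `fdr_method` | `"bh"` | Benjamini–Hochberg; `"storey"` offered |
| `q_threshold` | 0.05 | significance call |

The call-rate default of 0.25 is deliberately permissive — it reads the
conventional "genotype percentage below 25%" exclusion literally — and
is exposed so users preferring modern stringent QC can set 0.95. HWE is
tested in controls only by default, the standard GWAS practice, because
genuine association distorts genotype proportions in cases; `hwe_in =
"all"` is available. The additive trend scores (0, 1, 2) are the
canonical choice for an unknown inheritance model.

## Design choices that were genuinely open

* **Natural logarithm in the Fisher score.** With natural logs the score
  is exactly χ² with 2k df under the null; for k = 2 the combined
  p-value has the closed form \(p_1 p_2 (1 - \ln p_1 p_2)\), which the
  tests verify to 10⁻¹⁰.
* **Strict permutation counting.** The default p-value counts only
  strictly larger resampled scores, which is the only rule that can
  yield exact zeros for overwhelmingly enriched pathways; the
  add-one-corrected rule is available because strict zeros are
  statistically improper. Score comparisons use a relative tolerance of
  10⁻⁹ so floating-point reordering of the same weights never counts as
  an exceedance.
* **Permutation universe.** Genes are redrawn from the union of scored
  genes over the size-filtered pathways, not the whole genome, so the
  null respects which genes could have contributed at all. The universe
  is sorted before sampling and every pathway draws from an RNG
  substream derived from `(seed, pathway_id)`; results are therefore
  invariant to pathway order and to any parallel scheduling.
* **Minimum-p gene summary, uncorrected.** The gene-wise GWAS value is
  the raw minimum over tagSNPs, not adjusted for the number of tags.
  Genes with more tags therefore get stochastically smaller null
  p-values; the gene-resampling pathway null absorbs this, because
  resampled sets inherit the same score distribution.
* **Probe collapse before testing** (per-sample median by default; mean
  and strongest-probe offered) guarantees exactly one expression p-value
  per gene, which the k = 2 integration requires.
* **Genes without mapped SNPs are dropped**, not imputed to p = 1 — the
  analysis universe is the genes with at least one SNP, and the
  integrated table is restricted to genes scored by both arms.
* **p = 0 inputs are clamped to 10⁻³⁰⁰** before logs, keeping scores
  finite and the ordering intact.
* **BH arithmetic** is arranged as `(m / rank) * p` with a running
  minimum, which makes the q-values bit-identical to the standard
  reference implementation.

## What the synthetic-data generator emulates

The generator stands in for the real inputs of such a study — restricted
case-control genotypes, public expression series, a reference haplotype
panel, and a curated pathway collection — with known planted truth:

* **Genotypes.** Per gene, haplotypes come from an exchangeable copying
  model: each haplotype draws a founder allele for the gene's LD block
  and each SNP copies it with probability `ld_block_rho^(1/4)`,
  otherwise drawing fresh at the block's minor allele frequency. This
  gives pairwise allelic r² equal to `ld_block_rho` in expectation — the
  parameter is directly the within-block r², tunable from independence
  (0) to near-perfect LD — and all SNPs of a block share one MAF, as
  tightly linked variants do. A thresholded latent-Gaussian scheme was
  considered and rejected: dichotomizing attenuates correlation, so no
  latent correlation below 1 yields the r² > 0.8 structure a tagging
  module must be exercised against. Disease status follows a logistic
  model with per-minor-allele log-odds ln(OR) at one causal SNP per
  causal gene, with the intercept centered at the expected genetic score
  so the population prevalence stays at `base_prevalence`; cases and
  controls are sampled retrospectively by status, matching case-control
  ascertainment. The panel is an independent draw from the same
  haplotype process. Missing genotypes are injected at 1% to exercise
  the call-rate filter.
* **Expression.** Gene-level values are baseline + Gaussian noise; DE
  genes are shifted in cases by `de_effect_size × expr_noise_sd`. By
  default 70% of DE genes are also causal genes, so integration sees
  joint signal.
* **Pathways.** Sizes are uniform on 5–200 (the standard size filter's
  range). Enriched pathways draw `enrichment_fraction` of members from
  the planted signal genes (causal ∪ DE), the rest — and all background
  pathways — uniformly.

Reference conditions (the package defaults) are 500 cases / 500
controls, 2–6 SNPs per gene with MAF 0.05–0.5 and within-block r² 0.8,
10% causal genes at OR 1.5, 20 vs 20 expression samples with a
standardized shift of 1.5 in 10% of genes, 100 pathways with 5 enriched
at `enrichment_fraction` 0.5, and a 500-diploid phased panel. These are
deliberately reduced from a real study's scale (hundreds of thousands of
SNPs, tens of thousands of genes, 234 pathways) so that a full
three-mode analysis runs in seconds.

**What passing tests do and do not show.** The generator's genes are
independent given the planted structure, LD does not extend across
genes, expression noise is Gaussian and batch-free, and pathway overlap
arises only by chance. Recovery of planted pathways here demonstrates
that the statistical machinery is correct and calibrated — not that the
method is robust to cross-gene LD, expression batch effects, or the
correlated pathway memberships of real curated collections.

## Numerical and validation notes

The test suite validates every stage against an independent route: the
trend statistic against direct formula evaluation and a reference
implementation on 1,000 random tables (10⁻¹²); the exact
Hardy–Weinberg test against brute-force conditional enumeration; the
t-tests against the standard single-gene routine; the k = 2 Fisher
combination against its closed form on a 100 × 100 grid (10⁻¹⁰); r²
against exact haplotype-count constructions; greedy tagging against
exhaustive minimum covers on genes of ≤ 8 SNPs (valid cover always, size
within optimum + 1); permutation p-values against exhaustive subset
enumeration on universes of ≤ 12 genes (within 3 Monte-Carlo standard
errors at 200,000 replicates); and BH q-values bit-for-bit against the
reference step-up on 1,000 random vectors.

Calibration is checked on a global-null simulation (2,000 genes, 200
pathways, 10,000 permutations): pathway permutation p-values pass
Kolmogorov–Smirnov uniformity at the 1% level and the empirical type-I
rate at α = 0.05 sits inside its 99% binomial band. Power is
characterized over 20 replicate studies at the reference conditions
(1,000 permutations per pathway): with full overlap between causal and
DE genes the integrated mode recovers on average at least as many
planted pathways as either single-source mode, and the false discovery
proportion among flagged pathways averages ≈ 0.02, well under the
nominal level. At partial (70%) overlap, integration clearly dominates
the GWAS-only analysis while expression-only is statistically tied with
it, and small enriched pathways (5–30 genes, hence only 2–15 signal
genes) are recovered in most but not all replicates — their permutation
p-values land near the Benjamini–Hochberg cutoff. This is an honest
power boundary of the reference design, in which background pathways
also contain planted genes by chance, not a defect of the machinery.

## Known limitations

* No batch correction when expression series are pooled upstream; the
  module consumes one already-normalized matrix.
* Unphased panels use the composite genotype correlation for r² rather
  than EM haplotype phasing — adequate for tagging, slightly biased for
  rare variants.
* The strict permutation rule reports p = 0 for extreme pathways; at
  n_perm replicates, p-values below 1/n_perm are not resolvable (use
  `tie_rule = "add_one"` for downstream procedures that cannot accept
  zeros).
* Gene-gene correlation (shared SNPs in overlapping mapping windows,
  co-expression) is ignored by the resampling null, as it is in the
  class of methods this package implements.
* Normalization of raw expression data (e.g. RMA of array files) and
  retrieval of external genotype/expression/pathway resources are out of
  scope.
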