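---
title: "Inverse-probability weighted clustering for gene-based rare-variant screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-probability weighted clustering for gene-based rare-variant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipwclust)
```

## The problem

Rare variants (minor allele frequency, MAF, below 1%) are abundant in
sequenced exomes but nearly invisible to single-marker association tests:
with a handful of carriers in a cohort, no per-SNP statistic reaches
exome-wide significance unless effects are enormous. A rare variant is also
more plausibly one of several functional variants in the same gene, so the
gene is the natural unit of analysis. `ipwclust` collapses the multi-SNP
genotypes of a gene into a *partition of the individuals* and tests the
partition against the trait. The collapsing step is a weighted
identity-by-state comparison in which sharing a rare allele counts far more
than sharing a common one, so individuals carrying the same rare variants
end up in the same partition element.

## The similarity kernel

At a biallelic SNP with minor allele $a$ at frequency $p$, two alleles
$x, y$ score

$$ s(x, y) = \begin{cases} 1/p_x - 1 & x = y\\ -1 & x \neq y \end{cases}
\qquad p_a = p,\; p_A = 1 - p. $$

Drawing both alleles independently at the population frequencies gives
$E[s] = p^2(1/p - 1) + (1-p)^2(1/(1-p) - 1) - 2p(1-p) = 0$ identically, a
property the tests verify to $10^{-12}$ across a MAF grid. At $p = 0.01$ a
rare-allele match scores 99 and a common-allele match $\approx 0.0101$:
inverse-probability weighting is what lets a single shared rare variant
outweigh many shared common alleles.

Two genotypes score half the sum of the four allele cross-pairs, e.g.
$aa$ versus $aA$ decomposes into one $(a,a)$ match and one $(a,A)$
mismatch, $s = 1/p - 2$. Under Hardy–Weinberg genotype frequencies for two
independent individuals the genotypic score again has expectation exactly
zero. The gene-level similarity is the plain sum over the gene's SNPs, each
scored at its own sample MAF — we use the analysed sample's allele
frequencies, not an external reference panel, because that is what is
available in any study and keeps the kernel self-contained. Monomorphic
SNPs are dropped: an allele with $p = 0$ makes $1/p$ undefined and the SNP
carries no between-individual information anyway.

## Distance transform and clustering

Similarities are mapped to dissimilarities by

$$ d(i,j) = \exp(-\mathrm{sim}(i,j)/a), \qquad
   a = \max(1,\; \max_{i<j}|\mathrm{sim}(i,j)|/20), $$

with the diagonal set to 0. The transform is strictly decreasing in
similarity, and the normaliser keeps every off-diagonal distance within
$[e^{-20}, e^{20}]$, attaining $e^{20}$ exactly when the largest-magnitude
similarity at the gene is negative. The floor $a \ge 1$ avoids inflating
near-zero similarity noise at genes whose SNPs are all nearly monomorphic.
Numerically, $e^{20} \approx 4.85 \times 10^8$ stays comfortably inside
double range while still spreading the rare-sharing pairs (large positive
sim, distance $\approx e^{-20}$) far from mismatching pairs.

Individuals are clustered with Ward's minimum-dispersion criterion applied
to these dissimilarities as given (the `ward.D` convention). The
transformed similarity is not a Euclidean embedding, so the classical
squared-Euclidean reading of Ward cannot hold regardless of convention; we
therefore use the plain Lance–Williams update on the supplied values and
record the convention as configurable in `ward_tree()`. With non-Euclidean
input the merge heights can invert; this is tolerated because partitions
are produced by cutting the tree *by number of clusters* (`cut_tree()`,
partition sizes 5–10 by default), never by height, so inversions cannot
change any output. `stats::hclust` is deterministic, so identical inputs
give identical partitions across runs and platforms; all cuts of one gene
come from the same tree and are therefore nested.

The default sweep over partition sizes 5–10 follows the observation that
the most significant size varies between data sets; results are combined
afterwards by averaging selection counts across sizes (a best-size
alternative is available via `screen_config(aggregate = "best")`).

## Association tests

For each gene, trait and partition size:

* **One-way ANOVA** on the trait across partition elements, classical $F$
  with $(k-1, n-k)$ degrees of freedom. Dichotomous status is analysed as
  numeric 0/1 — a deliberate convention, making the test equivalent to a
  test of equal affection rates across elements.
* **Chi-square test of independence** on the $2 \times k$ affection-by-
  element table, no continuity correction. Sparse tables (expected cell
  below 1) are computed but flagged; sparseness is the known weakness of
  this test on fine partitions.
* **Partition retention** $I = \sum_i n_i^2(\bar y_i - \bar y)^2 / (n
  s^2)$, with $s^2$ the denominator-$n$ variance. $I$ applies unchanged to
  quantitative and 0/1 traits, is invariant to affine trait transforms,
  and under the null converges to a weighted sum of $\chi^2_1$ variables
  with mean 1 as the largest element share shrinks; its finite-sample null
  mean is $1 - \sum_i n_i^2/n^2$, which the tests verify by simulation.
  Whether the published form of the statistic used $n$ or $n-1$ in $s$ is
  not determinable from the source text; we use $n$ (the difference is
  $O(1/n)$ and does not affect ranking).

Multiplicity: ANOVA and chi-square p-values are Bonferroni-thresholded at
family-wise level $\alpha$ (default 0.05, per trait–method–size screen, the
number of tests being the number of genes in that screen). $I$ has no
convenient asymptotic p-value, so genes are ranked by $I$ and the top
fraction kept (default 0.001; the count uses a ceiling so at least one gene
is always selected, with ties broken by statistic then gene id for
determinism). For real applications, `permutation_pvalue()` provides a
seeded permutation alternative, and a Benjamini–Hochberg-style plug-in can
be applied downstream on the exported tables; asymptotic p-values are the
pragmatic choice when screening hundreds of replicates.

Fisher's exact test for $2 \times c$ tables (`fisher_exact_rxc()`,
probability-mass two-sided definition) is included as a diagnostic: a
partition built from one gene's SNPs can be cross-tabulated against a
causal SNP elsewhere to dissect "consistent false positives", which in
admixed cohorts typically reflect population structure rather than linkage.
Stratification adjustment itself is out of scope; standard tools
(PCA-based correction) should be applied upstream.

## The simulator

`simulate_genotypes()` / `simulate_phenotypes()` emulate the *shape* of the
GAW17 unrelated-individuals mini-exome, the benchmark this class of methods
is evaluated on: 697 individuals, 209 cases / 488 controls, 74% of SNPs
rare (observed MAF < 1%), genes averaging ≈ 7.6 SNPs (24,487 SNPs over
3,205 genes), three quantitative traits plus affection status, and 200
phenotype replicates over one fixed genotype matrix.

Choices worth stating:

* Each SNP's stratum (rare/common) is drawn first; rare MAFs are
  log-uniform on $[1/2n, 0.01)$ — populating the very-rare tail below
  0.5% — and common MAFs uniform on $[0.01, 0.5]$. Genotypes are
  Hardy–Weinberg draws, independent across SNPs.
* A SNP whose *realised* sample MAF leaves its stratum (monomorphic, rare
  observed at ≥ 1%, common observed below 1%) is redrawn. The 74% rare
  figure in the emulated data is a statement about observed MAF; without
  this conditioning, binomial leakage across the 1% boundary would bias
  the observed rare fraction to roughly 0.71.
* Quantitative traits are linear-additive, $Q_t = \sum_i \beta_{it} g_i +
  N(0, \sigma)$ with $\sigma = 1$ by default; affection is a
  liability-threshold dichotomisation (a designated trait plus independent
  noise, thresholded at its $(1-\text{case fraction})$ sample quantile),
  giving exactly 209 cases per replicate by construction. This is the
  simplest model consistent with per-SNP effects and a fixed case count;
  the original benchmark's generating model is richer.
* Not emulated: linkage disequilibrium, haplotype structure, population
  admixture, pedigrees, and the benchmark's actual trait architecture.
  Passing tests therefore demonstrate calibration and rare-variant
  clustering behaviour under clean conditions, not robustness to LD or
  stratification — on real data the permutation mode and upstream
  stratification adjustment matter.

`planted_cluster_fixture()` builds the canonical demonstration: one gene
with a single rare variant (e.g. 20 heterozygous carriers among 697, MAF
≈ 1.4%) over a background of common SNPs. The carriers' pairwise
similarity (≈ 34 from the rare SNP alone) dwarfs the common-SNP noise, so
every partition size from 5 to 10 leaves all carriers in one element — the
mechanism by which the screen gains power from multiple rare carriers.

## Numerical and design notes

* **Degenerate inputs.** A constant trait gives $I = 0$ with a flag; zero
  within-group variance in ANOVA returns the boundary p-value (0 or 1)
  with a flag; genes with fewer distinct genotype profiles than the
  requested partition size are still cut (legal, since the tree has $n$
  leaves) and recorded in the screen's `capped` table.
* **Problem sizes.** The test suite simulates at the cohort scale it
  emulates (n = 697) but with reduced exomes: 300 genes × 100 replicates
  for the null-calibration and power checks, 10,000 replicates at
  n = 2000 for the null mean of $I$. These sizes put Monte-Carlo error
  well inside the asserted tolerances (e.g. the $I$ null mean has
  standard error ≈ 0.002 at 10,000 replicates against a ±0.05 band).
* **Determinism.** Every stochastic component (simulator, permutation
  p-values) flows from an explicit integer seed; screens over fixed inputs
  are deterministic, and repeated runs write byte-identical tables.
* **Folding.** Dosages are always re-expressed as minor-allele counts at
  load (columns with alternate-allele frequency above 0.5 are folded;
  exact ties keep the file's orientation), because the kernel is defined
  in terms of the minor allele.
* **Missing data.** Missing genotype calls are a hard error. Imputation is
  deliberately out of scope; complete inputs are a precondition.
* **Alternative reconstructions.** The score tables sit behind
  `allele_score_table()` / `genotype_score_table()`, so a differently
  scaled inverse-probability kernel is a one-place change. A positive
  *rescaling* of the scores leaves Ward partitions unchanged; a *shift*
  would not, which is why the mean-zero property is pinned by tests.

## Limitations

Power collapses for extremely rare variants unless effect sizes scale up
as MAF drops — visible in `power_curve()` output as genes with small
$\sum_i \text{MAF}_i \beta_i$ hovering at the noise level. The chi-square
test degrades on sparse partitions (prefer $I$ there). Bonferroni across
thousands of genes is conservative; the top-fraction rule is a pragmatic
screen, not an error-controlled test. No covariates, no LD-aware kernel,
no continuous (imputed or stratification-adjusted) genotypes — the scores
are defined on hard calls.
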