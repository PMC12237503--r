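---
title: "dapcr: models, numerical choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dapcr: models, numerical choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapcr)
```

## The method

DAPC describes genetic structure in two stages. Principal component analysis
first compresses a samples × variants allele-dosage matrix into a small
number of orthogonal axes of total variation; Fisher linear discriminant
analysis then rotates those axes to maximize between-group relative to
within-group variation, yielding at most $k-1$ discriminant axes for $k$
groups and per-sample posterior membership probabilities. The PCA stage is
what makes the LDA well-posed: genotype data has far more variants than
samples, so discriminant analysis on raw dosages would be hopelessly
singular, while PC scores give a low-dimensional, decorrelated
representation with a well-conditioned pooled covariance.

The package assumes its input SNPs are biallelic and quasi-independent
(i.e. LD-pruned upstream), and that group structure is linear in dosage
space — the same assumptions the classical method makes.

## Sparse ingestion

`read_vcf()` streams GT fields chunk-wise into triplet accumulators and
builds a `Matrix::dgCMatrix` of alternate-allele dosages at the end, so peak
memory is one chunk of text plus the sparse triplets; the result is
provably independent of `chunk_size` (tested). Compressed sparse *column*
storage is used rather than CSR: the two are mirror layouts with identical
memory scaling (proportional to non-zero entries), and CSC is the native
format of the R `Matrix` stack that every downstream product uses.

Missing calls are a separate sparse pattern mask, never a stored dosage:
`0` always means "homozygous reference", and any GT containing `.`
(including half-calls like `./1`, whose dosage is ambiguous) is missing.
Multiallelic records are dropped with a reported count by default — the
method is defined on biallelic SNPs — or split into per-ALT pseudo-variants
on request, each counting one ALT allele. MAF filtering runs on observed
calls *before* imputation so frequencies are not distorted by imputed
values; mean imputation (the default) preserves each variant's allele
frequency exactly, and zero imputation preserves sparsity exactly.

PLINK BED files are decoded from the published two-bit encoding with the A1
allele playing the role of ALT, so a trio written by `write_plink()`
round-trips bit-exactly against the VCF path.

## Truncated SVD without densification

For genotype matrices one dimension is typically 10–1000× smaller than the
other. `fit_truncated_svd()` therefore eigendecomposes the smaller Gram
matrix — $K = X_c X_c^\top$ ($n \times n$) or $C = X_c^\top X_c$
($p \times p$) — and recovers the other factor by one sparse product.
Column centering is applied implicitly: with $m$ the column-mean vector,
$K = XX^\top - c\mathbf{1}^\top - \mathbf{1}c^\top + (m^\top m)\mathbf{1}\mathbf{1}^\top$
with $c = Xm$, a rank-one correction that never touches the sparse matrix.
This solver is exact and deterministic (LAPACK symmetric eigendecomposition),
which is why no randomized variant with a seed is needed at desk scale; it
is the design analogue of "exact Lanczos-style solver by default".

Numerical choices:

* **Centering default ON.** Centered truncated SVD *is* PCA, giving us an
  independent oracle (`eigen(cov(X))`) the test suite checks against at
  1e-6; `centering = "none"` reproduces the raw truncated SVD some sparse
  pipelines use. No variance scaling by default; `scale = TRUE` gives
  adegenet-style unit-variance columns.
* **Rank guard.** Components with singular value below $10^{-6} \sigma_1$
  (eigenvalue ratio $10^{-12}$) are treated as numerically zero; asking for
  more yields a warning and fewer components.
* **Sign convention.** Each loading column is oriented so its
  largest-magnitude entry is positive, making archives and plots
  reproducible across platforms.
* **Explained variance** is measured against the total variance of the
  (centered) matrix, i.e. the trace of the Gram matrix.

## Discriminant step

`fit_lda()` solves the generalized eigenproblem by Cholesky whitening of the
pooled within-class covariance $S_w$ (unbiased, $n-k$ denominator): axes are
$w = R^{-1} e$ for $R^\top R = S_w$ and $e$ the leading eigenvectors of
$R^{-\top} S_b R^{-1}$, so $w^\top S_w w = 1$. At most
$\min(k-1, r)$ axes are kept. If the Cholesky fails (collinear scores), a
ridge $10^{-6}\,\mathrm{tr}(S_w)/r \cdot I$ is added — only then, so
well-posed fits are never silently perturbed. Classes with one sample are
rejected with guidance rather than regularized into a meaningless fit.

Posteriors use the shared-covariance Gaussian model
$P(c\mid x) \propto \pi_c \exp(-\tfrac12 d_{S_w}^2(x, \mu_c))$ with
empirical priors by default, computed with log-sum-exp for stability. This
is a *definition* adopted by the package (documented, tested for simplex
and symmetry properties); whether it matches adegenet's membership
probabilities numerically is deliberately left open. Argmax ties break to
the first class in sorted label order.

## Cross-validation and PC selection

Split plans are explicit objects: plain k-fold shuffles (seed mandatory, so
sorted-by-population input files cannot produce class-free training folds),
stratified k-fold splits each class separately with remainders spread over
random folds (per-fold class counts provably within 1 of proportional), and
LOOCV enumerates singletons. Within `cross_validate()` the SVD and LDA are
refitted per training fold and the held-out fold is projected with
*training* centering and loadings — the no-leakage property is tested by
corrupting held-out genotypes and asserting fold-model invariance.

Grid search keeps the full accuracy table; the winner is the highest mean
accuracy with ties broken to the **smallest** PC count. The tie rule is the
package's own choice: when accuracy plateaus, the smallest model is the one
that has not begun to overfit. The `k_minus_one_pcs()` rule (retain $k-1$
PCs for $k$ groups) is provided for the de novo workflow, where those $k-1$
axes carry all linearly separable group information.

## De novo clustering

K-means runs on PC scores (never raw genotypes) with k-means++ starts and
`n_init = 10` restarts, best SSE wins, deterministic given the seed. The
sweep table over candidate $k$ always reports both SSE (for elbow
inspection; never auto-thresholded) and mean silhouette; automated
selection takes the maximum silhouette, smallest $k$ on ties, because
silhouette has an intrinsic optimum whereas SSE decreases monotonically.
BIC-based selection is intentionally absent. The silhouette uses the
standard $(b-a)/\max(a,b)$ with singleton clusters contributing 0.

How many PCs to cluster on is genuinely open; `choose_n_pcs()` implements a
90%-cumulative-variance heuristic (capped at 120), but the package's own
validation clusters on 10 PCs — matching the supervised recovery setting —
and the sweep table should always be inspected.

## The simulator: a stated world

`simulate_cohort()` implements the Balding–Nichols model: ancestral
frequency $p \sim U(0.05, 0.5)$ per SNP, population frequency
$\sim \mathrm{Beta}\!\big(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\big)$ so that
per-population frequencies have mean $p$ and variance $p(1-p)F$, genotypes
$\sim \mathrm{Binomial}(\text{ploidy}, p_{pop})$. Defaults — 4 populations,
50 samples each, 1000 SNPs, $F_{ST} = 0.1$, diploid, no missingness — are a
desk-scale analogue of a pruned parasite-cohort job: 4 is the number of
effective populations the de novo analysis should recover, 1000 SNPs is a
realistic post-pruning panel fraction, and $F_{ST} = 0.1$ is moderate
continental-scale differentiation. The Hudson-style estimator (with the
finite-sample correction of Bhatia et al.'s recommended form, ratio of
averages) closes the loop: simulated cohorts at $F = 0.1$ are recovered
within ±0.02 at 10 000 SNPs.

What the simulator does **not** emulate: linkage disequilibrium (SNPs are
independent — consistent with the pipeline's pruned-input assumption, but
meaning green tests say nothing about LD-confounded structure), admixed
individuals, selection, mutation-rate heterogeneity, or call-rate structure
(missingness is uniform). A green recovery test therefore establishes that
the pipeline detects clean island-model structure at moderate FST — not
that it resolves clines or admixture the way the method's guidelines
discuss.

One estimator subtlety surfaced by testing: with the finite-sample
correction, two populations with *identical sample frequencies* give a
slightly negative FST estimate (the correction subtracts sampling variance
that the construction lacks). The estimator is unbiased around zero under
actual resampling, which is what the test asserts.

## Serialization

Model archives are versioned JSON documents of named numeric arrays plus
provenance (dimensions, options, seed, package version) — portable and
inspectable, unlike a native object dump. JSON numbers carry ~15–17
significant digits, so numeric fields round-trip to ~1e-15 relative and
predictions/posteriors to well below 1e-12 (both tested). Truncated
archives fail the JSON parse; a foreign version tag is refused explicitly.

## Known limitations

* The exact Gram-route SVD is $O(\min(n,p)^3)$; for cohorts where *both*
  dimensions exceed ~20 000 an iterative solver would be preferable.
* Posterior probabilities depend on the shared-covariance Gaussian
  assumption; strongly unequal within-group dispersions will miscalibrate
  them (labels are usually still right; probabilities, not).
* `read_vcf` trusts the GT field and ignores genotype likelihoods; dosage
  uncertainty is not propagated.
* Stratified CV requires every class to have at least `kcv` members; rare
  populations must be merged, dropped, or cross-validated with plain
  k-fold.
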