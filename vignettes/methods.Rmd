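---
title: "Methods: shrinkage bases for GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shrinkage bases for GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

GWAS summary statistics mix three sources of variation: biological signal,
technical differences between studies (platform, processing, cohort), and
sampling noise. A principal component analysis applied directly to effect
estimates maximises variance explained without distinguishing these
sources, so it magnifies technical and random structure along with the
biology. `gwasbasis` addresses this by shrinking effect estimates towards
zero in proportion to the evidence that their region is genuinely
associated with at least one of the training diseases, before the
decomposition; and by splitting the data into training studies (which
define the space) and projected studies (which are tested in it), so that
standard hypothesis tests apply.

## The model

### Harmonisation

All studies are aligned to a reference panel's variant index. Effects are
oriented to the panel's alternative allele: when a study reports the effect
for the panel's reference allele (alleles swapped), the sign of the effect
flips. No strand flipping is attempted; strand-ambiguous palindromic (A/T,
C/G) variants are always dropped, as are variants whose alleles match the
panel neither directly nor swapped. This conservative rule loses a few
percent of variants but cannot silently mis-orient an effect. Variants are
filtered to minor allele frequency above 1% and regions with long-range,
complex LD are masked (the MHC, GRCh37 chr6:20–40 Mb, by default — its
dense disease associations would otherwise dominate the decomposition).
Masks are read in BED convention (0-based, half-open) and converted to the
package's 1-based inclusive positions.

### Shrinkage

The variance of an effect estimate factorises into an allele-frequency part
and a sample-size part. Only the frequency part,
$\sigma_{MAF} = 1/\sqrt{2f(1-f)}$ for alternative-allele frequency $f$, is
adjusted for: dividing by the sample-size part as well would shrink small
studies relative to large ones, which is exactly what the method must
avoid. This factorisation is the only one consistent with adjusting for
between-SNP but not between-study variance.

Within each LD block (intended to be recombination-hotspot-defined, so
that blocks can be treated as independent), and under the working
assumption of at most one causal variant per block, the Wakefield
asymptotic Bayes factor for SNP $i$ in study $t$ is

$$\log \mathrm{ABF}_{ti} = \tfrac12 \log\frac{se_{ti}^2}{se_{ti}^2 + W}
  + \tfrac12 z_{ti}^2 \frac{W}{se_{ti}^2 + W}, \qquad z_{ti} = \hat\beta_{ti}/se_{ti},$$

with prior effect variance $W$. The posterior probability that SNP $i$ is
the causal one in its block is the softmax of the block's log ABFs,
computed with log-sum-exp so that extreme $z$ cannot overflow. The
single-causal-variant model is used for its *side effect*: it spreads
posterior mass across an LD clique (avoiding double counting) and assigns
near-zero mass everywhere no association exists. The per-SNP weight $w_i$
averages these posteriors across the training studies (equal study weights
by default, configurable); the basis input is $\hat\gamma_i = w_i
\hat\beta_i / \sigma_{MAF,i}$.

Two comparison transforms are provided for method evaluation: `naive`
($\hat\gamma = \hat\beta$, no shrinkage) and `z_threshold` ($\hat\gamma =
z$ if the two-sided p-value is at most 0.001, else 0, with ties at exactly
0.001 kept).

### Basis construction

The trait × SNP matrix of $\hat\gamma$, augmented with a synthetic control
trait whose effects are all zero (the limit of a null GWAS as the sample
size tends to infinity), is column mean-centred — no variance scaling —
and decomposed by thin SVD. The control row is included in the centring:
it is a row of the matrix like any other, and excluding it would rescale
the centring vector by $n/(n-1)$ without changing any projection
*difference*, since centring cancels in $\hat\delta$.

The retained rank is the smallest truncation minimising the mean squared
reconstruction error, scanned over all ranks; for an $n$-row matrix of
generic data this is $n-1$, because centring removes one degree of
freedom. An absolute tie tolerance of $10^{-12}$ prevents a
numerically-zero trailing singular value from inflating the rank.

Each retained rotation column $Q_k$ is sparsified by hard thresholding:
$Q_k(\alpha) = Q_k \cdot I(|Q_k| > \alpha)$, with the distortion measured
on the training matrix as $D_k(\alpha) = 1 - \mathrm{cor}(M^c Q_k, M^c
Q_k(\alpha))$ and $\alpha_k$ chosen as the largest value keeping
$D_k < 0.001$. The search grid is the sorted set of distinct $|Q_{ik}|$
values — exact and finite, so $\alpha_k$ is reproducible — and the grid is
scanned exhaustively (via cumulative removal sums, $O(np)$ per component),
so local non-monotonicity of $D_k$ cannot mislead the search. The value at
the grid maximum is excluded (it would zero the whole column). SNPs
surviving the mask are the component's driver SNPs.

### Projection and inference

A new study is harmonised to the basis index, transformed with the
*frozen* training weights ($w$, $\sigma_{MAF}$ travel inside the saved
basis; projected studies never alter them), and multiplied by the sparse
rotation. Variants absent from the study enter as zero, which biases
$\hat\delta$ towards the null — conservative, and warned about above 5%
missingness. $\hat\delta$ is reported relative to the projected control,
which is exactly zero under this route.

Because the rotation is fixed, $\hat\delta$ is a linear score of the
study's estimates, and its covariance follows by the delta method with the
panel's block-diagonal LD:

$$\mathrm{Var}(\hat\delta)_{kl} = \sum_{b} \sum_{i,j \in b}
  a_{ik}\, a_{jl}\, r_{ij}\, se_i\, se_j,
  \qquad a_{ik} = Q^s_{ik} w_i / \sigma_{MAF,i},$$

with cross-block correlation zero. This construction is validated against
Monte-Carlo resampling of $\hat\beta$ in the test suite. The overall null
hypothesis $\delta = 0$ is tested by $T = \hat\delta^\top V^{-1}
\hat\delta$ against a chi-square with degrees of freedom equal to the rank
of $V$ (eigen-pseudo-inverse when degenerate); full covariance is the
default, with a diagonal-only option for LD-free input. Per-component
two-sided z tests are adjusted by Benjamini-Hochberg independently within
each trait category and each component; a trait-component pair is flagged
only when the trait is overall-significant *and* component-significant
(both strictly below their thresholds, 0.01 by default).

### Follow-up

*Consistency.* A significant projection should reflect many small effects
in coherent directions, not one heavily-weighted driver SNP in chance LD
with one large trait effect. Driver SNPs of the component are greedily
pruned to pairwise $r^2 < 0.01$ in decreasing order of $|Q_{ik}|$, and the
weighted Spearman correlation (average-rank transform, then weighted
Pearson with weights $w/\sigma_{MAF}$ — stated explicitly because no
single canonical definition exists) is computed between the study's
$\hat\gamma$ and $Q_k$. Significance comes from permuting the study's
values; the permutation count defaults to 10,000 and the seed is
mandatory, so $p = (1 + \#\{|\rho_{perm}| \ge |\rho|\})/(n_{perm}+1)$ is
exactly reproducible.

*Subset-selected FDR.* GWAS p-values at the union of driver SNPs of a
trait's significant components are BH-adjusted within that subset only,
then SNPs are ordered by increasing ssFDR (ties: smaller p, then variant
key) and any SNP with $r^2 > 0.1$ against a higher-placed SNP is marked
pruned — the first-ranked SNP of each LD clique survives.

*Clustering.* Ward.D2 linkage on Euclidean distances between projected
locations, with Newick export. Clustering is a visual overview, not a
formal test; tie-breaks follow input order.

## Tunable parameters

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `W` | 0.04 | squared log-OR | prior SD 0.2 for a causal log odds ratio, the conventional fine-mapping choice |
| `null_odds` | none | prior odds | pure softmax by default; a per-block null mass is available |
| `study_weights` | equal | — | the cross-study average is a design choice; per-study weights accepted |
| `tol` (sparsification) | 0.001 | 1 − correlation | loses at most 0.1% of training-projection correlation per component |
| `maf_min` | 0.01 | frequency | rare variants carry unstable effect estimates |
| MHC mask | chr6:20–40 Mb (GRCh37) | BED | long-range LD and outsized disease associations |
| FDR thresholds | 0.01 overall, component, ssFDR | — | strict inequalities; conjunction rule for component calls |
| `r2_max` (consistency) | 0.01 | squared correlation | near-independence for the rank test |
| `r2_prune` (ssFDR) | 0.1 | squared correlation | one representative per LD clique |
| `n_perm` | 10,000 | permutations | permutation p resolution 1e-4; seed mandatory |

## The synthetic-data generator

`simulate_panel()` lays variants in contiguous blocks with AR(1)
within-block correlation ($r_{ij} = \rho^{|i-j|}$, $\rho = 0.9$ by
default; an exchangeable option exists) and zero cross-block correlation —
chosen for the analytic tractability of the variance oracle. Allele pairs
are drawn from the non-palindromic combinations; frequencies are uniform
on (0.05, 0.95).

`simulate_traits()` draws sparse causal patterns (at most one causal SNP
per block per component, matching the method's working assumption), with
standardised causal effects of SD `effect_sd` (default 0.05, so a causal
variant in a 5,000/5,000 case-control study — effective sample size
$N_{eff} = 4/(1/N_{ca} + 1/N_{co}) = 10{,}000$ — reaches $|z| \approx 5$).
Trait loadings on the components are orthogonalised Gaussian columns
scaled by geometrically decaying component strengths (0.8 per step), so
the latent components are identifiable and separable — without
orthogonality the PCA would recover the latent *subspace* but arbitrary
rotations within it, and no parameter-recovery check would be meaningful.
Marginal effects are LD-tagged by multiplying through the block
correlation; estimates add block-correlated sampling noise at
$1/\sqrt{N_{eff}}$ (the Gaussian sampling model makes the delta-method
covariance exact, which is what makes exact null calibration checkable)
and a technical artifact (default SD 0.002 on the standardised scale, a
fifth of a 10k-sample study's sampling error) shared by all studies with
the same cohort label. Reported effects are per-allele:
$\hat\beta = \hat\beta_{std}\,\sigma_{MAF}$, $se = \sigma_{MAF}/\sqrt{N_{eff}}$.

What the generator does *not* emulate: realistic human LD maps and
long-range LD, discrete genotype sampling (dosages are Gaussian;
`sample_dosages()` matches the target LD in expectation by construction),
case-control ascertainment effects on $se$ beyond the effective-sample-size
approximation, population stratification, and allele-frequency differences
between study and panel. Tests passing on this generator therefore
demonstrate the statistical machinery — calibration, shrinkage behaviour,
recovery — under the model's own assumptions, not robustness to real-data
violations of them.

The shrinkage-versus-naive contrast is exercised with a dedicated
scenario: four diseases with 10,000/10,000 studies in separate cohorts,
each with a 500-case/20,000-control replicate, all four replicates sharing
one "biobank" cohort artifact (SD 0.01, comparable to a 10k study's
sampling error), and strong established loci (`effect_sd` 0.08, a fifth of
blocks causal per component). This mirrors the situation where
self-reported biobank traits share platform structure: under the naive
transform the shared artifact, spread over all SNPs, dominates the
decomposition and the replicates cluster with each other; continuous
shrinkage zeroes the artifact wherever no training disease is associated,
and the replicates cluster with their diseases.

## Numerical choices

- PCA by thin SVD of the centred matrix; rotation-column signs fixed so
  the largest-|entry| loading is positive (PCA signs are otherwise
  arbitrary and would break serialisation and regression tests).
- Softmax and log-ABF in log space throughout (log1p, log-sum-exp).
- Pseudo-inverse rank threshold for the chi-square: eigenvalues below
  $10^{-8}$ of the largest are treated as null directions and the degrees
  of freedom reduced accordingly; a zero-rank covariance with zero delta
  returns $p = 1$.
- The basis container serialises every floating-point number with 17
  significant digits (`%.17g`), so save → load → save is byte-identical,
  loaded thresholds reproduce driver sets exactly, and projections through
  a loaded basis match the in-memory basis to machine precision. The
  manifest records md5 checksums and a format version; both are verified
  on load.
- Per-block Cholesky factors are cached on simulated panels so repeated
  null-study generation (2,000 replicates in the calibration check) stays
  cheap.
- Degenerate inputs error early with informative messages: empty blocks,
  zero-variance projections, missing LD for driver-SNP blocks (named),
  fewer than three pruned SNPs for a rank correlation, duplicate variant
  keys (named), empty study-panel intersections.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise the structure rather
than real-data scale: a shared 8-trait/2,000-SNP fixture for unit tests;
13 traits over 20,000 SNPs in 200 blocks for rank selection and
sparsification; 2,000 null projections on a 10,000-SNP basis for
calibration; a 30-SNP/3-block panel against $10^5$ Monte-Carlo draws for
the covariance; 20 scenario seeds for the shrinkage-versus-naive contrast;
and the 10-trait/20,000-SNP default scenario for latent-component
recovery. `scripts/acceptance.R` re-runs the 13-trait construction from
scratch at 20,000 SNPs.

## Known limitations

- The single-causal-variant assumption is unrealistic in regions of
  allelic heterogeneity; it is retained because it requires no
  study-specific LD and, in practice, captures the strongest signal per
  region. Regions like the MHC, where it fails badly, should stay masked.
- Signals in projected studies are only discoverable if represented in the
  training diseases; a null projection means "no detected association with
  these components", not "no genetic association".
- The number of distinguishable components is bounded by the number of
  training studies.
- Setting missing variants to zero biases projections towards the null;
  heavily incomplete studies need external imputation (out of scope here).
- No allele-frequency concordance check between study and panel is
  performed by default; grossly mismatched ancestries will pass
  harmonisation silently if alleles match.
- Permutation p-values are bounded below by $1/(n_{perm}+1)$.
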