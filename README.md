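# gwasbasis

Shared genetic risk across a set of related diseases can be summarised in a
handful of dimensions — if the noise that dominates genome-wide association
study (GWAS) summary statistics is tamed first. `gwasbasis` learns such a
low-dimensional **basis** from a set of large GWAS and then projects
independent, possibly very small, GWAS into it with formal statistical
tests. It is aimed at statistical geneticists who want to place rare
diseases or disease subtypes (hundreds of cases) in the context of large
studies of related common diseases, using only summary-level data.

## The method

For each SNP *i* with effect estimate β̂ᵢ (log odds ratio with respect to
the reference panel's alternative allele) and standard error, the package
computes a continuous shrinkage weight from Bayesian fine-mapping under the
assumption of at most one causal variant per recombination-hotspot-defined
LD block:

- **Wakefield log approximate Bayes factor** per SNP and study:
  log ABF = ½ log(se² / (se² + W)) + ½ z² W / (se² + W), z = β̂/se,
  with prior effect variance W = 0.2² by default;
- **posterior probability of causality** within each block: softmax of the
  log ABFs (log-sum-exp), optionally with a null-model mass;
- **overall weight** wᵢ: the average of these posteriors across the input
  studies, so wᵢ ≈ 0 wherever no study shows association;
- **shrunk effects** γ̂ᵢ = wᵢ β̂ᵢ / σ_MAF,ᵢ, where σ_MAF = 1/√(2f(1−f)) is
  the allele-frequency (sample-size-free) part of the standard error.

The trait × SNP matrix of γ̂, plus a synthetic all-zero **control trait**,
is column mean-centred and decomposed by PCA. The informative rank is the
smallest truncation minimising the mean squared reconstruction error (n − 1
for n rows of generic data). Each rotation column Q_k is then hard
thresholded at the largest α_k keeping the distortion
D_k(α) = 1 − cor(M^c Q_k, M^c Q_k(α)) below 0.001; the surviving SNPs are
the component's **driver SNPs**.

An independent study is harmonised to the same variant index, shrunk with
the *frozen* training weights, and multiplied by the sparse rotation. The
result δ̂ — its distance from the projected control — gets an LD-aware
covariance (block-diagonal delta-method variance of the linear SNP score),
an overall chi-square test, per-component z tests, and Benjamini-Hochberg
FDR within user-defined trait categories. Follow-up tools: a weighted
Spearman consistency test on LD-pruned driver SNPs with permutation
p-values, subset-selected FDR over driver SNPs of significant components,
and Ward.D2 clustering of projected traits.

A synthetic-data module simulates reference panels with AR(1) LD blocks and
multi-trait GWAS with known latent components, so the whole pipeline is
testable without any external download.

## Worked example

```r
library(gwasbasis)

# simulate 8 related GWAS sharing 3 latent risk components
sc    <- simulation_scenario(seed = 42, n_snps = 2000, n_blocks = 40,
                             n_traits = 8, n_components = 3)
panel <- simulate_panel(sc)
sim   <- simulate_traits(sc, panel)

weights <- compute_shrinkage(sim$studies, panel,
                             index = intersect_studies(sim$studies))
basis   <- build_basis(sim$studies, weights, panel)
basis
#> GWAS basis: 8 traits + control, 2000 SNPs, 8 components (mode: continuous , sparsified )

# project a 500-case replicate of trait 1 and a null study
sc_rep <- simulation_scenario(seed = 42, n_snps = 2000, n_blocks = 40,
                              n_traits = 8, n_components = 3,
                              replicates = data.frame(disease = 1,
                                                      n_cases = 500,
                                                      n_controls = 5000))
rep1 <- simulate_traits(sc_rep, panel)$studies[["trait01_rep"]]
project_study(basis, rep1, panel = panel)
#> Projection of 'trait01_rep': chi-square 43.21 (df 8), p = 8.0063e-07

project_study(basis, simulate_null_study(panel, 2000, 2000, seed = 7),
              panel = panel)
#> Projection of 'null_study': chi-square 13.55 (df 8), p = 0.094263
```

The replicate — a small study of a disease the basis was trained on — is
clearly non-null, while the simulated null study is not: the chi-square
statistic over the 8 components and its p-value are the primary measure of
whether a projected trait shares genetic architecture with the basis
diseases. `projection_table()` + `flag_significant()` add per-component
and category-wise FDR; `consistency_test()` guards against single-SNP
artifacts; `cluster_traits()` draws the dendrogram.

File-based workflows go through `run_pipeline("config.yaml")` or the
`gwasbasis` command-line wrapper (`simulate`, `harmonise`, `shrink`,
`build`, `project`, `consistency`, `driver-snps`, `cluster`).

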