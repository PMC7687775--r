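Package: gwasbasis
Title: Shrinkage-Based Principal Component Bases for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a low-dimensional "basis" of shared genetic risk from a set
    of large genome-wide association studies (GWAS) using Bayesian
    fine-mapping-derived continuous shrinkage of effect sizes followed by
    principal component analysis, and projects independent (possibly very
    small) GWAS into that space with formal statistical tests. Includes
    allele harmonisation against a reference panel, per-component driver-SNP
    sparsification, LD-aware variance estimation for projected scores,
    chi-square and per-component significance testing with Benjamini-Hochberg
    false discovery rate control, weighted Spearman consistency checks,
    subset-selected FDR for driver SNPs, trait clustering, and a synthetic
    data generator with block-structured linkage disequilibrium for
    validation without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
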