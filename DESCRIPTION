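Package: mfqtl
Title: Multifamily Bayesian QTL Mapping and Ideotype Simulation for
    Doubled Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian quantitative trait locus (QTL) analysis of
    several doubled haploid (DH) families that share a common parent.
    Builds a joint genetic map on a 1-cM interval grid, imputes interval
    genotypes with a no-interference Markov model, fits a
    variable-dimension (reversible-jump) MCMC model with family-specific
    QTL segregation indicators, calibrates genome-wide significance of
    per-chromosome QTL intensity by permutation, predicts phenotypes by
    posterior-probability-weighted marker effects with k-fold
    cross-validation, and simulates ideotype genotypes that fix
    favorable alleles in selected QTL regions.  Includes a synthetic
    multifamily DH data generator, season-effect phenotype adjustment,
    realized-kinship REML heritability, and trait correlation
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
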