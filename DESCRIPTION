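Package: petmix
Title: Bayesian Truncated-Poisson Mixture Modelling of ChIA-PET Chromatin
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls significant long-range chromatin interactions from
    cluster-level ChIA-PET data with a two-component (k-1)-truncated Poisson
    mixture model in a Bayesian framework. The noise rate of every anchor
    pair is linked to four systematic biases (local enrichment measured by
    self-ligation PETs, GC content, mappability, and genomic distance for
    intrachromosomal pairs), the signal rate is offset by a shared positive
    constant, and pair-specific mixing weights carry a Beta prior driven by
    marginal PET counts. Posterior inference is by adaptive
    Metropolis-within-Gibbs MCMC with split-Rhat convergence gating,
    posterior predictive checks, aggregate peak analysis (APA) with P2LL
    scoring, a synthetic-data generator with known ground truth, and a
    command-line pipeline over BEDPE/BED/bedGraph/FASTA inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
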