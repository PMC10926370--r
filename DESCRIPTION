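Package: helihybrid
Title: Genome Admixture Detection of Helicoverpa armigera-zea Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects hybridization between the invasive cotton bollworm
    (Helicoverpa armigera) and the native New World corn earworm
    (Helicoverpa zea) from multi-sample SNP genotype data. Implements
    site-level variant filtering, sliding-window linkage-disequilibrium
    pruning, maximum-likelihood K=2 global ancestry estimation (EM for the
    binomial admixture model, unsupervised and supervised), purity-based
    identification of unhybridized reference genomes, discovery of
    ancestry informative markers (AIMs), AIM-based ancestry scoring, and
    diagnostics for the reference-allele bias that joint variant callers
    introduce at low-coverage sites. Ships a two-population genotype
    simulator (Balding-Nichols divergence model with F1, backcross and
    arbitrarily admixed individuals, Poisson read depths, and emulation of
    the caller artifact that zero-coverage positions are emitted as
    homozygous reference) so the full pipeline is testable against known
    truth without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    vcfR,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
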