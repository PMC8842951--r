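Package: gametephase
Title: Haplotype Phasing and Read Partitioning from Single Gamete Cells
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs chromosome-scale parental haplotypes of a diploid
    individual from SNP calls of single haploid gamete cells (e.g. microspores)
    by majority voting over adjacent-SNP linkage, calls per-cell crossovers and
    haplotype blocks with a two-state hidden Markov model, partitions gamete
    cell short reads into two parental pools using the haplotype blocks, and
    normalizes each pool by k-mer depth to mimic regular parental WGS coverage
    for downstream trio-binning assembly. Includes a meiosis and
    MDA-amplification simulator with full ground truth, SNP- and cell-level QC
    filters, and evaluation metrics (hapmer-based PPV, switch error, crossover
    recovery) so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
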