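Package: petpeaks
Title: Model-Based Peak Calling for ChIA-PET Paired-End Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds protein binding sites from ChIA-PET paired-end tag (PET)
    data using both tags of every self-ligated PET. Implements linker
    filtering and PET classification (self-ligated, intra- and
    inter-chromosomal, via an elbow cut-off on the PET length histogram and
    PCR-duplicate removal), segmentation of the genome into regions of
    overlapping self-ligated PETs, and a two-dimensional mixture model per
    region in which each binding site contributes a pair of skew
    generalized t (SGT) tag peaks and noise is uniform, fitted by a
    penalized-likelihood ECME algorithm. Candidate sites are tested against
    local Poisson backgrounds and reported with Benjamini-Hochberg adjusted
    q-values in narrowPeak and tabular formats. Includes seeded simulators
    for reads, PET libraries and planted binding sites with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
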