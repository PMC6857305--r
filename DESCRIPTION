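Package: hrsig
Title: Mutational Phenotyping of Homologous Recombination Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic phenotyping of homologous-recombination (HR) deficient
    cell clones from somatic mutation catalogs. Builds 96-channel trinucleotide
    substitution spectra, extracts de novo mutational signatures by
    non-negative matrix factorization with cophenetic rank diagnostics, fits
    spectra against reference signature sets by non-negative least squares,
    classifies short deletions by sequence context (tandem repeat,
    microhomology, none) and into the 83-channel COSMIC indel scheme,
    classifies structural rearrangements into the 32-category clustered /
    non-clustered scheme with piecewise-constant-fit cluster detection,
    quantifies deletion and insertion events at CRISPR/Cas9 cut sites from
    amplicon reads, and provides seed-deterministic synthetic-data generators
    (signature-mixture catalogs, genomes with planted context-classified
    deletions, rearrangement catalogs) including a signature-separability
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    pracma,
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
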