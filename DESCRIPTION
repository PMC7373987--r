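Package: phasedinserts
Title: Phased Insert Design and Entropy Prediction for Low-Diversity Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequencing low-diversity amplicon libraries, such as
    ribozyme pools from in vitro selection, on Illumina instruments without
    sacrificing reads to PhiX. Designs sets of variable-length, base-balanced
    "phased inserts" that shift otherwise identical reads out of register,
    predicts the per-cycle nucleotide Shannon entropy of a library (analytically
    and by Monte-Carlo read simulation, with optional PhiX admixture),
    demultiplexes and trims phased 5'-RACE reads, classifies them as cleaved or
    uncleaved ribozyme products, and quantifies per-genotype self-cleavage
    activity (fraction cleaved), including single/double mutant activity
    matrices and a binomial model for the probability of failing to detect rare
    sequences. A ground-truthed synthetic FASTQ generator makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    graphics,
    grDevices,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
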