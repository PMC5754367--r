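Package: epitrio
Title: Allele-Resolved Epimutation Discovery at Sense-Antisense Gene Trios
Version: 0.1.0
Authors@R:
    person("epitrio", "developers", email = "epitrio@example.org",
           role = c("aut", "cre"))
Description: Tools to detect heritable secondary epimutations at
    bidirectional-promoter CpG islands shared by reverse-forward-reverse
    gene trios. Implements allele-resolved bisulfite clone epigram
    analysis with conversion-efficiency quality control, methylome-wide
    outlier (MVP) detection and control-cohort carrier screening from
    beta-value matrices, epi-linkage-disequilibrium estimation between
    adjacent CpG probes via an EM haplotype algorithm and the composite
    haplotype method, annotation scanning for tail-to-tail and
    head-to-head sense-antisense gene pairs and trio configurations,
    strand-aware antisense readthrough detection from stranded read
    intervals, splice-acceptor disruption consequence prediction, and
    rare-variant co-segregation filtering. A deterministic synthetic-data
    generator produces every input format so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
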