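Package: ptclickseq
Title: Particle-Templated ClickSeq and Crosslink Transition Analysis for Small Viral Genomes
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to profile genomic RNA exposure in partially disassembled
    virus particles from randomly primed, azido-terminated (ClickSeq-style)
    sequencing libraries, and to map RNA-capsid contacts from
    photoactivatable-ribonucleoside crosslinking (4SU) U-to-C transition
    signals. Includes a parameterised simulator of particle-templated
    libraries (hexamer priming restricted to exposed regions, geometric
    azido termination, 12N unique molecular identifiers, PCR duplication,
    crosslink-induced transitions), a native read-processing chain for
    small (under 5 kb) references (paired FASTQ parsing, UMI extraction,
    k-mer-seeded ungapped alignment, UMI deduplication, pileup), ratiometric
    coverage and priming-site statistics over a disassembly temperature
    series, crosslink fold-change signal tracks with depth masking and
    Kolmogorov-Smirnov condition tests, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
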