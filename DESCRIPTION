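Package: smorfkit
Title: Functional Assessment of Small Open Reading Frames
Version: 0.1.0
Authors@R: person("Packaged", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cataloguing and functionally assessing small open
    reading frames (smORFs) and short coding sequences (sCDS) in annotated
    genomes. Provides a six-frame ORF finder with annotation-based class
    assignment (sCDS, uORF, dORF, lncORF, pseudogene, intergenic) and
    catalogue curation; GC-ratio coding-potential statistics by class and
    length; scoring of hemizygous viability crosses and of multi-generation
    balancer-competition (Knight-Robertson) fitness tests, including a
    deterministic population-genetic null model, a stochastic simulator and
    maximum-likelihood selection-coefficient inference; proteomic
    detection-overlap, detection-rate and false-positive accounting; and
    integration of per-gene functional indicators into group summaries and
    functional fractions. A synthetic-data module generates genomes,
    crosses, competition populations and detection tables with known truth
    so that every stage can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
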