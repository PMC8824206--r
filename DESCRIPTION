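Package: pupminer
Title: Mining Polyphenol Utilization Proteins and Their Gene Clusters in
    Gut Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates microbial proteins as polyphenol utilization
    proteins (PUPs) by signature Pfam domain combinations, detects
    physically linked PUP gene clusters (PGCs) in annotated genomes,
    infers PGC substrates by majority vote over seed-family substrate
    groups, classifies homologs into subfamilies with sequence
    similarity networks, profiles abundance and prevalence of PUPs
    across genome collections grouped by taxonomy and geography, tests
    Pfam domain enrichment in gene clusters with the hypergeometric
    distribution, and summarises read-level PUP abundance (percent
    reads mapped, RPKM) in metagenome samples. Ships a transcription of
    the 26-family PUP seed catalog and seeded synthetic-data generators
    so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rtracklayer,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
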