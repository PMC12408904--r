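Package: proxitype
Title: Assembly-Free Sequence Typing with Proximity-Scored Read Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly-free multilocus sequence typing (MLST) directly from raw
    short- or long-read sequencing data. Reads are mapped against an allele
    database with a two-stage k-mer signature index, chained with a
    collinear-anchor dynamic programme, and aligned globally by anchor joining.
    Multi-mapping reads are resolved with the ConClave vote, optionally widened
    by proximity scoring so that error-prone long reads still support the true
    allele. Per-locus alleles are called from consensus pileups with depth,
    breadth, identity and consistency statistics, and imperfect consensus
    sequences are reassigned against the full database. A seeded simulator for
    MLST-like schemes and Illumina-/Nanopore-like reads is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    fastmatch,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
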