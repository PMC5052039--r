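Package: circkit
Title: Annotation and Quantification of Alternative Back-Splicing and
    Alternative Splicing in Circular RNAs
Version: 0.1.0
Authors@R: person("circkit", "developers", role = c("aut", "cre"),
    email = "circkit@example.org")
Description: Annotates back-splice junctions from RNA-seq chimeric-read
    evidence into exon-resolved circular RNA (circRNA) models, discovers
    previously unannotated exons inside circRNA loci, and quantifies
    alternative back-splicing (Percent Circularized-site Usage, PCU) and
    alternative splicing within circRNAs (PSI, PIR, PSU) against their
    linear cognate transcripts. Includes detection of orientation-opposite
    complementary sequence pairs in flanking introns whose competition is
    associated with alternative back-splice site selection, a seeded
    simulator producing complete synthetic inputs with ground truth, and a
    command-line interface tying the stages together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
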