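Package: radsexmark
Title: Sex-Specific RAD Marker Discovery and Synteny Assignment from RADseq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering sex chromosome systems from
    restriction-site-associated DNA sequencing (RADseq): demultiplexing of
    inline-barcoded reads with a restriction-overhang check, depth-supported
    RAD-tag calling, single-linkage Hamming clustering of tags into candidate
    loci with an allele-count filter, presence/absence identification of
    putative sex-specific markers, a raw-read confirmation step that removes
    false positives caused by depth-threshold dropout, heterogamety inference
    (XX/XY versus ZZ/ZW), and chromosome-level synteny assignment of the sex
    linkage group by an exact hypergeometric enrichment test over two-step
    BLAST tabular hits. Includes a synthetic RADseq read simulator with known
    XY/ZW architecture (sex-limited loci, diverged gametolog pairs, allelic
    dropout, sequencing error) so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
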