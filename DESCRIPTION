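Package: ampliguide
Title: Taxon-Specific CRISPR-Cas9 Guide Design and Host-Amplicon Depletion
    Simulation for 18S rRNA Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs taxon-specific CRISPR-Cas9 guide target sites inside
    "universal"-primer-flanked 18S rRNA V4 amplicons, so that a metazoan or
    plant host's amplicons are cleaved while protistan and fungal amplicons
    are left intact. Provides SILVA-style reference parsing, in-silico PCR
    with degenerate primers, PAM-adjacent protospacer enumeration, exact
    20-mer off-target screening against a microeukaryote reference, per-taxon
    guide databases with breadth statistics, sgRNA template-oligo assembly,
    and a simulator for the two-round Cas9 cut / PCR / SPRI size-selection
    workflow that predicts residual host fraction in mock communities. A
    synthetic-reference generator with planted target sites makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
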