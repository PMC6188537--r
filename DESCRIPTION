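Package: mcpminer
Title: Mining Multicopy Neuropeptide Precursors from Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery pipeline for multicopy neuropeptide precursors in
    translated transcriptomes. Scans protein sequences with PROSITE-style
    variable-gap motifs describing recurrent cleavage and amidation sites,
    models prohormone processing (signal peptide gate, dibasic and monobasic
    convertase cleavage, C-terminal amidation via a glycine donor), groups
    near-identical peptide paracopies into multicopy-peptide families with
    position-frequency consensus motifs, recovers divergent orthologs by
    reciprocal Smith-Waterman search, and confirms predicted peptides
    against observed monoisotopic masses within ppm tolerances. Includes a
    ground-truthed synthetic-data generator (decoy proteomes with planted
    precursors and matching mass lists) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
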