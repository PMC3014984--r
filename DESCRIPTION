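Package: binpat
Title: Binary-Patterned Combinatorial Protein Library Design and Screen Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the binary-code strategy of combinatorial protein
    design: degenerate-codon algebra over IUPAC ambiguity symbols, a template
    model for 102-residue four-helix bundles patterned with polar and nonpolar
    residues, exact big-integer library diversity, seeded in-silico library
    synthesis with an oligonucleotide-synthesis error model and frame/stop
    preselection, indel-aware validation of observed proteins against the
    designed pattern via class-aware global alignment, amphipathic-helix
    hydrophobic-moment geometry, and the statistics of auxotroph-rescue
    screens (complementation frequencies with exact confidence intervals,
    rescue probability, and library coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Alignment, Proteomics
RoxygenNote: 7.3.3
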