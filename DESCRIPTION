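Package: chardiag
Title: Character-Based Molecular Diagnoses for DNA Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts diagnostic nucleotide and amino-acid characters
    ("single pure character attributes") from per-marker multiple sequence
    alignments by exhaustive comparison of each species against all its
    congeners, reports them in dual alignment/reference-sequence
    coordinates, masks alignments with a Gblocks-style conserved-block
    selector, assesses the robustness of diagnoses across alternative
    alignments, and validates the whole procedure on simulated alignments
    with planted species-fixed differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
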