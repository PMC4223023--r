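Package: microsynteny
Title: Refining Syntenic Regions into Blocks of Perfectly Conserved Gene Order
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Refines pre-computed syntenic regions between two genomes into
    maximal blocks of perfectly conserved gene order. Resolves one-to-many and
    many-to-many ortholog groups into syntenic one-to-one pairs by sequence
    identity and gene order, detects breakpoints and peels out
    micro-rearranged blocks (local translocations and inversions), and finds
    external translocations of genes between syntenic regions. Also compares
    positional feature tracks (BED) between species over the resolved ortholog
    pairs via per-gene Z-score differences with a randomization null, and
    computes a k-mer Manhattan distance between region sequences. Includes a
    seedable synthetic genome-pair generator with planted rearrangements and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
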