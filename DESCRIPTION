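Package: g4scan
Title: Putative G-Quadruplex Sequence Scanning, cG/cC Scoring and a
    G4-Protein Interaction Record Store
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative G-quadruplex forming sequences (PQS) in DNA
    and RNA by matching the four-G-tract/three-loop motif grammar on both
    the sense and antisense strands with leftmost non-overlapping
    semantics, scores each hit with the cumulative cG/cC guanine and
    cytosine content scores, and provides a flat-file store with quick and
    advanced search over curated G-quadruplex-protein interaction records.
    Includes deterministic generators of motif-planted sequences and
    synthetic interaction records, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
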