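Package: lonr
Title: Lineage-Tree Detection of Within-Clone Selection in B-Cell Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects selection acting within individual B-cell clones from the
    shape of their somatic-hypermutation lineage trees. For every nucleotide
    substitution reconstructed on a tree branch, the log offspring number
    ratio (LONR) compares the number of sampled descendants below the mutated
    branch with the number below its unmutated sibling; selection in a
    sequence region is then assessed by an unequal-variance t-test between
    the LONR values of non-synonymous and synonymous substitutions. The
    package covers the full path from raw repertoire reads to reports:
    germline V/J assignment by ungapped sliding alignment, clonal grouping by
    V/J usage and junction length, truncation to the analysis window,
    neighbor-joining tree construction, Fitch parsimony ancestral
    reconstruction, mutation-event enumeration and classification,
    region/position-level statistics, and a forward-time neutral-expansion
    simulator used to calibrate the false-positive rate of the test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
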