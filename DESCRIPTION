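Package: sgpack
Title: De Novo Transcript Assembly by Bin Packing on Weighted Splicing Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers full-length transcript isoforms and their relative
    abundances from short RNA-seq reads. Reads are assembled into weighted
    splicing graphs (a de Bruijn front end with linear-path collapse and
    junction weighting), each graph is augmented with a source and sink and
    balanced at nodes whose in- and out-weights differ beyond a threshold,
    and the graph is then decomposed into s-t paths by an iterative
    bin-packing procedure whose node-local subproblems are 0-1 quadratic
    programs solved exactly after linearization to 0-1 integer programs.
    Includes a synthetic read simulator with alternative-splicing ground
    truth and an evaluation module for full-length recovery statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
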