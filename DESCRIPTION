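Package: bglccr
Title: Differential Expression of Glucose-Tolerant Beta-Glucosidase Genes
    Under Carbon Catabolite Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how microbial communities regulate glucose-tolerant
    versus non-glucose-tolerant GH1 family beta-glucosidase genes under carbon
    catabolite repression. Classifies genes as glucose tolerant from the conserved
    Trp168/Leu173 residues after six-frame translation and anchoring to a reference
    protein; computes per-gene relative abundances at DNA and RNA level,
    transcription efficiency (RNA/DNA) and the relative transcription efficiency
    statistic against a control treatment; cross-maps metagenome and
    metatranscriptome gene sets by reciprocal best hits at a percent-identity
    threshold; builds signed taxon co-occurrence networks with a correlation
    threshold and permutation test; and simulates sequences, abundance tables and
    qPCR copy numbers with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
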