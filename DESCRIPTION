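Package: mediascape
Title: Mediator Interactome Filtering and Super-Enhancer Analysis for
    Neural Stem Cell Regulatory Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to call chromatin-independent protein interactors of the
    Mediator complex from affinity-purification mass-spectrometry tables
    (Mascot/emPAI fold rules, nuclease/ethidium-bromide robustness), to define
    enhancers from Ep300 and H3K27ac peaks and identify super enhancers by
    ranked Med1 ChIP-seq signal with a hockey-stick tangent cutoff, to compute
    genome-wide summit colocalization between factors, to partition genes by
    super-enhancer assignment and broad H3K4me3 promoter domains, and to
    summarize strand-aware TSS metaprofiles and knockdown responses per gene
    category. Seeded synthetic-data generators with recorded ground truth let
    the whole pipeline run and be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
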