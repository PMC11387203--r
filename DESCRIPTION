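Package: mitoCUB
Title: Mitogenome Composition and Codon Usage Bias Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of insect mitochondrial genomes with a focus on codon
    usage bias. Reads annotated mitogenomes (FASTA plus feature tables or a
    GenBank flat-file subset), computes nucleotide composition and AT/GC
    strand skews per region class, relative synonymous codon usage (RSCU)
    with over/under-representation calls, start and stop codon summaries,
    PR2-bias and neutrality-plot diagnostics of mutation pressure versus
    selection, correspondence analysis of RSCU matrices, grand average of
    hydropathy (GRAVY) of the protein-coding genes, and sliding-window
    nucleotide diversity over aligned gene sets. Includes a synthetic
    mitogenome generator and a Jukes-Cantor family simulator so every stage
    of the pipeline can be exercised and validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
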