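Package: antigenrich
Title: Property Enrichment Analysis for Autoantigen Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking which structural and biological properties
    distinguish antigen gene sets (tumor-associated, autoimmunity-associated
    and natural-occurring autoantigens) from exon-length-controlled
    reference sets of protein-coding genes. Implements over-representation
    analysis via the hypergeometric tail for binary annotations (GO-like
    terms, pathways, protein domains, subcellular locations, sequence
    motifs), one-tailed Wilcoxon-Mann-Whitney rank tests for numeric
    per-gene features (mean exon length, SNP and somatic-mutation counts
    and their per-kilobase normalizations), Benjamini-Hochberg false
    discovery rate control with category-size and prevalence filters,
    construction of UNIVERSAL "ancient domain" gene sets from
    organism-by-domain tables, and per-organism molecular-mimicry
    enrichment from BLAST tabular hit files. A seeded synthetic-data
    generator produces every input format with planted effects so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
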