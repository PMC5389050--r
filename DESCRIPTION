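Package: SynBridge
Title: Synteny-Bridge Super-Scaffolding, Genetic-Map Anchoring and
    Domestication Scans for Draft Legume Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-usable implementations of the bespoke computational stages
    used to finish a draft legume genome and scan it for domestication
    signals: k-mer based sequencing-depth and genome-size estimation,
    selection of recent-peak orthologous synteny blocks and their use as
    bridges to join scaffolds into oriented super-scaffolds, anchoring of
    scaffolds to a genotyping-by-sequencing genetic map to build
    pseudo-chromosomes, post-genotyping variant-site filters for
    wild-relative resequencing data, Nei-Gojobori (1986) Ka/Ks estimation
    with peak partitioning, and cross-genome QTL coordinate translation
    through synteny blocks.  A synthetic-data module generates truth-tagged
    inputs (rearranged reference genomes, fragmented scaffolds, F4
    single-seed-descent populations, variant tables, codon-evolved ortholog
    pairs) so every stage can be exercised end-to-end against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
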