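Package: pepmapr
Title: Peptide-to-Genome Coordinate Mapping for Proteogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps peptides identified by mass spectrometry onto exact spliced
    genomic coordinates through an annotated proteome. Coding exons from a GTF
    annotation are projected onto protein sequences as protein exons carrying
    N-/C-terminal codon offsets, peptides are located in the proteome with a
    k-mer dictionary that treats leucine and isoleucine as indistinguishable
    and tolerates up to two amino-acid substitutions, and the resulting loci
    are written as genome-browser-ready BED12 tracks (colored by mapping
    uniqueness), BED12 tracks of post-translational modification sites, GTF
    features, and GCT matrices carrying multi-sample quantitation. A fixtures
    module generates self-consistent toy genomes, annotations, proteomes and
    peptide evidence so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
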