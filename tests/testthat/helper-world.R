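# Shared fixture world: built once per test run, written under tempdir().
# Covers single-/multi-exon transcripts on both strands, a tandem-repeat
# gene, a protein shared by two genes, two transcripts of one gene, and an
# incompletely annotated (missing start codon) transcript.

SHARED_PROTEIN <- "MSHAREDPEPTKAVGFNDQWERTYHKLMNP"

fixture_blueprints <- function() {
  list(
    transcript_blueprint(aa_len = 40, n_exons = 1, strand = "+", chrom = "chr1"),
    transcript_blueprint(aa_len = 40, n_exons = 2, strand = "+", chrom = "chr1"),
    transcript_blueprint(aa_len = 35, n_exons = 2, strand = "-", chrom = "chr1"),
    transcript_blueprint(aa_len = 45, n_exons = 3, strand = "+", chrom = "chr2"),
    transcript_blueprint(repeat_motif = "VPEPGCTK", repeat_copies = 5,
                         chrom = "chr2"),
    transcript_blueprint(protein_seq = SHARED_PROTEIN, n_exons = 2,
                         strand = "+", chrom = "chr3",
                         gene_id = "ENSG00000000106"),
    transcript_blueprint(protein_seq = SHARED_PROTEIN, n_exons = 1,
                         strand = "-", chrom = "chr3",
                         gene_id = "ENSG00000000107"),
    transcript_blueprint(aa_len = 32, n_exons = 2, strand = "+",
                         chrom = "chr4", gene_id = "ENSG00000000108",
                         protein_seq = "MTWNFRMSGENEKAVTRPQWDNMHESTYR"),
    transcript_blueprint(aa_len = 30, n_exons = 1, strand = "+",
                         chrom = "chr4", gene_id = "ENSG00000000108",
                         protein_seq = "MTWNFRMSGENEKAVTRPQWDNMHESTYR"),
    transcript_blueprint(aa_len = 33, n_exons = 2, strand = "+",
                         chrom = "chr5", incomplete_start_frame = 1)
  )
}

fixture_world <- generate_world(fixture_blueprints(), seed = 42L)
fixture_dir <- file.path(tempdir(), "pepmapr-fixture-world")
fixture_paths <- write_world(fixture_world, fixture_dir)
fixture_ann <- build_annotation(fixture_paths$fasta, fixture_paths$gtf)

world_meta <- function(world, transcript_id) {
  Filter(function(m) m$transcript_id == transcript_id, world$transcripts)[[1]]
}

# strand-aware extraction + translation of a mapping's blocks from the toy
# genome; the independent check that mapped coordinates really encode the
# peptide (I/L-blind comparisons happen at the caller)
translate_locus <- function(world, mapping) {
  chrom_seq <- world$genome[[mapping$chromosome]]
  pieces <- vapply(seq_len(nrow(mapping$blocks)), function(i)
    substring(chrom_seq, mapping$blocks[i, 1], mapping$blocks[i, 2]), "")
  nt <- paste(pieces, collapse = "")
  if (mapping$strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

# brute-force codon tiling of one exon: walk 3 bp at a time from the first
# residue's O_N bp and report the bp count of the last residue's codon
brute_cterm <- function(L, o_n) {
  used <- o_n
  while (used + 3 <= L) used <- used + 3
  if (used == L) 3L else L - used
}

# independent protein-exon oracle: derive aa spans and offsets of every exon
# from the truth table (which codon owns each genomic base), not from the
# offset formulas
tiled_exon_map <- function(world, tid) {
  meta <- world_meta(world, tid)
  tt <- as.data.frame(world$truth)
  tt <- tt[tt$transcript_id == tid, ]
  cod <- as.matrix(tt[, c("bp1", "bp2", "bp3")])
  rbindlist(lapply(seq_along(meta$exon_starts), function(e) {
    lo <- min(meta$exon_starts[e], meta$exon_ends[e])
    hi <- max(meta$exon_starts[e], meta$exon_ends[e])
    inside <- matrix(cod >= lo & cod <= hi & !is.na(cod), nrow = nrow(cod))
    hit <- which(rowSums(inside) > 0L)
    data.table(aa_start = tt$aa_index[min(hit)],
               aa_end = tt$aa_index[max(hit)],
               o_n = sum(inside[min(hit), ]),
               o_c = sum(inside[max(hit), ]))
  }))
}

# mini GTF/FASTA writers for hand-rolled parser tests
write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, feature, start, end, strand, frame, tx, gene,
                     extra = "") {
  paste(chrom, "test", feature, start, end, ".", strand, frame,
        sprintf('gene_id "%s"; transcript_id "%s";%s', gene, tx, extra),
        sep = "\t")
}

# explicit feature-test peptide evidence: 11 mappable peptides covering the
# structural cases plus one per unmappable category
feature_peptides <- function(world) {
  sub_pep <- function(tx, a, b) {
    substring(world_meta(world, tx)$protein, a, b)
  }
  p_single  <- sub_pep("ENST00000000001", 5, 20)
  p_phospho <- sub_pep("ENST00000000001", 22, 35)
  p_phospho <- sub("^(.)", "\\1(phospho)", p_phospho)
  p_junc    <- sub_pep("ENST00000000002", 8, 30)
  p_rev     <- sub_pep("ENST00000000003", 5, 30)
  p_2junc   <- sub_pep("ENST00000000004", 2, 44)   # spans both junctions
  p_repeat2 <- "VPEPGCTKVPEPGCTK"
  p_repeat1 <- "VPEPGCTK"
  p_shared  <- "SHAREDPEPTK"
  p_2forms  <- "AVTRPQWDNMHESTYR"
  p_multi_ph <- sub_pep("ENST00000000002", 14, 28)
  ch <- strsplit(p_multi_ph, "")[[1]]
  ch[2] <- paste0(ch[2], "(phospho)")
  ch[9] <- paste0(ch[9], "(phospho)")
  p_multi_ph <- paste(ch, collapse = "")
  p_two_types <- sub_pep("ENST00000000004", 20, 33)
  ch <- strsplit(p_two_types, "")[[1]]
  ch[1] <- paste0(ch[1], "(phospho)")
  ch[6] <- paste0(ch[6], "(acetyl)")
  p_two_types <- paste(ch, collapse = "")
  p_short <- "KLR"                                   # below word length
  p_incomplete <- sub_pep("ENST00000000010", 1, 12)  # covers truncated aa 1
  p_orphan <- "MQQWDERTAVNKPH"                       # FASTA-only protein

  mapped <- c(p_single, p_phospho, p_junc, p_rev, p_2junc, p_repeat2,
              p_repeat1, p_shared, p_2forms, p_multi_ph, p_two_types)
  list(mapped = mapped,
       unmappable = c(p_short, p_incomplete, p_orphan),
       lines = sprintf("s1\t%s\t%d\t%.4f",
                       c(mapped, p_short, p_incomplete, p_orphan),
                       seq_len(14), seq_len(14) / 7))
}

# fixture FASTA with one extra record absent from the GTF (sequence-database
# mismatch category)
fixture_fasta_with_orphan <- function() {
  f <- tempfile(fileext = ".fa")
  writeLines(c(readLines(fixture_paths$fasta),
               ">ORPHAN|ENST00000999999.1|ENSG00000999999.1",
               "MQQWDERTAVNKPHGGSW"), f)
  f
}
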