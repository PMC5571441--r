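test_that("read_gtf extracts CDS features in reading order per strand", {
  fwd <- write_lines_tmp(c(
    gtf_line("chr1", "CDS", 100, 130, "+", 0, "ENST00000000001.2", "ENSG00000000001.1",
             ' gene_name "MAPK3"; gene_type "protein_coding";'),
    gtf_line("chr1", "CDS", 137, 200, "+", 2, "ENST00000000001.2", "ENSG00000000001.1"),
    gtf_line("chr1", "exon", 90, 210, "+", ".", "ENST00000000001.2", "ENSG00000000001.1")
  ), ".gtf")
  tx <- read_gtf(fwd)
  expect_length(tx, 1L)
  model <- tx[["ENST00000000001"]]
  expect_s3_class(model, "TranscriptModel")
  expect_equal(model$gene_id, "ENSG00000000001")
  expect_equal(model$gene_name, "MAPK3")
  expect_equal(model$gene_biotype, "protein_coding")
  expect_equal(model$exons$start, c(100L, 137L))
  expect_equal(model$exons$end, c(130L, 200L))

  rev <- write_lines_tmp(c(
    gtf_line("chr1", "CDS", 100, 130, "-", 0, "ENST00000000002.1", "ENSG00000000002.1"),
    gtf_line("chr1", "CDS", 137, 200, "-", 0, "ENST00000000002.1", "ENSG00000000002.1")
  ), ".gtf")
  model <- read_gtf(rev)[["ENST00000000002"]]
  expect_equal(model$exons$start, c(137L, 100L))
  expect_equal(model$exons$end, c(200L, 130L))
})

test_that("read_gtf ignores non-CDS features, skips malformed lines, rejects strand conflicts", {
  no_cds <- write_lines_tmp(
    gtf_line("chr1", "exon", 100, 200, "+", ".", "ENST00000000001.1", "ENSG00000000001.1"),
    ".gtf")
  expect_length(read_gtf(no_cds), 0L)

  malformed <- write_lines_tmp(c(
    gtf_line("chr1", "CDS", 100, 130, "+", 0, "ENST00000000001.1", "ENSG00000000001.1"),
    "chr1\tonly\tthree"
  ), ".gtf")
  expect_warning(tx <- read_gtf(malformed), "line\\(s\\) 2")
  expect_length(tx, 1L)

  conflict <- write_lines_tmp(c(
    gtf_line("chr1", "CDS", 100, 130, "+", 0, "ENST00000000001.1", "ENSG00000000001.1"),
    gtf_line("chr1", "CDS", 150, 170, "-", 0, "ENST00000000001.1", "ENSG00000000001.1")
  ), ".gtf")
  expect_error(read_gtf(conflict), "ENST00000000001")
})

test_that("read_protein_fasta parses headers, strips stops, skips and deduplicates", {
  fa <- write_lines_tmp(c(
    ">X|ENST00000000001.2|ENSG00000000001.1", "MKLIVR",
    ">junk_no_id", "MKL",
    ">Y|ENST00000000002.1|ENSG00000000002.1", "MKLIVR*",
    ">Z|ENST00000000002.3|ENSG00000000002.1", "MKAAAA"
  ), ".fa")
  expect_warning(expect_warning(p <- read_protein_fasta(fa),
                                "junk_no_id"), "ENST00000000002")
  expect_equal(nrow(p), 2L)
  expect_equal(p$protein_id, c("X", "Y"))
  expect_equal(p$transcript_id, c("ENST00000000001", "ENST00000000002"))
  expect_equal(p$gene_id, c("ENSG00000000001", "ENSG00000000002"))
  expect_equal(p$sequence, c("MKLIVR", "MKLIVR"))  # stop stripped on Y
})

test_that("compute_cterm_offset follows the offset formula with normalization", {
  expect_equal(compute_cterm_offset(92L, 1L), 1L)  # X = 4 > 3 -> X mod 3
  expect_equal(compute_cterm_offset(90L, 3L), 3L)  # whole codons
  expect_equal(compute_cterm_offset(31L, 3L), 1L)
  expect_error(compute_cterm_offset(10L, 0L), "nterm_offset")
})

test_that("compute_cterm_offset agrees with brute-force codon tiling", {
  for (L in 3:60) for (o in 1:3) {
    if (o > L) next
    expect_equal(compute_cterm_offset(L, o), brute_cterm(L, o),
                 info = sprintf("L=%d o=%d", L, o))
  }
})

make_tx <- function(exons, strand = "+", chrom = "chr1",
                    tid = "ENST00000000001") {
  structure(list(transcript_id = tid, gene_id = "ENSG00000000001",
                 gene_name = "G", gene_biotype = "protein_coding",
                 chromosome = chrom, strand = strand,
                 exons = data.table::as.data.table(exons)),
            class = "TranscriptModel")
}

test_that("build_protein_exon_map handles single complete exons", {
  tx <- make_tx(data.frame(start = 1001L, end = 1090L, frame = 0L))
  prot <- strrep("A", 30)
  e <- build_protein_exon_map(tx, prot)
  expect_equal(e$status, "ok")
  expect_true(e$annotation_complete)
  expect_equal(e$exon_map$aa_start, 1L)
  expect_equal(e$exon_map$aa_end, 30L)
  expect_equal(e$exon_map$o_n, 3L)
  expect_equal(e$exon_map$o_c, 3L)
})

test_that("build_protein_exon_map shares junction residues and keeps offsets congruent", {
  # 31 + 64 = 95 bp for a 31-aa protein: aa 11's codon = bp 130 + bp 137-138
  tx <- make_tx(data.frame(start = c(100L, 137L), end = c(130L, 200L),
                           frame = c(0L, NA)))
  e <- build_protein_exon_map(tx, strrep("A", 31))
  expect_equal(e$exon_map$aa_start, c(1L, 11L))
  expect_equal(e$exon_map$aa_end, c(11L, 31L))
  expect_equal(e$exon_map$o_n, c(3L, 2L))
  expect_equal(e$exon_map$o_c[1], 1L)
  expect_equal((e$exon_map$o_c[1] + e$exon_map$o_n[2]) %% 3L, 0L)
})

test_that("stop-codon-including CDS dialects are trimmed with a warning", {
  # 93 bp CDS for a 30-aa protein: trailing 3 bp treated as the stop codon
  tx <- make_tx(data.frame(start = 1001L, end = 1093L, frame = 0L))
  expect_warning(e <- build_protein_exon_map(tx, strrep("A", 30)), "stop codon")
  expect_equal(e$exon_map$aa_end, 30L)
  expect_true(e$annotation_complete)
  # gross disagreement flags the entry unmappable
  tx2 <- make_tx(data.frame(start = 1001L, end = 1060L, frame = 0L))
  e2 <- build_protein_exon_map(tx2, strrep("A", 30))
  expect_equal(e2$status, "length_mismatch")
})

test_that("missing start codons shift the first offset by the annotated frame", {
  # frame 1: one bp of residue 1's codon is annotated, two lie upstream
  tx <- make_tx(data.frame(start = c(1001L, 1101L), end = c(1030L, 1130L),
                           frame = c(1L, NA)))
  e <- build_protein_exon_map(tx, strrep("A", 20))  # 60 bp = 3*20 - 2 + 2
  expect_equal(e$exon_map$o_n[1], 1L)
  expect_equal(e$aa_first, 2L)     # truncated residue 1 is not mappable
  expect_false(e$annotation_complete)
  expect_equal((e$exon_map$o_c[1] + e$exon_map$o_n[2]) %% 3L, 0L)
})

test_that("exon maps match the codon-tiling truth table across the fixture world", {
  for (m in fixture_world$transcripts) {
    entry <- Filter(function(e) e$transcript_id == m$transcript_id,
                    fixture_ann$entries)[[1]]
    expect_equal(entry$status, "ok")
    oracle <- tiled_exon_map(fixture_world, m$transcript_id)
    got <- entry$exon_map[, .(aa_start, aa_end, o_n, o_c)]
    if (m$lead > 0L) {
      # the truth table cannot see the missing upstream bases of residue 1,
      # so its first o_n equals the annotated bp, like the mapper's
      expect_equal(got$o_n[1], 3L - m$lead)
    }
    expect_equal(got, oracle, info = m$transcript_id)
    # bp conservation over the whole protein for complete annotations
    if (entry$annotation_complete) {
      expect_equal(sum(entry$exon_map$length), 3L * nchar(entry$sequence))
    }
    # adjacency congruence for every consecutive protein-exon pair
    em <- entry$exon_map
    if (nrow(em) > 1L) {
      expect_true(all((em$o_c[-nrow(em)] + em$o_n[-1]) %% 3L == 0L))
      # junction residue shared exactly when the codon is split
      shared <- em$o_c[-nrow(em)] < 3L
      expect_equal(em$aa_end[-nrow(em)] == em$aa_start[-1], shared)
    }
  }
})

test_that("build_annotation pairs FASTA with GTF and flags orphans", {
  fa <- fixture_fasta_with_orphan()
  ann <- build_annotation(fa, fixture_paths$gtf)
  st <- vapply(ann$entries, function(e) e$status, "")
  expect_equal(sum(st == "no_transcript"), 1L)
  expect_equal(sum(st == "ok"), length(fixture_world$transcripts))
})
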