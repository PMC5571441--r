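single_exon_entry <- function(start = 1001L, end = 1090L, strand = "+",
                              len = 30L) {
  tx <- structure(list(transcript_id = "ENST00000000001",
                       gene_id = "ENSG00000000001", gene_name = "G",
                       gene_biotype = "protein_coding", chromosome = "chr1",
                       strand = strand,
                       exons = data.table(start = start, end = end, frame = 0L)),
                  class = "TranscriptModel")
  build_protein_exon_map(tx, strrep("A", len))
}

junction_entry <- function() {
  tx <- structure(list(transcript_id = "ENST00000000001",
                       gene_id = "ENSG00000000001", gene_name = "G",
                       gene_biotype = "protein_coding", chromosome = "chr1",
                       strand = "+",
                       exons = data.table(start = c(100L, 137L),
                                          end = c(130L, 200L),
                                          frame = c(0L, NA))),
                  class = "TranscriptModel")
  build_protein_exon_map(tx, strrep("A", 31))
}

match_row <- function(s, e, mm = 0L, mmpos = integer(0)) {
  data.table(entry = 1L, protein_id = "P", s_A = s, e_A = e,
             mismatches = mm, mismatch_positions = list(mmpos))
}

test_that("forward-strand peptides project through the offset formulas", {
  mp <- peptide_to_genome(match_row(2L, 4L), single_exon_entry())
  expect_equal(mp$start, 1004L)  # dS = (2-1-1)*3 + 3 = 3
  expect_equal(mp$end, 1012L)    # dE = (4-1)*3 + 3 - 1 = 11
  expect_equal(nrow(mp$blocks), 1L)
})

test_that("reverse-strand peptides mirror the forward arithmetic", {
  mp <- peptide_to_genome(match_row(2L, 4L),
                          single_exon_entry(2001L, 2090L, "-"))
  expect_equal(mp$start, 2079L)  # S_E = 2090; S_A = S_E - dE
  expect_equal(mp$end, 2087L)
  expect_equal(nrow(mp$blocks), 1L)
})

test_that("junction-spanning peptides split codons across both blocks", {
  mp <- peptide_to_genome(match_row(10L, 12L), junction_entry())
  expect_equal(unname(mp$blocks), cbind(c(127L, 137L), c(130L, 141L)))
  expect_equal(sum(mp$blocks[, 2] - mp$blocks[, 1] + 1L), 9L)
})

test_that("strand mirroring yields mirror-image block structures", {
  # same exon lengths placed symmetrically around position 5000
  mirror <- function(x) 5000L - x + 1L
  tx_f <- structure(list(transcript_id = "T1", gene_id = "G1", gene_name = "",
                         gene_biotype = "", chromosome = "chr1", strand = "+",
                         exons = data.table(start = c(101L, 200L),
                                            end = c(131L, 263L),
                                            frame = c(0L, NA))),
                    class = "TranscriptModel")
  tx_r <- structure(list(transcript_id = "T2", gene_id = "G2", gene_name = "",
                         gene_biotype = "", chromosome = "chr1", strand = "-",
                         exons = data.table(start = mirror(c(131L, 263L)),
                                            end = mirror(c(101L, 200L)),
                                            frame = c(0L, NA))),
                    class = "TranscriptModel")
  prot <- strrep("A", 31)
  ef <- build_protein_exon_map(tx_f, prot)
  er <- build_protein_exon_map(tx_r, prot)
  for (se in list(c(1L, 5L), c(9L, 13L), c(10L, 12L), c(20L, 31L))) {
    mf <- peptide_to_genome(match_row(se[1], se[2]), ef)
    mr <- peptide_to_genome(match_row(se[1], se[2]), er)
    mirrored <- cbind(rev(mirror(mf$blocks[, 2])), rev(mirror(mf$blocks[, 1])))
    expect_equal(unname(mr$blocks), unname(mirrored))
  }
})

test_that("block lengths always sum to three times the peptide length", {
  set.seed(31)
  for (m in fixture_world$transcripts) {
    entry <- Filter(function(e) e$transcript_id == m$transcript_id,
                    fixture_ann$entries)[[1]]
    len <- nchar(entry$sequence)
    for (i in 1:8) {
      s <- sample(entry$aa_first:(entry$aa_last - 4L), 1)
      e <- min(entry$aa_last, s + sample(4:20, 1))
      mp <- peptide_to_genome(match_row(s, e), entry)
      expect_equal(sum(mp$blocks[, 2] - mp$blocks[, 1] + 1L),
                   3L * (e - s + 1L))
    }
  }
})

test_that("peptides overlapping an incompletely annotated start are skipped", {
  entry <- Filter(function(e) e$transcript_id == "ENST00000000010",
                  fixture_ann$entries)[[1]]
  expect_warning(mp <- peptide_to_genome(match_row(1L, 8L), entry),
                 "incomplete")
  expect_s3_class(mp, "SkippedMapping")
  expect_equal(mp$reason, "incomplete CDS")
  ok <- peptide_to_genome(match_row(2L, 9L), entry)
  expect_s3_class(ok, "MappedPeptide")
})

test_that("mappings found with spare mismatch budget equal the exact mapping", {
  idx <- fixture_ann$index
  pep <- substring(world_meta(fixture_world, "ENST00000000002")$protein, 8, 27)
  m0 <- find_peptide(idx, pep, 0)
  m2 <- find_peptide(idx, pep, 2)[mismatches == 0L]
  expect_equal(m0, m2, ignore_attr = TRUE)
  e <- fixture_ann$entries[[m0$entry[1]]]
  expect_equal(peptide_to_genome(m0[1], e)$blocks,
               peptide_to_genome(m2[1], e)$blocks)
})

test_that("PTM spans cover first-to-last site codons, one locus per type", {
  entry <- single_exon_entry()
  mp <- peptide_to_genome(match_row(2L, 4L), entry)
  one <- map_ptms(data.table(offset = 0L, name = "phospho"), mp, entry)
  expect_length(one, 1L)
  expect_equal(one[[1]]$thick_start, 1004L)
  expect_equal(one[[1]]$thick_end, 1006L)

  both <- map_ptms(data.table(offset = c(0L, 2L), name = c("phospho", "phospho")),
                   mp, entry)
  expect_length(both, 1L)  # same type collapses to first..last site
  expect_equal(both[[1]]$thick_start, 1004L)
  expect_equal(both[[1]]$thick_end, 1012L)

  two <- map_ptms(data.table(offset = c(0L, 2L), name = c("phospho", "acetyl")),
                  mp, entry)
  expect_length(two, 2L)
  expect_setequal(vapply(two, `[[`, "", "ptm_type"), c("phospho", "acetyl"))

  expect_error(map_ptms(data.table(offset = 5L, name = "phospho"), mp, entry),
               "outside")
})

test_that("PTM spans on the reverse strand stay inside the peptide locus", {
  entry <- single_exon_entry(2001L, 2090L, "-")
  mp <- peptide_to_genome(match_row(2L, 6L), entry)
  ptm <- map_ptms(data.table(offset = 4L, name = "phospho"), mp, entry)[[1]]
  expect_equal(ptm$thick_end - ptm$thick_start + 1L, 3L)
  expect_gte(ptm$thick_start, mp$start)
  expect_lte(ptm$thick_end, mp$end)
})

fake_mapping <- function(chrom, start, end, tid, gid, strand = "+") {
  structure(list(chromosome = chrom, strand = strand, start = start,
                 end = end, blocks = cbind(start, end),
                 transcript_ids = tid, gene_ids = gid, gene_name = "",
                 gene_biotype = "", s_A = 1L, e_A = 5L, mismatches = 0L,
                 mismatch_positions = integer(0)),
            class = "MappedPeptide")
}

test_that("uniqueness classes follow the track color semantics", {
  # one locus, one transcript -> red
  one <- classify_uniqueness(list(fake_mapping("chr1", 10L, 24L, "T1", "G1")))
  expect_equal(one[[1]]$uniqueness, "unique_transcript")

  # identical locus from two transcripts of one gene -> merged, black
  shared <- classify_uniqueness(list(
    fake_mapping("chr1", 10L, 24L, "T1", "G1"),
    fake_mapping("chr1", 10L, 24L, "T2", "G1")))
  expect_length(shared, 1L)
  expect_equal(shared[[1]]$transcript_ids, c("T1", "T2"))
  expect_equal(shared[[1]]$uniqueness, "unique_gene")

  # loci in two genes -> grey
  multi <- classify_uniqueness(list(
    fake_mapping("chr1", 10L, 24L, "T1", "G1"),
    fake_mapping("chr2", 50L, 64L, "T9", "G2")))
  expect_true(all(vapply(multi, `[[`, "", "uniqueness") == "multi_gene"))

  # several loci within one transcript (tandem repeat) stay black, not grey
  rep2 <- classify_uniqueness(list(
    fake_mapping("chr1", 10L, 24L, "T1", "G1"),
    fake_mapping("chr1", 34L, 48L, "T1", "G1")))
  expect_true(all(vapply(rep2, `[[`, "", "uniqueness") == "unique_gene"))
})

test_that("translating mapped blocks recovers the peptide (I/L-blind)", {
  set.seed(13)
  for (m in fixture_world$transcripts) {
    entry <- Filter(function(e) e$transcript_id == m$transcript_id,
                    fixture_ann$entries)[[1]]
    for (i in 1:4) {
      s <- sample(entry$aa_first:(entry$aa_last - 6L), 1)
      e <- min(entry$aa_last, s + sample(6:25, 1))
      mp <- peptide_to_genome(match_row(s, e), entry)
      pep <- substring(entry$sequence, s, e)
      expect_equal(normalize_sequence(translate_locus(fixture_world, mp)),
                   normalize_sequence(pep))
    }
  }
})
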