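## Fixture generator: self-consistent toy genome + GTF + translated protein
## FASTA + peptide evidence, with a per-residue codon-coordinate truth table
## used as the independent oracle in tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  C = c("TGT", "TGC"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG",
  N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG",
  Y = c("TAT", "TAC")
)

reverse_translate <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    cs <- CODON_TABLE[[a]]
    if (is.null(cs)) stop("cannot reverse-translate residue ", a)
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, ""), collapse = "")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# split `total` bp into n pieces, each at least min_len
split_lengths <- function(total, n, min_len = 3L) {
  if (n == 1L) return(total)
  stopifnot(total >= n * min_len)
  extra <- total - n * min_len
  w <- runif(n)
  add <- floor(extra * w / sum(w))
  add[n] <- extra - sum(add[-n])
  as.integer(min_len + add)
}

#' Blueprint for one toy transcript
#'
#' @param aa_len Protein length (ignored when `protein_seq` given).
#' @param n_exons Number of coding exons.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name.
#' @param gene_id,transcript_id,protein_id Identifiers; auto-assigned when
#'   `NULL`.
#' @param protein_seq Explicit protein sequence (must start with a residue
#'   in the standard 20-letter alphabet).
#' @param repeat_motif,repeat_copies When set, the protein is built as
#'   `M + motif x copies + 3 random residues`, giving tandem-repeat loci.
#' @param incomplete_start_frame 0 for complete annotations; 1 or 2 marks a
#'   missing start codon: the annotation omits `3 - frame` bp of the first
#'   residue's codon and the first CDS line carries that frame.
#' @return A blueprint list consumed by [generate_world()].
#' @export
transcript_blueprint <- function(aa_len = 30L, n_exons = 1L, strand = "+",
                                 chrom = "chrZ", gene_id = NULL,
                                 transcript_id = NULL, protein_id = NULL,
                                 protein_seq = NULL, repeat_motif = NULL,
                                 repeat_copies = 5L,
                                 incomplete_start_frame = 0L) {
  list(aa_len = aa_len, n_exons = as.integer(n_exons), strand = strand,
       chrom = chrom, gene_id = gene_id, transcript_id = transcript_id,
       protein_id = protein_id, protein_seq = protein_seq,
       repeat_motif = repeat_motif, repeat_copies = repeat_copies,
       incomplete_start_frame = as.integer(incomplete_start_frame))
}

#' Generate a self-consistent toy world
#'
#' Builds, deterministically under `seed`, a toy genome sequence, a GTF
#' annotation (CDS + exon features with correct frames), the translated
#' protein FASTA, and a truth table giving the genomic coordinates of every
#' residue's codon. The truth table is derived by walking the annotated
#' exons base-by-base in reading order — independent of the offset
#' arithmetic used by the mapper — and is the oracle for round-trip tests.
#' Translating each transcript's spliced CDS from the generated genome
#' always reproduces its FASTA protein.
#'
#' @param transcripts List of [transcript_blueprint()]s.
#' @param seed RNG seed.
#' @param intron_range,gap_range Ranges (bp) for intron lengths and for the
#'   spacing between transcripts on a chromosome.
#' @return A `toy_world` list: `genome` (named character vector of
#'   chromosome sequences), `gtf_lines`, `fasta_lines`, `proteins`
#'   (data.table of ids and sequences), `truth` (data.table: `protein_id`,
#'   `transcript_id`, `aa_index`, `bp1..bp3` genomic codon positions in
#'   reading order, NA for bases missing from incomplete annotations,
#'   `chrom`, `strand`), and `transcripts` (per-transcript metadata).
#' @export
generate_world <- function(transcripts, seed = 1L,
                           intron_range = c(30L, 120L),
                           gap_range = c(200L, 400L)) {
  set.seed(seed)
  cursor <- list()
  exon_registry <- list()   # per chrom: list of (start, end, nt)
  gtf_lines <- character(0)
  fasta_lines <- character(0)
  truth <- list()
  meta <- list()

  for (i in seq_along(transcripts)) {
    bp <- transcripts[[i]]
    gene_id <- bp$gene_id %||% sprintf("ENSG%011d", i)
    tx_id <- bp$transcript_id %||% sprintf("ENST%011d", i)
    prot_id <- bp$protein_id %||% sprintf("PROT%d", i)
    gene_name <- sprintf("GENE%s", sub("^ENSG0*", "", gene_id))

    protein <- if (!is.null(bp$protein_seq)) {
      bp$protein_seq
    } else if (!is.null(bp$repeat_motif)) {
      paste0("M", strrep(bp$repeat_motif, bp$repeat_copies),
             paste(sample(AA20, 3L, replace = TRUE), collapse = ""))
    } else {
      paste0("M", paste(sample(AA20, bp$aa_len - 1L, replace = TRUE),
                        collapse = ""))
    }
    len <- nchar(protein)
    cds <- reverse_translate(protein)

    f1 <- bp$incomplete_start_frame
    lead <- (3L - f1) %% 3L
    cds_ann <- substring(cds, lead + 1L)      # annotated part of the CDS
    total <- nchar(cds_ann)
    stopifnot(bp$n_exons * 3L <= total)
    exon_len <- split_lengths(total, bp$n_exons)

    # genomic placement
    if (is.null(cursor[[bp$chrom]])) cursor[[bp$chrom]] <- 0L
    start0 <- cursor[[bp$chrom]] +
      sample(seq(gap_range[1], gap_range[2]), 1L)
    introns <- if (bp$n_exons > 1L)
      sample(seq(intron_range[1], intron_range[2]), bp$n_exons - 1L,
             replace = TRUE) else integer(0)
    span <- sum(exon_len) + sum(introns)

    # genomic intervals, 5'->3' in genome orientation
    g_lens <- if (bp$strand == "+") exon_len else rev(exon_len)
    g_starts <- integer(bp$n_exons)
    g_ends <- integer(bp$n_exons)
    at <- start0 + 1L
    g_introns <- if (bp$strand == "+") introns else rev(introns)
    for (e in seq_len(bp$n_exons)) {
      g_starts[e] <- at
      g_ends[e] <- at + g_lens[e] - 1L
      at <- g_ends[e] + 1L + if (e < bp$n_exons) g_introns[e] else 0L
    }
    cursor[[bp$chrom]] <- start0 + span

    # reading-order view of the intervals
    if (bp$strand == "+") {
      r_starts <- g_starts; r_ends <- g_ends
    } else {
      r_starts <- rev(g_starts); r_ends <- rev(g_ends)
    }

    # slice annotated CDS into reading-order pieces, register genome nt
    piece_off <- cumsum(c(0L, head(exon_len, -1L)))
    for (e in seq_len(bp$n_exons)) {
      piece <- substring(cds_ann, piece_off[e] + 1L, piece_off[e] + exon_len[e])
      nt <- if (bp$strand == "+") piece else revcomp(piece)
      exon_registry[[bp$chrom]] <- c(exon_registry[[bp$chrom]],
        list(list(start = r_starts[e], end = r_ends[e], nt = nt)))
    }

    # GTF lines (CDS with frame, plus exon features the reader must ignore)
    frames <- (3L - ((lead + piece_off) %% 3L)) %% 3L
    for (e in seq_len(bp$n_exons)) {
      attrs <- sprintf('gene_id "%s.1"; transcript_id "%s.1"; gene_name "%s"; gene_type "protein_coding";',
                       gene_id, tx_id, gene_name)
      gtf_lines <- c(gtf_lines,
        paste(bp$chrom, "toy", "exon", r_starts[e], r_ends[e], ".",
              bp$strand, ".", attrs, sep = "\t"),
        paste(bp$chrom, "toy", "CDS", r_starts[e], r_ends[e], ".",
              bp$strand, frames[e], attrs, sep = "\t"))
    }

    fasta_lines <- c(fasta_lines,
                     sprintf(">%s|%s.1|%s.1 %s", prot_id, tx_id, gene_id, gene_name),
                     protein)

    # truth table: genomic position of every annotated coding base, in
    # reading order, with the missing lead bases of incomplete starts as NA
    pos <- unlist(lapply(seq_len(bp$n_exons), function(e) {
      if (bp$strand == "+") seq(r_starts[e], r_ends[e])
      else seq(r_ends[e], r_starts[e])
    }))
    virt <- c(rep(NA_integer_, lead), pos)
    n_cod <- length(virt) %/% 3L
    codons <- matrix(virt[seq_len(n_cod * 3L)], ncol = 3L, byrow = TRUE)
    truth[[i]] <- data.table(
      protein_id = prot_id, transcript_id = tx_id, gene_id = gene_id,
      aa_index = seq_len(n_cod),
      bp1 = codons[, 1L], bp2 = codons[, 2L], bp3 = codons[, 3L],
      chrom = bp$chrom, strand = bp$strand
    )
    meta[[i]] <- list(protein_id = prot_id, transcript_id = tx_id,
                      gene_id = gene_id, gene_name = gene_name,
                      chrom = bp$chrom, strand = bp$strand,
                      protein = protein, cds = cds, lead = lead,
                      exon_starts = r_starts, exon_ends = r_ends)
  }

  # assemble chromosome sequences: random background, exons spliced in
  genome <- vapply(names(cursor), function(ch) {
    chrom_len <- cursor[[ch]] + 100L
    chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    for (ex in exon_registry[[ch]]) {
      chars[ex$start:ex$end] <- strsplit(ex$nt, "")[[1]]
    }
    paste(chars, collapse = "")
  }, "")

  structure(list(genome = genome, gtf_lines = gtf_lines,
                 fasta_lines = fasta_lines,
                 proteins = rbindlist(lapply(meta, function(m)
                   data.table(protein_id = m$protein_id,
                              transcript_id = m$transcript_id,
                              gene_id = m$gene_id, sequence = m$protein))),
                 truth = rbindlist(truth), transcripts = meta),
            class = "toy_world")
}

#' Write a toy world's files to a directory
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`genome`, `gtf`, `fasta`), invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                fasta = file.path(dir, "proteins.fa"))
  writeLines(unlist(lapply(names(world$genome), function(ch)
    c(paste0(">", ch), world$genome[[ch]]))), paths$genome)
  writeLines(world$gtf_lines, paths$gtf)
  writeLines(world$fasta_lines, paths$fasta)
  invisible(paths)
}

# genomic blocks of residues [a1, a2] of one transcript, from the truth
# table alone (merge runs of consecutive positions; ascending output)
truth_blocks <- function(truth_tx, a1, a2) {
  rows <- truth_tx[truth_tx$aa_index >= a1 & truth_tx$aa_index <= a2, ]
  pos <- as.integer(t(as.matrix(rows[, c("bp1", "bp2", "bp3"), with = FALSE])))
  stopifnot(!anyNA(pos))
  if (rows$strand[1] == "-") pos <- rev(pos)   # ascending
  breaks <- which(diff(pos) != 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))]
  cbind(starts, ends)
}

#' Reference all-alignments peptide scan
#'
#' Brute-force scanner used as the independent oracle for the k-mer search:
#' slides the J-normalized peptide over every alignment of every protein and
#' reports alignments with Hamming distance at most `m`. No dictionary, no
#' pigeonhole split.
#'
#' @param seqs Character vector of protein sequences (raw; normalized
#'   internally).
#' @param peptide Peptide sequence.
#' @param m Allowed mismatches.
#' @return `data.table` with `entry` (index into `seqs`), `s_A`,
#'   `mismatches`.
#' @export
naive_peptide_scan <- function(seqs, peptide, m = 0L) {
  pep <- normalize_sequence(toupper(peptide))
  L <- nchar(pep)
  pr <- charToRaw(pep)
  out <- list()
  for (i in seq_along(seqs)) {
    sr <- charToRaw(normalize_sequence(toupper(seqs[i])))
    n <- length(sr)
    if (n < L) next
    for (s in seq_len(n - L + 1L)) {
      d <- sum(sr[s:(s + L - 1L)] != pr)
      if (d <= m) out[[length(out) + 1L]] <-
          data.table(entry = i, s_A = s, mismatches = as.integer(d))
    }
  }
  if (!length(out))
    return(data.table(entry = integer(), s_A = integer(),
                      mismatches = integer()))
  rbindlist(out)
}

#' Sample peptide evidence with known truth from a toy world
#'
#' Draws tryptic-like peptides (cut after K/R, up to two missed cleavages,
#' falling back to random substrings when no fragment fits the length range)
#' from the world's proteins, optionally plants 1-2 amino-acid substitutions
#' and phosphosite annotations, and records the expected genomic locus of the
#' source occurrence from the truth table.
#'
#' @param world A [generate_world()] result.
#' @param n Number of peptides.
#' @param length_range Min/max peptide length (residues).
#' @param mutation_rate Fraction of peptides receiving planted substitutions
#'   (each mutated peptide gets 1 or 2, never at an I/L-equivalent residue).
#' @param ptm_rate Fraction of peptides receiving phospho annotations on 1-2
#'   S/T/Y residues (peptides lacking S/T/Y stay unmodified).
#' @param seed RNG seed.
#' @param samples Sample identifiers cycled over the peptides.
#' @return A `data.table` truth set, one row per peptide: input fields
#'   (`sample`, `annotated`, `psm_count`, `quant`), provenance
#'   (`source_protein`, `source_transcript`, `s_A`, `e_A`, `n_mut`,
#'   `ptm_offsets` list), and expected mapping (`chrom`, `strand`,
#'   `exp_start`, `exp_end`, `exp_blocks` list matrix, `exp_ptm_start`,
#'   `exp_ptm_end`). Serialize with [write_peptides()].
#' @export
generate_peptides <- function(world, n = 20L, length_range = c(8L, 25L),
                              mutation_rate = 0, ptm_rate = 0, seed = 1L,
                              samples = "sample1") {
  set.seed(seed)
  usable <- Filter(function(m) m$lead == 0L, world$transcripts)
  stopifnot(length(usable) > 0L)
  rows <- vector("list", n)
  seen <- character(0)   # (sample, annotated) pairs must stay unique
  tries <- 0L
  i <- 1L
  while (i <= n && tries < 50L * n) {
    tries <- tries + 1L
    m <- usable[[sample(length(usable), 1L)]]
    prot <- m$protein
    len <- nchar(prot)
    # tryptic fragments with <= 2 missed cleavages
    cuts <- gregexpr("[KR]", prot)[[1]]
    cuts <- cuts[cuts > 0 & cuts < len]
    bounds <- c(0L, cuts, len)
    frags <- list()
    for (a in seq_len(length(bounds) - 1L)) {
      for (b in a:min(a + 2L, length(bounds) - 1L)) {
        s <- bounds[a] + 1L
        e <- bounds[b + 1L]
        w <- e - s + 1L
        if (w >= length_range[1] && w <= length_range[2])
          frags[[length(frags) + 1L]] <- c(s, e)
      }
    }
    if (length(frags)) {
      se <- frags[[sample(length(frags), 1L)]]
    } else {
      w <- sample(seq(length_range[1], min(length_range[2], len)), 1L)
      s <- sample(seq_len(len - w + 1L), 1L)
      se <- c(s, s + w - 1L)
    }
    s_A <- se[1]; e_A <- se[2]
    pep <- substring(prot, s_A, e_A)
    plen <- nchar(pep)

    # planted substitutions (always a real mismatch after J-normalization)
    n_mut <- 0L
    if (runif(1) < mutation_rate) {
      n_mut <- sample(1:2, 1L)
      mut_pos <- sample(plen, n_mut)
      chars <- strsplit(pep, "")[[1]]
      for (p in mut_pos) {
        fromj <- normalize_sequence(chars[p])
        cand <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "K", "L", "M",
                          "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                        if (fromj == "J") "L" else chars[p])
        chars[p] <- sample(cand, 1L)
      }
      pep <- paste(chars, collapse = "")
    }

    # planted phospho sites
    ptm_offsets <- integer(0)
    if (runif(1) < ptm_rate) {
      sty <- which(strsplit(pep, "")[[1]] %in% c("S", "T", "Y"))
      if (length(sty)) {
        ptm_offsets <- sort(sample(sty, min(length(sty), sample(1:2, 1L)))) - 1L
      }
    }
    annotated <- if (length(ptm_offsets)) {
      chars <- strsplit(pep, "")[[1]]
      chars[ptm_offsets + 1L] <- paste0(chars[ptm_offsets + 1L], "(phospho)")
      paste(chars, collapse = "")
    } else pep

    this_sample <- samples[(i - 1L) %% length(samples) + 1L]
    key <- paste(this_sample, annotated, sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)

    tb <- truth_blocks(world$truth[world$truth$transcript_id == m$transcript_id, ],
                       s_A, e_A)
    ptm_span <- if (length(ptm_offsets)) {
      pb <- truth_blocks(world$truth[world$truth$transcript_id == m$transcript_id, ],
                         s_A + min(ptm_offsets), s_A + max(ptm_offsets))
      c(min(pb[, 1L]), max(pb[, 2L]))
    } else c(NA_integer_, NA_integer_)

    rows[[i]] <- data.table(
      sample = this_sample,
      annotated = annotated,
      psm_count = sample(1:9, 1L),
      quant = round(rnorm(1), 4L),
      source_protein = m$protein_id,
      source_transcript = m$transcript_id,
      s_A = s_A, e_A = e_A, n_mut = n_mut,
      ptm_offsets = list(ptm_offsets),
      chrom = m$chrom, strand = m$strand,
      exp_start = min(tb[, 1L]), exp_end = max(tb[, 2L]),
      exp_blocks = list(tb),
      exp_ptm_start = ptm_span[1], exp_ptm_end = ptm_span[2]
    )
    i <- i + 1L
  }
  rbindlist(rows[!vapply(rows, is.null, TRUE)])
}

#' Write a generated peptide set as an evidence input file
#'
#' @param pepset A [generate_peptides()] truth set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(pepset, path) {
  writeLines(sprintf("%s\t%s\t%d\t%.4f", pepset$sample, pepset$annotated,
                     pepset$psm_count, pepset$quant), path)
  invisible(path)
}
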