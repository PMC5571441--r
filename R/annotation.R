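## Annotation index: GTF CDS parsing, protein FASTA parsing, and the
## protein-exon <-> genomic-exon coordinate bridge with codon offsets.

# Extract the value of `key "value";` from GTF attribute strings (vectorized).
gtf_attr <- function(attrs, key) {
  pat <- sprintf('%s "([^"]*)"', key)
  out <- rep("", length(attrs))
  m <- regexpr(pat, attrs)
  hit <- m > 0L
  out[hit] <- sub(pat, "\\1", regmatches(attrs, m))
  out
}

# Pull a canonical identifier out of a raw id/header using `pattern`;
# fall back to the raw value with a trailing ".N" version stripped.
extract_id <- function(x, pattern) {
  out <- sub("\\.\\d+$", "", x)
  m <- regexpr(pattern, x)
  hit <- m > 0L
  out[hit] <- regmatches(x, m)
  out
}

#' Read coding-sequence features from a GTF annotation
#'
#' Extracts `CDS` features and assembles one transcript model per transcript,
#' with exons ordered in reading (translation) direction: ascending genomic
#' coordinates on the forward strand, descending on the reverse strand.
#' All non-CDS features (`exon`, UTRs, `stop_codon`, ...) are ignored.
#'
#' @param path Path to a GTF file (tab-separated, 9 columns, 1-based
#'   inclusive coordinates, attributes as `key "value";` pairs).
#' @param transcript_id_pattern,gene_id_pattern Regular expressions used to
#'   extract canonical transcript/gene identifiers from the attribute column.
#'   Defaults match Ensembl/GENCODE human identifiers (`ENST`/`ENSG` followed
#'   by 11 digits), which also strips `.N` version suffixes.
#' @return A named list of `TranscriptModel` objects (name = transcript id).
#'   Each holds `transcript_id`, `gene_id`, `gene_name`, `gene_biotype`,
#'   `chromosome`, `strand`, and `exons` (a `data.table` with `start`, `end`,
#'   `frame` in reading order).
#' @details Malformed lines (wrong column count) are skipped with a warning
#'   naming their line numbers. A transcript whose CDS features disagree on
#'   strand or chromosome is a hard error.
#' @export
read_gtf <- function(path,
                     transcript_id_pattern = "ENST\\d{11}",
                     gene_id_pattern = "ENSG\\d{11}") {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  ln <- ln[keep]
  if (!length(lines)) return(structure(list(), names = character()))

  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 9L
  if (any(bad)) {
    warning(sprintf("skipping %d malformed GTF line(s) (wrong column count): line(s) %s",
                    sum(bad), paste(ln[bad], collapse = ", ")))
    parts <- parts[!bad]
    ln <- ln[!bad]
  }
  if (!length(parts)) return(structure(list(), names = character()))

  m <- do.call(rbind, parts)
  dt <- data.table(chrom = m[, 1], feature = m[, 3],
                   start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   strand = m[, 7], frame = m[, 8], attrs = m[, 9])
  dt <- dt[feature == "CDS"]
  if (!nrow(dt)) return(structure(list(), names = character()))

  dt[, transcript_id := extract_id(gtf_attr(attrs, "transcript_id"), transcript_id_pattern)]
  dt[, gene_id := extract_id(gtf_attr(attrs, "gene_id"), gene_id_pattern)]
  dt[, gene_name := gtf_attr(attrs, "gene_name")]
  bt <- gtf_attr(dt$attrs, "gene_biotype")
  ty <- gtf_attr(dt$attrs, "gene_type")
  dt[, gene_biotype := fifelse(nzchar(bt), bt, ty)]
  dt[, frame_i := suppressWarnings(as.integer(frame))]

  models <- lapply(split(dt, by = "transcript_id", sorted = TRUE), function(sub) {
    strands <- unique(sub$strand)
    if (length(strands) > 1L)
      stop("conflicting strands for transcript ", sub$transcript_id[1])
    if (length(unique(sub$chrom)) > 1L)
      stop("conflicting chromosomes for transcript ", sub$transcript_id[1])
    ord <- if (strands == "+") order(sub$start) else order(-sub$start)
    sub <- sub[ord]
    structure(list(
      transcript_id = sub$transcript_id[1],
      gene_id       = sub$gene_id[1],
      gene_name     = sub$gene_name[which(nzchar(sub$gene_name))[1]] %||% "",
      gene_biotype  = sub$gene_biotype[which(nzchar(sub$gene_biotype))[1]] %||% "",
      chromosome    = sub$chrom[1],
      strand        = strands,
      exons         = sub[, .(start, end, frame = frame_i)]
    ), class = "TranscriptModel")
  })
  models
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Read translated protein sequences from FASTA
#'
#' Headers are expected to carry the transcript (and usually gene) identifier
#' in `|`-separated fields, as in GENCODE `pc_translations` files. Sequences
#' are uppercased and a trailing stop symbol `*` is stripped.
#'
#' @inheritParams read_gtf
#' @param path Path to the protein FASTA file.
#' @return A `data.table` with columns `protein_id` (first header field),
#'   `transcript_id`, `gene_id` (empty string when absent) and `sequence`.
#'   Records whose header contains no transcript identifier are skipped with
#'   a warning; for duplicated transcript ids the first record wins.
#' @export
read_protein_fasta <- function(path,
                               transcript_id_pattern = "ENST\\d{11}",
                               gene_id_pattern = "ENSG\\d{11}") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  seqs <- sub("\\*$", "", toupper(as.character(aa)))

  tm <- regexpr(transcript_id_pattern, headers)
  hit <- tm > 0L
  if (any(!hit)) {
    warning(sprintf("skipping %d FASTA record(s) without a transcript identifier: %s",
                    sum(!hit), paste(headers[!hit], collapse = ", ")))
  }
  headers <- headers[hit]
  seqs <- seqs[hit]
  tid <- regmatches(names(aa), tm)

  gm <- regexpr(gene_id_pattern, headers)
  gid <- rep("", length(headers))
  gid[gm > 0L] <- regmatches(headers, gm)

  pid <- vapply(strsplit(headers, "|", fixed = TRUE), `[`, "", 1L)
  pid <- sub("\\s.*$", "", pid)

  dup <- duplicated(tid)
  if (any(dup)) {
    warning(sprintf("duplicate transcript id(s) in FASTA, keeping first record: %s",
                    paste(unique(tid[dup]), collapse = ", ")))
  }
  data.table(protein_id = pid[!dup], transcript_id = tid[!dup],
             gene_id = gid[!dup], sequence = seqs[!dup])
}

#' C-terminal codon offset of a protein exon
#'
#' Number of base pairs of a coding exon contributing to the codon of the
#' exon's last amino acid, given the exon length and the N-terminal offset
#' (bp contributing to the first amino acid's codon). Computed as
#' `X = (L mod 3) - O_N + 3`, with `X mod 3` taken when `X > 3` and `X = 0`
#' normalized to 3 so the result stays in {1,2,3}.
#'
#' @param exon_length_bp Exon length(s) in bp (>= 1).
#' @param nterm_offset N-terminal offset(s), each in {1,2,3}.
#' @return Integer vector of C-terminal offsets in {1,2,3}.
#' @export
compute_cterm_offset <- function(exon_length_bp, nterm_offset) {
  if (!all(nterm_offset %in% 1:3))
    stop("nterm_offset must be in {1,2,3}")
  if (any(exon_length_bp < 1L)) stop("exon_length_bp must be >= 1")
  x <- (exon_length_bp %% 3L) - as.integer(nterm_offset) + 3L
  x <- ifelse(x > 3L, x %% 3L, x)
  as.integer(ifelse(x == 0L, 3L, x))
}

# Trim `n` bp from the reading-direction end of an exon table (used to drop a
# stop codon that a GTF dialect included in its CDS features).
trim_reading_end <- function(exons, strand, n) {
  while (n > 0L && nrow(exons)) {
    i <- nrow(exons)
    L <- exons$end[i] - exons$start[i] + 1L
    take <- min(L, n)
    if (take == L) {
      exons <- exons[-i]
    } else if (strand == "+") {
      exons$end[i] <- exons$end[i] - take
    } else {
      exons$start[i] <- exons$start[i] + take
    }
    n <- n - take
  }
  exons
}

#' Build the protein-exon map for one transcript/protein pair
#'
#' Projects the exonic structure of a coding transcript onto its protein:
#' each protein exon records the amino-acid span encoded by one genomic exon
#' together with the N-/C-terminal codon offsets (bp of the first/last
#' residue's codon lying in that exon). A residue whose codon spans a splice
#' junction appears in both flanking protein exons (`aa_end[i] ==
#' aa_start[i+1]` whenever the C-terminal offset is < 3), and consecutive
#' offsets always satisfy `(O_C + O_N') mod 3 == 0`.
#'
#' For complete annotations the first N-terminal offset is 3. When the start
#' codon is missing (first CDS frame in {1,2}) the leading partial codon has
#' `frame` annotated bp; the first residue is treated as truncated with
#' N-terminal offset equal to the frame, and peptides covering it are later
#' refused. A trailing 3 bp surplus over `3 * nchar(sequence)` is trimmed as
#' a stop codon (with a warning); larger disagreement than 3 bp marks the
#' entry unmappable.
#'
#' @param transcript A `TranscriptModel` from [read_gtf()].
#' @param sequence The protein sequence (amino acids, no stop symbol).
#' @param protein_id Identifier stored on the entry (defaults to the
#'   transcript id).
#' @return A `ProteinEntry`: list with the identifiers, `sequence`,
#'   `j_sequence` (I/L collapsed to J), `exon_map` (data.table with
#'   `aa_start`, `aa_end`, `o_n`, `o_c`, `g_start`, `g_end`, `length`),
#'   `status` (`"ok"` or `"length_mismatch"`), `aa_first`/`aa_last` (range of
#'   residues whose codons are completely annotated), and
#'   `annotation_complete`.
#' @export
build_protein_exon_map <- function(transcript, sequence,
                                   protein_id = transcript$transcript_id) {
  stopifnot(inherits(transcript, "TranscriptModel"), nzchar(sequence))
  exons <- copy(transcript$exons)
  strand <- transcript$strand
  len <- nchar(sequence)

  f1 <- exons$frame[1]
  if (is.na(f1) || !(f1 %in% 0:2)) f1 <- 0L
  lead <- (3L - f1) %% 3L  # bp of residue 1's codon missing upstream

  total <- sum(exons$end - exons$start + 1L)
  needed <- 3L * len - lead
  if (total - needed == 3L) {
    warning("trimming 3 bp stop codon from CDS of ", transcript$transcript_id)
    exons <- trim_reading_end(exons, strand, 3L)
    total <- total - 3L
  }
  diff <- total - needed
  status <- if (abs(diff) > 3L) "length_mismatch" else "ok"

  L <- exons$end - exons$start + 1L
  B <- cumsum(c(1L, head(L, -1L)))  # 1-based start of each exon in spliced CDS
  o_n <- 3L - ((B + lead - 1L) %% 3L)
  o_c <- ((B + L + lead - 2L) %% 3L) + 1L
  s_p <- as.integer(ceiling((B + lead) / 3))
  e_p <- pmin(as.integer(ceiling((B + L - 1L + lead) / 3)), len)

  exon_map <- data.table(
    aa_start = s_p, aa_end = e_p, o_n = o_n, o_c = o_c,
    g_start = exons$start, g_end = exons$end, length = L
  )
  exon_map <- exon_map[aa_start <= len & aa_start <= aa_end]

  structure(list(
    protein_id    = protein_id,
    transcript_id = transcript$transcript_id,
    gene_id       = transcript$gene_id,
    gene_name     = transcript$gene_name,
    gene_biotype  = transcript$gene_biotype,
    chromosome    = transcript$chromosome,
    strand        = strand,
    sequence      = sequence,
    j_sequence    = normalize_sequence(sequence),
    exon_map      = exon_map,
    status        = status,
    aa_first      = if (lead > 0L) 2L else 1L,
    aa_last       = min(len, (lead + total) %/% 3L),
    annotation_complete = (lead == 0L && diff == 0L)
  ), class = "ProteinEntry")
}

#' Build the full annotation index (GTF + FASTA + k-mer dictionary)
#'
#' Reads the annotation and the translated proteome, pairs proteins with
#' transcripts through their identifiers, constructs the protein-exon map for
#' every pair, and indexes the J-normalized proteome in a k-mer dictionary.
#'
#' @inheritParams read_gtf
#' @param fasta,gtf File paths.
#' @param k Word length of the k-mer dictionary (default 5).
#' @return A `PepAnnotation` object: list with `entries` (one `ProteinEntry`
#'   per usable FASTA record; entries whose transcript is absent from the GTF
#'   get `status = "no_transcript"` and no exon map), and `index`
#'   (a [build_kmer_index()] dictionary over the entries).
#' @export
build_annotation <- function(fasta, gtf, k = 5L,
                             transcript_id_pattern = "ENST\\d{11}",
                             gene_id_pattern = "ENSG\\d{11}") {
  tx <- read_gtf(gtf, transcript_id_pattern, gene_id_pattern)
  fa <- read_protein_fasta(fasta, transcript_id_pattern, gene_id_pattern)

  entries <- vector("list", nrow(fa))
  for (i in seq_len(nrow(fa))) {
    tid <- fa$transcript_id[i]
    if (!is.null(tx[[tid]])) {
      entries[[i]] <- build_protein_exon_map(tx[[tid]], fa$sequence[i],
                                             protein_id = fa$protein_id[i])
    } else {
      entries[[i]] <- structure(list(
        protein_id = fa$protein_id[i], transcript_id = tid,
        gene_id = fa$gene_id[i], gene_name = "", gene_biotype = "",
        chromosome = NA_character_, strand = NA_character_,
        sequence = fa$sequence[i],
        j_sequence = normalize_sequence(fa$sequence[i]),
        exon_map = NULL, status = "no_transcript",
        aa_first = NA_integer_, aa_last = NA_integer_,
        annotation_complete = FALSE
      ), class = "ProteinEntry")
    }
  }
  structure(list(entries = entries,
                 index = build_kmer_index(entries, k = k),
                 k = as.integer(k)),
            class = "PepAnnotation")
}

#' @export
print.PepAnnotation <- function(x, ...) {
  st <- vapply(x$entries, function(e) e$status, "")
  cat(sprintf("PepAnnotation: %d proteins (%d mappable, %d without transcript, %d length-mismatched), k = %d\n",
              length(x$entries), sum(st == "ok"), sum(st == "no_transcript"),
              sum(st == "length_mismatch"), x$k))
  invisible(x)
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s [%d CDS exon(s)]\n",
              x$transcript_id, x$gene_id, x$chromosome, x$strand, nrow(x$exons)))
  invisible(x)
}

#' @export
print.ProteinEntry <- function(x, ...) {
  cat(sprintf("ProteinEntry %s (%s/%s) %d aa, status %s\n",
              x$protein_id, x$transcript_id, x$gene_id, nchar(x$sequence), x$status))
  invisible(x)
}
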