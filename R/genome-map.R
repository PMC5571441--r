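## Genome mapper: protein-space matches -> spliced genomic loci, PTM
## projection, and uniqueness classification.

# Project the residue range [a_from, a_to] of a protein entry onto genomic
# blocks (1-based inclusive, ascending order). Junction residues contribute
# partial codons to both flanking blocks. Returns a 2-column integer matrix
# (start, end) or NULL when nothing overlaps.
residues_to_blocks <- function(entry, a_from, a_to) {
  em <- entry$exon_map
  if (is.null(em) || !nrow(em)) return(NULL)
  ov <- em[em$aa_start <= a_to & em$aa_end >= a_from, ]
  if (!nrow(ov)) return(NULL)
  fwd <- entry$strand == "+"
  blocks <- matrix(0L, nrow = nrow(ov), ncol = 2L)
  for (r in seq_len(nrow(ov))) {
    a1 <- max(a_from, ov$aa_start[r])
    a2 <- min(a_to, ov$aa_end[r])
    # distances from the exon's reading-direction start S_E
    dS <- (a1 - ov$aa_start[r] - 1L) * 3L + ov$o_n[r]
    dE <- (a2 - ov$aa_start[r]) * 3L + ov$o_n[r] - 1L
    dS <- max(dS, 0L)                   # shared junction residue at exon start
    dE <- min(dE, ov$length[r] - 1L)    # shared junction residue at exon end
    if (fwd) {
      blocks[r, ] <- c(ov$g_start[r] + dS, ov$g_start[r] + dE)
    } else {
      blocks[r, ] <- c(ov$g_end[r] - dE, ov$g_end[r] - dS)
    }
  }
  blocks[order(blocks[, 1L]), , drop = FALSE]
}

#' Convert a protein-space peptide match to a spliced genomic locus
#'
#' Retrieves the protein exons overlapped by the matched peptide and converts
#' each covered amino-acid sub-range into a genomic block using the distance
#' of the peptide from the exon's reading-direction start (`S_E + dS` /
#' `S_E + dE` on the forward strand, `S_E - dS` / `S_E - dE` on the reverse,
#' with `dS = (s_A - s_P - 1)*3 + O_N` and `dE = (e_A - s_P)*3 + O_N - 1`).
#' A residue whose codon spans a splice junction is emitted as partial codons
#' in both flanking blocks, so block lengths always sum to
#' `3 * peptide length`.
#'
#' @param match One row of a [find_peptide()] result (`s_A`, `e_A`,
#'   `mismatches`, `mismatch_positions`).
#' @param entry The matched `ProteinEntry`.
#' @return A `MappedPeptide`: list with `chromosome`, `strand`,
#'   `start`/`end` (1-based inclusive, ascending), `blocks` (2-column matrix),
#'   id/metadata fields, `mismatches` and `mismatch_positions`. When the
#'   entry is unmappable or the peptide overlaps an incompletely annotated
#'   CDS terminus the peptide-transcript pair is skipped and a
#'   `SkippedMapping` (list with a `reason` field) is returned instead.
#' @export
peptide_to_genome <- function(match, entry) {
  s_A <- match$s_A
  e_A <- match$e_A
  if (entry$status != "ok") {
    return(skipped_mapping(if (entry$status == "no_transcript")
      "sequence-database mismatch" else "incomplete CDS"))
  }
  if (s_A < entry$aa_first || e_A > entry$aa_last) {
    warning(sprintf("peptide at %d-%d of %s overlaps an incompletely annotated CDS terminus; skipped",
                    s_A, e_A, entry$transcript_id))
    return(skipped_mapping("incomplete CDS"))
  }
  blocks <- residues_to_blocks(entry, s_A, e_A)
  if (is.null(blocks)) return(skipped_mapping("incomplete CDS"))
  stopifnot(sum(blocks[, 2L] - blocks[, 1L] + 1L) == 3L * (e_A - s_A + 1L))
  structure(list(
    chromosome = entry$chromosome,
    strand = entry$strand,
    start = min(blocks[, 1L]),
    end = max(blocks[, 2L]),
    blocks = blocks,
    transcript_ids = entry$transcript_id,
    gene_ids = entry$gene_id,
    gene_name = entry$gene_name,
    gene_biotype = entry$gene_biotype,
    s_A = s_A, e_A = e_A,
    mismatches = match$mismatches,
    mismatch_positions = match$mismatch_positions[[1]]
  ), class = "MappedPeptide")
}

#' Project post-translational modifications onto the genome
#'
#' Maps the modified residues of a peptide to a genomic "thick" span, one per
#' modification type. Multiple sites of the same type on one peptide collapse
#' into a single span running from the first to the last modified residue's
#' codon; the span may bridge an intron in coordinate terms while the parent
#' peptide's blocks delimit the coding bases. Different modification types
#' are mapped separately.
#'
#' @param ptms `data.table` with columns `offset` (0-based position of the
#'   modified residue relative to the peptide start) and `name` (PSI
#'   modification name), as produced by [parse_peptide_line()].
#' @param mapping The peptide's `MappedPeptide` locus.
#' @param entry The `ProteinEntry` the locus was derived from.
#' @return List of `PTMLocus` objects: `ptm_type`, `thick_start`,
#'   `thick_end` (1-based inclusive genomic span).
#' @export
map_ptms <- function(ptms, mapping, entry) {
  if (is.null(ptms) || !nrow(ptms)) return(list())
  pep_len <- mapping$e_A - mapping$s_A + 1L
  if (any(ptms$offset < 0L | ptms$offset >= pep_len))
    stop("PTM position outside the peptide")
  types <- unique(tolower(ptms$name))
  lapply(types, function(ty) {
    off <- ptms$offset[tolower(ptms$name) == ty]
    r1 <- mapping$s_A + min(off)
    r2 <- mapping$s_A + max(off)
    tb <- residues_to_blocks(entry, r1, r2)
    structure(list(ptm_type = ty,
                   thick_start = min(tb[, 1L]),
                   thick_end = max(tb[, 2L])),
              class = "PTMLocus")
  })
}

skipped_mapping <- function(reason) {
  structure(list(reason = reason), class = "SkippedMapping")
}

locus_key <- function(m) {
  paste(m$chromosome, m$strand, paste(t(m$blocks), collapse = ","), sep = "|")
}

#' Merge duplicate loci and classify peptide uniqueness
#'
#' Given every genomic mapping of a single peptide sequence, mappings with
#' identical loci (chromosome, strand and block structure) are merged into
#' one feature whose transcript/gene sets are the unions. Each merged locus
#' is then classified: `multi_gene` when the peptide's mappings involve more
#' than one gene (grey in the BED track), `unique_transcript` when there is
#' exactly one locus arising from one transcript (red), and `unique_gene`
#' otherwise, i.e. one gene but several transcripts and/or loci (black).
#'
#' @param mappings List of `MappedPeptide` objects for one peptide.
#' @return List of merged `MappedPeptide` objects, each with a `uniqueness`
#'   field added.
#' @export
classify_uniqueness <- function(mappings) {
  if (!length(mappings)) return(mappings)
  keys <- vapply(mappings, locus_key, "")
  merged <- lapply(unique(keys), function(kk) {
    grp <- mappings[keys == kk]
    m <- grp[[1]]
    m$transcript_ids <- sort(unique(unlist(lapply(grp, `[[`, "transcript_ids"))))
    m$gene_ids <- sort(unique(unlist(lapply(grp, `[[`, "gene_ids"))))
    nm <- unique(vapply(grp, `[[`, "", "gene_name"))
    m$gene_name <- paste(nm[nzchar(nm)], collapse = ",")
    m
  })
  all_genes <- unique(unlist(lapply(merged, `[[`, "gene_ids")))
  for (i in seq_along(merged)) {
    merged[[i]]$uniqueness <-
      if (length(all_genes) > 1L) "multi_gene"
      else if (length(merged) == 1L && length(merged[[1]]$transcript_ids) == 1L)
        "unique_transcript"
      else "unique_gene"
  }
  merged
}
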