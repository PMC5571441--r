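## Output writers: BED12 peptide track (uniqueness-colored), PTM BED track
## (thick block = modification span), GTF with redefined feature types, and
## GCT 1.2 quantitation matrix. All writers are deterministic: fixed sort
## orders and fixed 4-decimal float formatting.

#' Default track color scheme
#'
#' Uniqueness colors follow browser-track convention: peptides unique to a
#' single transcript are red (255,0,0), peptides shared between multiple
#' transcripts of one gene black (0,0,0), peptides mapping to multiple genes
#' grey (128,128,128). Ten biologically relevant modification types carry
#' distinct colors for easy discrimination; unknown types fall back to black
#' with a warning.
#'
#' @return A `ColorScheme` list with `uniqueness` and `ptm` named vectors of
#'   `"R,G,B"` strings (components 0-255).
#' @export
default_color_scheme <- function() {
  structure(list(
    uniqueness = c(unique_transcript = "255,0,0",
                   unique_gene       = "0,0,0",
                   multi_gene        = "128,128,128"),
    ptm = c(phospho   = "255,51,51",
            acetyl    = "0,153,0",
            amidated  = "255,153,0",
            oxidation = "204,102,0",
            methyl    = "0,0,204",
            dimethyl  = "102,0,204",
            trimethyl = "204,0,204",
            glygly    = "51,204,204",
            palmitoyl = "153,102,51",
            formyl    = "102,102,102")
  ), class = "ColorScheme")
}

# Assemble the BED12 coordinate columns for one mapping; validates the block
# invariants (ascending, non-overlapping, flush with the feature ends).
bed12_fields <- function(m) {
  b <- m$blocks
  if (nrow(b) > 1L && any(b[-1L, 1L] <= b[-nrow(b), 2L]))
    stop("overlapping blocks in one feature")
  chrom_start <- m$start - 1L
  chrom_end <- m$end
  sizes <- b[, 2L] - b[, 1L] + 1L
  starts <- b[, 1L] - 1L - chrom_start
  stopifnot(starts[1L] == 0L,
            starts[nrow(b)] + sizes[nrow(b)] == chrom_end - chrom_start)
  list(chrom_start = chrom_start, chrom_end = chrom_end,
       n = nrow(b),
       sizes = paste0(paste(sizes, collapse = ","), ","),
       starts = paste0(paste(starts, collapse = ","), ","))
}

sort_mappings <- function(mappings) {
  ord <- order(vapply(mappings, `[[`, "", "chromosome"),
               vapply(mappings, `[[`, 0L, "start"),
               vapply(mappings, `[[`, 0L, "end"))
  mappings[ord]
}

#' Write mapped peptides as a BED12 track
#'
#' One line per mapped peptide locus: 0-based half-open coordinates, name =
#' peptide sequence, score 1000, thick region spanning the whole feature, and
#' `itemRgb` encoding the uniqueness class ([classify_uniqueness()]). Blocks
#' reproduce the spliced structure of the mapping. Lines are sorted by
#' (chromosome, start).
#'
#' @param mappings List of classified `MappedPeptide` objects, each with a
#'   `peptide` field set.
#' @param out Output file path.
#' @param scheme A [default_color_scheme()]-shaped `ColorScheme`.
#' @return Number of lines written, invisibly.
#' @export
write_bed <- function(mappings, out, scheme = default_color_scheme()) {
  mappings <- sort_mappings(mappings)
  lines <- vapply(mappings, function(m) {
    f <- bed12_fields(m)
    rgb <- scheme$uniqueness[[m$uniqueness]]
    paste(m$chromosome, f$chrom_start, f$chrom_end, m$peptide, 1000L,
          m$strand, f$chrom_start, f$chrom_end, rgb,
          f$n, f$sizes, f$starts, sep = "\t")
  }, "")
  writeLines(lines, out)
  invisible(length(lines))
}

#' Write post-translational modification loci as a BED12 track
#'
#' Same structure as [write_bed()], but one line per (peptide locus,
#' modification type): the thick block delimits the span from the first to
#' the last site of that modification type, the name retains the bracket
#' annotation, and `itemRgb` encodes the modification type.
#'
#' @param ptm_tracks List of lists, each with `mapping` (a `MappedPeptide`),
#'   `annotated` (peptide string with brackets), and `ptm` (a `PTMLocus`).
#' @inheritParams write_bed
#' @return Number of lines written, invisibly.
#' @export
write_ptm_bed <- function(ptm_tracks, out, scheme = default_color_scheme()) {
  ord <- order(vapply(ptm_tracks, function(p) p$mapping$chromosome, ""),
               vapply(ptm_tracks, function(p) p$mapping$start, 0L),
               vapply(ptm_tracks, function(p) p$ptm$ptm_type, ""),
               vapply(ptm_tracks, function(p) p$annotated, ""))
  ptm_tracks <- ptm_tracks[ord]
  lines <- vapply(ptm_tracks, function(p) {
    m <- p$mapping
    f <- bed12_fields(m)
    ty <- p$ptm$ptm_type
    rgb <- scheme$ptm[ty]
    if (is.na(rgb)) {
      warning("no color defined for PTM type '", ty, "'; using black")
      rgb <- "0,0,0"
    }
    paste(m$chromosome, f$chrom_start, f$chrom_end, p$annotated, 1000L,
          m$strand, p$ptm$thick_start - 1L, p$ptm$thick_end, rgb,
          f$n, f$sizes, f$starts, sep = "\t")
  }, "")
  writeLines(lines, out)
  invisible(length(lines))
}

gtf_escape <- function(x) gsub('"', "", x)

#' Write mapped peptides as GTF features
#'
#' Feature types are repurposed: `transcript` marks a mapped peptide spanning
#' its full genomic extent and one `exon` line per block gives the concrete
#' exonic mapping. Attributes carry gene id/name/biotype, the associated
#' transcript ids, the peptide sequence, the mismatch count, and one
#' `sample "X"; psms N; quant Q;` triplet per sample in which the peptide was
#' identified.
#'
#' @param mappings List of classified `MappedPeptide` objects, each with
#'   `peptide` and a `samples` data.table (`sample`, `psm_count`, `quant`).
#' @param out Output file path.
#' @param source Value of the GTF source column.
#' @return Number of lines written, invisibly.
#' @export
write_gtf <- function(mappings, out, source = "pepmapr") {
  mappings <- sort_mappings(mappings)
  lines <- unlist(lapply(mappings, function(m) {
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s"; peptide "%s"; mismatches "%d";',
      paste(m$gene_ids, collapse = ","),
      paste(m$transcript_ids, collapse = ","),
      gtf_escape(m$gene_name), gtf_escape(m$gene_biotype),
      m$peptide, m$mismatches)
    if (!is.null(m$samples) && nrow(m$samples)) {
      sm <- m$samples
      attr_str <- paste0(attr_str, paste0(
        sprintf(' sample "%s"; psms "%d"; quant "%.4f";',
                gtf_escape(sm$sample), sm$psm_count, sm$quant),
        collapse = ""))
    }
    c(paste(m$chromosome, source, "transcript", m$start, m$end, ".",
            m$strand, ".", attr_str, sep = "\t"),
      vapply(seq_len(nrow(m$blocks)), function(i) {
        paste(m$chromosome, source, "exon", m$blocks[i, 1L], m$blocks[i, 2L],
              ".", m$strand, ".", attr_str, sep = "\t")
      }, ""))
  }))
  if (is.null(lines)) lines <- character(0)
  writeLines(lines, out)
  invisible(length(lines))
}

#' Write a GCT 1.2 quantitation matrix
#'
#' Rows identify a peptide with its genomic mapping
#' (`NAME = peptide@chrom:start-end(strand)`, `Description` = gene id(s)),
#' columns identify samples, and each cell holds the quantitative value for
#' that (peptide, sample) pair; absent pairs are written as `NA`.
#'
#' @param quants Long-format `data.table` with columns `name`,
#'   `description`, `sample`, `quant` — one row per observed (peptide
#'   mapping, sample) pair. A duplicated (name, sample) pair is a hard error.
#' @param out Output file path.
#' @param samples Column order; defaults to order of first appearance.
#' @return `c(rows, cols)` of the matrix, invisibly.
#' @export
write_gct <- function(quants, out, samples = NULL) {
  stopifnot(all(c("name", "description", "sample", "quant") %in% names(quants)))
  if (anyDuplicated(quants[, c("name", "sample"), with = FALSE]))
    stop("Peptide and sample pairings may only occur once in the input file")
  if (is.null(samples)) samples <- unique(quants$sample)
  if (!nrow(quants)) {
    writeLines(c("#1.2", paste(0L, length(samples), sep = "\t"),
                 paste(c("NAME", "Description", samples), collapse = "\t")),
               out)
    return(invisible(c(rows = 0L, cols = length(samples))))
  }
  rows <- unique(quants[, c("name", "description"), with = FALSE])
  setorder(rows, name)
  wide <- dcast(quants, name + description ~ factor(sample, levels = samples),
                value.var = "quant", drop = FALSE)
  wide <- wide[rows, on = c("name", "description")]
  cells <- vapply(seq_len(nrow(wide)), function(i) {
    v <- as.numeric(wide[i, samples, with = FALSE])
    paste(ifelse(is.na(v), "NA", sprintf("%.4f", v)), collapse = "\t")
  }, "")
  lines <- c("#1.2",
             paste(nrow(rows), length(samples), sep = "\t"),
             paste(c("NAME", "Description", samples), collapse = "\t"),
             paste(wide$name, wide$description, cells, sep = "\t"))
  writeLines(lines, out)
  invisible(c(rows = nrow(rows), cols = length(samples)))
}
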