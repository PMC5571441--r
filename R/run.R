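## Orchestration: one shared annotation index, each peptide evidence file
## mapped independently, outputs per requested format with mismatch-bearing
## mappings routed to suffixed companion files.

map_one_sequence <- function(annotation, sequence, mm) {
  res <- find_peptide(annotation$index, sequence, mm)
  if (!is.null(attr(res, "reason")))
    return(list(mappings = list(), reason = attr(res, "reason")))
  if (!nrow(res)) return(list(mappings = list(), reason = "not found"))
  mappings <- list()
  reasons <- character(0)
  for (r in seq_len(nrow(res))) {
    entry <- annotation$entries[[res$entry[r]]]
    mp <- peptide_to_genome(res[r], entry)
    if (inherits(mp, "SkippedMapping")) {
      reasons <- c(reasons, mp$reason)
    } else {
      mp$entry_index <- res$entry[r]
      mappings[[length(mappings) + 1L]] <- mp
    }
  }
  if (!length(mappings)) {
    # every matched protein was unusable; report the dominant reason
    reason <- if ("incomplete CDS" %in% reasons) "incomplete CDS"
              else "sequence-database mismatch"
    return(list(mappings = list(), reason = reason))
  }
  list(mappings = mappings, reason = NA_character_)
}

process_peptide_file <- function(annotation, path, formats, mm, out_dir,
                                 scheme) {
  recs <- read_peptides(path)
  stem <- file.path(out_dir, basename(file_path_sans_ext(path)))
  samples_order <- unique(recs$sample)
  seqs <- unique(recs$sequence)

  counts <- c(read = length(seqs), mapped = 0L, loci = 0L,
              `not found` = 0L, `below word length` = 0L,
              `incomplete CDS` = 0L, `sequence-database mismatch` = 0L)

  # search and map every distinct bare sequence once
  per_seq <- list()
  for (sq in seqs) {
    got <- map_one_sequence(annotation, sq, mm)
    if (!length(got$mappings)) {
      counts[got$reason] <- counts[got$reason] + 1L
    } else {
      counts["mapped"] <- counts["mapped"] + 1L
      per_seq[[sq]] <- got$mappings
    }
  }

  # classify within each mismatch stratum and attach sample information
  strata <- sort(unique(unlist(lapply(per_seq, function(ms)
    vapply(ms, `[[`, 0L, "mismatches")))))
  if (!length(strata)) strata <- 0L  # nothing mapped: still emit empty outputs
  outputs <- list()
  for (st in strata) {
    feats <- list()     # classified mappings with samples
    ptm_tracks <- list()
    gct_rows <- list()
    for (sq in names(per_seq)) {
      ms <- Filter(function(m) m$mismatches == st, per_seq[[sq]])
      if (!length(ms)) next
      merged <- classify_uniqueness(ms)
      sub <- recs[recs$sequence == sq, ]
      samp <- sub[, .(psm_count = sum(psm_count), quant = quant[1L]),
                  by = .(sample)]
      for (m in merged) {
        m$peptide <- sq
        m$samples <- samp
        feats[[length(feats) + 1L]] <- m
        # PTM projection per annotated form carrying modifications
        for (ri in seq_len(nrow(sub))) {
          ptms <- sub$ptms[[ri]]
          ann <- sub$annotated[ri]
          gct_rows[[length(gct_rows) + 1L]] <- data.table(
            name = sprintf("%s@%s:%d-%d(%s)", ann, m$chromosome, m$start,
                           m$end, m$strand),
            description = paste(m$gene_ids, collapse = ","),
            sample = sub$sample[ri], quant = sub$quant[ri])
          if (!is.null(ptms) && nrow(ptms)) {
            entry <- annotation$entries[[m$entry_index]]
            for (pt in map_ptms(ptms, m, entry)) {
              key <- paste(ann, locus_key(m), pt$ptm_type)
              ptm_tracks[[key]] <- list(mapping = m, annotated = ann, ptm = pt)
            }
          }
        }
      }
    }
    counts["loci"] <- counts["loci"] + length(feats)
    suffix <- if (st == 0L) "" else sprintf("_%dMM", st)
    written <- character(0)
    if ("bed" %in% formats) {
      f <- paste0(stem, suffix, ".bed")
      write_bed(feats, f, scheme)
      written <- c(written, f)
    }
    if ("ptmbed" %in% formats) {
      f <- paste0(stem, suffix, "_ptm.bed")
      write_ptm_bed(unname(ptm_tracks), f, scheme)
      written <- c(written, f)
    }
    if ("gtf" %in% formats) {
      f <- paste0(stem, suffix, ".gtf")
      write_gtf(feats, f)
      written <- c(written, f)
    }
    if ("gct" %in% formats) {
      f <- paste0(stem, suffix, ".gct")
      gq <- if (length(gct_rows)) unique(rbindlist(gct_rows)) else
        data.table(name = character(), description = character(),
                   sample = character(), quant = numeric())
      write_gct(gq, f, samples = samples_order)
      written <- c(written, f)
    }
    outputs[[as.character(st)]] <- written
  }
  list(counts = counts, rejected_lines = attr(recs, "rejected"),
       outputs = outputs)
}

#' Map peptide evidence files to the genome and write browser tracks
#'
#' End-to-end pipeline: builds one shared annotation index from the GTF and
#' protein FASTA, then maps each evidence file independently, writing the
#' requested output formats next to each input (or under `out_dir`).
#' Mappings carrying 1 or 2 substitutions go to companion files suffixed
#' `_1MM` / `_2MM` so the uniqueness colors of the main track stay clean.
#'
#' @inheritParams build_annotation
#' @param input_files Character vector of evidence file paths (a single
#'   comma-separated string is also accepted); each is mapped separately.
#' @param formats Subset of `c("bed", "ptmbed", "gtf", "gct")`.
#' @param mm Allowed amino-acid substitutions (0-2).
#' @param out_dir Output directory; default: alongside each input file.
#' @param scheme Track [default_color_scheme()].
#' @return A `pep_run_summary`: per input file, peptides read/mapped, loci
#'   written, unmappable counts by reason (not found, below word length,
#'   incomplete CDS, sequence-database mismatch), rejected input lines, and
#'   the paths written. `peptides read = mapped + sum(unmappable)` always
#'   holds. A run in which nothing maps still succeeds (empty outputs, loud
#'   warning), since it usually signals mismatched FASTA/GTF inputs.
#' @export
run_mapping <- function(fasta, gtf, input_files,
                        formats = c("bed", "ptmbed", "gtf", "gct"),
                        mm = 0L, k = 5L, out_dir = NULL,
                        transcript_id_pattern = "ENST\\d{11}",
                        gene_id_pattern = "ENSG\\d{11}",
                        scheme = default_color_scheme()) {
  stopifnot(mm %in% 0:2)
  formats <- match.arg(tolower(formats),
                       c("bed", "ptmbed", "gtf", "gct"), several.ok = TRUE)
  if (length(input_files) == 1L && grepl(",", input_files))
    input_files <- strsplit(input_files, ",", fixed = TRUE)[[1]]
  annotation <- build_annotation(fasta, gtf, k = k,
                                 transcript_id_pattern = transcript_id_pattern,
                                 gene_id_pattern = gene_id_pattern)
  summaries <- lapply(input_files, function(p) {
    process_peptide_file(annotation, p,
                         formats = formats, mm = mm,
                         out_dir = out_dir %||% dirname(p),
                         scheme = scheme)
  })
  names(summaries) <- input_files
  total_mapped <- sum(vapply(summaries, function(s) s$counts[["mapped"]], 0L))
  if (total_mapped == 0L)
    warning("no peptide could be mapped in any input file - do the protein FASTA and GTF describe the same annotation?")
  structure(list(files = summaries, mm = mm, k = k, formats = formats),
            class = "pep_run_summary")
}

#' @export
print.pep_run_summary <- function(x, ...) {
  cat(sprintf("peptide-to-genome run (k = %d, mm = %d)\n", x$k, x$mm))
  for (f in names(x$files)) {
    s <- x$files[[f]]
    cat(sprintf("  %s: %d peptide(s) read, %d mapped, %d locus/loci written\n",
                f, s$counts[["read"]], s$counts[["mapped"]],
                s$counts[["loci"]]))
    unmap <- s$counts[c("not found", "below word length", "incomplete CDS",
                        "sequence-database mismatch")]
    unmap <- unmap[unmap > 0L]
    if (length(unmap))
      cat(sprintf("    unmappable: %s\n",
                  paste(sprintf("%s (%d)", names(unmap), unmap),
                        collapse = ", ")))
    if (s$rejected_lines > 0L)
      cat(sprintf("    rejected input lines: %d\n", s$rejected_lines))
  }
  invisible(x)
}
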