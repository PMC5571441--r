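## Peptide evidence input: tab-separated (sample, peptide, PSMs, quant) with
## PTM annotation in round brackets after the modified residue.

# Tokenize an annotated peptide string into the bare sequence and a table of
# (0-based offset, PSI name) modifications. Returns NULL + message on error.
parse_annotated_peptide <- function(pep) {
  chars <- strsplit(pep, "", fixed = TRUE)[[1]]
  bare <- character(0)
  offs <- integer(0)
  names_ <- character(0)
  i <- 1L
  nres <- 0L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) return(list(error = "unclosed bracket"))
      if (nres == 0L) return(list(error = "bracket without preceding residue"))
      nm <- tolower(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (!nzchar(nm)) return(list(error = "empty modification name"))
      offs <- c(offs, nres - 1L)
      names_ <- c(names_, nm)
      i <- j + 1L
    } else if (ch == ")") {
      return(list(error = "unbalanced bracket"))
    } else if (grepl("^[A-Za-z]$", ch)) {
      nres <- nres + 1L
      bare <- c(bare, toupper(ch))
      i <- i + 1L
    } else {
      return(list(error = sprintf("invalid character '%s' in peptide", ch)))
    }
  }
  if (!nres) return(list(error = "empty peptide sequence"))
  list(sequence = paste(bare, collapse = ""),
       ptms = data.table(offset = offs, name = names_))
}

#' Parse one line of peptide evidence
#'
#' Expects four tab-separated fields: sample identifier, peptide sequence,
#' number of peptide-to-spectrum matches, and a quantitative value. Post-
#' translational modifications are annotated in the peptide as the PSI name
#' in round brackets immediately after the modified residue, e.g.
#' `IADPEHDHT(phospho)GFLTEYVATR`. Lowercase `s`, `t`, `y` phosphosite
#' shorthand is accepted and converted to the bracket form first.
#'
#' @param line A single tab-separated line.
#' @param line_number Optional line number used in rejection warnings.
#' @return A `PeptideRecord` list: `sample`, `sequence` (bare, uppercase),
#'   `annotated` (bracket form), `ptms` (`data.table` of `offset` [0-based]
#'   and `name`), `psm_count`, `quant` — or `NULL` with a warning when the
#'   line is rejected (wrong column count, bracket before any residue,
#'   unparseable numbers).
#' @export
parse_peptide_line <- function(line, line_number = NA_integer_) {
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 4L) {
    warning(sprintf("rejected peptide line%s: expected 4 tab-separated fields, got %d",
                    where, length(fields)))
    return(NULL)
  }
  # lowercase s/t/y phosphosite shorthand; never mixed with bracket syntax
  pep_raw <- if (grepl("(", fields[2], fixed = TRUE)) fields[2] else
    gsub("([sty])", "\\U\\1\\E(phospho)", fields[2], perl = TRUE)
  parsed <- parse_annotated_peptide(pep_raw)
  if (!is.null(parsed$error)) {
    warning(sprintf("rejected peptide line%s: %s", where, parsed$error))
    return(NULL)
  }
  psm <- suppressWarnings(as.integer(fields[3]))
  quant <- suppressWarnings(as.numeric(fields[4]))
  if (is.na(psm) || psm < 0L || is.na(quant)) {
    warning(sprintf("rejected peptide line%s: unparseable PSM count or quant value", where))
    return(NULL)
  }
  list(sample = fields[1], sequence = parsed$sequence, annotated = pep_raw,
       ptms = parsed$ptms, psm_count = psm, quant = quant)
}

#' Read a peptide evidence file
#'
#' Reads a tab-separated file of (sample, peptide, PSMs, quant) rows via
#' [parse_peptide_line()]. If the first line's third and fourth fields are
#' non-numeric it is treated as a header and skipped. Rejected lines are
#' reported with their line numbers and the run continues. A repeated
#' (annotated peptide, sample) pairing is a hard error, since it would no
#' longer identify a unique quantitative value.
#'
#' @param path Path to the evidence file.
#' @return `data.table` with one row per accepted record: `sample`,
#'   `sequence`, `annotated`, `ptms` (list column), `psm_count`, `quant`,
#'   `line` (source line number); the number of rejected lines is attached
#'   as `attr(, "rejected")`.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) stop("peptide input file not found: ", path)
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  ln <- ln[keep]
  if (length(lines)) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 4L &&
        is.na(suppressWarnings(as.numeric(f1[3]))) &&
        is.na(suppressWarnings(as.numeric(f1[4])))) {
      lines <- lines[-1]
      ln <- ln[-1]
    }
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    r <- parse_peptide_line(lines[i], ln[i])
    if (!is.null(r)) recs[[i]] <- data.table(
      sample = r$sample, sequence = r$sequence, annotated = r$annotated,
      ptms = list(r$ptms), psm_count = r$psm_count, quant = r$quant,
      line = ln[i]
    )
  }
  ok <- !vapply(recs, is.null, TRUE)
  out <- if (any(ok)) rbindlist(recs[ok]) else
    data.table(sample = character(), sequence = character(),
               annotated = character(), ptms = list(),
               psm_count = integer(), quant = numeric(), line = integer())
  if (anyDuplicated(out[, .(annotated, sample)]))
    stop("Peptide and sample pairings may only occur once in the input file")
  attr(out, "rejected") <- sum(!ok)
  out
}
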