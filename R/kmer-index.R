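## Peptide index: J-normalization, k-mer dictionary, and mismatch-tolerant
## peptide lookup (exact split search with a pigeonhole guarantee for long
## peptides, variant enumeration of the first word for short ones).

# 19-letter amino-acid alphabet with I and L collapsed to J.
J_ALPHABET <- strsplit("ACDEFGHJKMNPQRSTVWY", "")[[1]]

#' Collapse isoleucine and leucine to the shared symbol J
#'
#' Leucine and isoleucine are isobaric and indistinguishable in standard mass
#' spectrometry; all dictionary keys and mismatch counts therefore operate on
#' sequences with both residues replaced by `J`.
#'
#' @param seq Character vector of uppercase amino-acid sequences.
#' @return Sequences of the same lengths with every `I`/`L` replaced by `J`.
#' @export
normalize_sequence <- function(seq) chartr("IL", "JJ", seq)

#' Build the k-mer dictionary over a proteome
#'
#' Indexes every window of `k` residues (overlapping by `k - 1`) of every
#' J-normalized protein sequence, recording the protein and the 1-based start
#' position of the window. Proteins shorter than `k` cannot contribute keys
#' and are kept on a separate list for direct linear scanning.
#'
#' @param entries List of `ProteinEntry` objects (see
#'   [build_protein_exon_map()]); only `j_sequence` and `protein_id` are used.
#' @param k Word length, >= 2 (default 5).
#' @return A `KmerIndex`: list with `k`, `table` (keyed data.table
#'   `kmer`/`entry`/`pos`), `seqs` (J-normalized sequences by entry index),
#'   `protein_ids`, and `short` (indices of proteins shorter than `k`).
#' @export
build_kmer_index <- function(entries, k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  seqs <- vapply(entries, function(e) e$j_sequence, "")
  n <- nchar(seqs)
  long <- which(n >= k)
  tabs <- lapply(long, function(i) {
    np <- n[i] - k + 1L
    data.table(kmer = substring(seqs[i], 1:np, k:(np + k - 1L)),
               entry = i, pos = 1:np)
  })
  tab <- if (length(tabs)) rbindlist(tabs) else
    data.table(kmer = character(), entry = integer(), pos = integer())
  setkey(tab, kmer)
  structure(list(k = k, table = tab, seqs = seqs,
                 protein_ids = vapply(entries, function(e) e$protein_id, ""),
                 short = setdiff(seq_along(seqs), long)),
            class = "KmerIndex")
}

#' @export
print.KmerIndex <- function(x, ...) {
  cat(sprintf("KmerIndex: k = %d, %d postings over %d keys, %d protein(s), %d below word length\n",
              x$k, nrow(x$table), uniqueN(x$table$kmer), length(x$seqs),
              length(x$short)))
  invisible(x)
}

# All J-alphabet variants of word `w` with at most m substitutions (m <= 2).
kmer_variants <- function(w, m) {
  chars <- strsplit(w, "")[[1]]
  k <- length(chars)
  out <- w
  if (m >= 1L) {
    for (i in seq_len(k)) {
      alt <- setdiff(J_ALPHABET, chars[i])
      v <- vapply(alt, function(a) {
        x <- chars; x[i] <- a; paste(x, collapse = "")
      }, "")
      out <- c(out, v)
    }
  }
  if (m >= 2L && k >= 2L) {
    for (pr in combn(k, 2L, simplify = FALSE)) {
      i <- pr[1]; j <- pr[2]
      ai <- setdiff(J_ALPHABET, chars[i])
      aj <- setdiff(J_ALPHABET, chars[j])
      grid <- expand.grid(a = ai, b = aj, stringsAsFactors = FALSE)
      pre <- if (i > 1L) paste(chars[1:(i - 1L)], collapse = "") else ""
      mid <- if (j - i > 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      suf <- if (j < k) paste(chars[(j + 1L):k], collapse = "") else ""
      out <- c(out, paste0(pre, grid$a, mid, grid$b, suf))
    }
  }
  unique(out)
}

empty_match_table <- function() {
  data.table(entry = integer(), protein_id = character(),
             s_A = integer(), e_A = integer(), mismatches = integer(),
             mismatch_positions = list())
}

#' Find all proteins containing a peptide with up to m substitutions
#'
#' Searches the k-mer dictionary for every occurrence of `peptide` in the
#' indexed proteome allowing `m` (0-2) amino-acid substitutions, counted on
#' J-normalized sequences so I/L exchanges are never mismatches.
#'
#' Peptides of length at least `(m + 1) * k` are split into `floor(len/k)`
#' consecutive non-overlapping k-mers, each looked up exactly: at most `m`
#' words can carry a substitution, so at least one word must match perfectly
#' (pigeonhole). Shorter peptides use the first word only, enumerating all of
#' its variants with up to `m` substitutions over the 19-letter J-alphabet.
#' Every candidate position is validated against the full peptide by Hamming
#' distance and protein bounds; proteins below the word length are scanned
#' linearly. Results are deduplicated on (protein, start).
#'
#' @param index A [build_kmer_index()] dictionary.
#' @param peptide Amino-acid string; peptides shorter than `k` are not
#'   searchable and yield an empty result carrying
#'   `attr(, "reason") == "below word length"`.
#' @param m Allowed substitutions, 0, 1 or 2.
#' @return `data.table` with one row per match: `entry` (index into the
#'   indexed entries), `protein_id`, `s_A`/`e_A` (1-based inclusive span in
#'   the protein), `mismatches`, and `mismatch_positions` (list column of
#'   1-based peptide-relative positions).
#' @export
find_peptide <- function(index, peptide, m = 0L) {
  stopifnot(inherits(index, "KmerIndex"), m %in% 0:2)
  k <- index$k
  pep <- normalize_sequence(toupper(peptide))
  n <- nchar(pep)
  if (n < k) {
    out <- empty_match_table()
    attr(out, "reason") <- "below word length"
    return(out)
  }

  if (n < (m + 1L) * k) {
    vars <- kmer_variants(substr(pep, 1L, k), m)
    hits <- index$table[J(vars), nomatch = 0L]
    cand <- hits[, .(entry, s_A = pos)]
  } else {
    nw <- n %/% k
    offs <- (seq_len(nw) - 1L) * k
    words <- substring(pep, offs + 1L, offs + k)
    cand <- rbindlist(lapply(seq_len(nw), function(j) {
      index$table[J(words[j]), .(entry, s_A = pos - offs[j]), nomatch = 0L]
    }))
  }

  # proteins too short to be indexed: every alignment is a candidate
  for (i in index$short) {
    ni <- nchar(index$seqs[i])
    if (ni >= n)
      cand <- rbind(cand, data.table(entry = i, s_A = seq_len(ni - n + 1L)))
  }

  cand <- unique(cand[s_A >= 1L])
  if (!nrow(cand)) return(empty_match_table())

  pr <- charToRaw(pep)
  res <- vector("list", nrow(cand))
  nres <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand$entry[r]
    s <- cand$s_A[r]
    e <- s + n - 1L
    if (e > nchar(index$seqs[i])) next
    mm <- which(charToRaw(substr(index$seqs[i], s, e)) != pr)
    if (length(mm) <= m) {
      nres <- nres + 1L
      res[[nres]] <- data.table(entry = i, protein_id = index$protein_ids[i],
                                s_A = s, e_A = e,
                                mismatches = length(mm),
                                mismatch_positions = list(as.integer(mm)))
    }
  }
  if (!nres) return(empty_match_table())
  out <- rbindlist(res[seq_len(nres)])
  setorder(out, entry, s_A)
  out
}
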