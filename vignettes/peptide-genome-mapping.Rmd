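---
title: "Mapping peptides to spliced genomic coordinates"
author: "pepmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peptides to spliced genomic coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmapr)
```

## The problem

Mass spectrometry identifies peptides by searching spectra against a protein
sequence database, so the natural coordinate system of proteomic evidence is
the protein. Comparing that evidence with RNA-seq coverage, variant calls, or
annotation features requires the peptide's position on the *genome*, across
splice junctions, on either strand. `pepmapr` performs that projection
purely arithmetically: it never reads genomic nucleotide sequence. Given a
GTF annotation with CDS features and the matching translated proteome in
FASTA, every protein position has a unique codon location on the genome, and
a peptide's genomic locus follows from its position in the protein.

The pipeline is: parse GTF + FASTA and pair them by transcript identifier;
bridge each protein to its transcript's exon structure ("protein exons");
locate each evidence peptide in the proteome with a k-mer dictionary that
tolerates up to two amino-acid substitutions; convert protein positions to
spliced genomic blocks; and write browser tracks (BED12, a PTM BED12, GTF,
and a GCT quantitation matrix).

## Protein exons and codon offsets

A transcript is an ordered set of coding exons $t_1 \dots t_n$, ordered in
reading direction — ascending genomic coordinates on the forward strand,
descending on the reverse. Each exon maps to a *protein exon* $p_i$ holding
the amino-acid range $[s_p, e_p]$ it encodes, plus two offsets: the number
of base pairs of the first residue's codon lying in this exon
($O(p_i(\mathrm{N_{term}})) \in \{1,2,3\}$) and likewise for the last residue
($O(p_i(\mathrm{C_{term}}))$). For a complete annotation
$O(p_1(\mathrm{N_{term}})) = 3$, and the C-terminal offset follows from the
exon length $L$:

$$O(p_i(\mathrm{C_{term}})) = X = (L \bmod 3) - O(p_i(\mathrm{N_{term}})) + 3,
\qquad X > 3 \Rightarrow X \bmod 3 .$$

We additionally normalize $X = 0$ to 3: an offset of zero would claim that a
residue's codon uses no bases of the exon that contains it, which cannot
happen. Consecutive offsets always satisfy
$(O(p_i(\mathrm{C_{term}})) + O(p_{i+1}(\mathrm{N_{term}}))) \bmod 3 = 0$,
and when $O(p_i(\mathrm{C_{term}})) < 3$ the junction residue's codon is
split across the intron, so that residue belongs to *both* protein exons
($e_{p_i} = s_{p_{i+1}}$). This shared-residue convention is what produces
correct BED block structure: the split codon contributes its partial bases
to both flanking blocks.

The offset formula is exact for exons of at least 3 bp. A 1–2 bp micro-exon
lying entirely inside one codon has no valid offset pair in $\{1,2,3\}$;
such exons are vanishingly rare in curated annotations and unsupported here
(the fixture generator never emits them).

### Incomplete annotations

When a transcript lacks an annotated start codon, the GTF frame of its first
CDS exon is nonzero: frame $f$ means the leading partial codon has $f$
annotated bases, with $3-f$ bases missing upstream of the annotation. We
treat the protein's first residue as that truncated codon's residue and set
$O(p_1(\mathrm{N_{term}})) = f$. This is the only choice consistent with the
projection arithmetic below and with round-trip translation from a genome:
with it, residue 2's codon begins exactly $f$ bases into the exon, and every
downstream coordinate is exact. The truncated residue itself cannot be
mapped (part of its codon is unannotated), so peptides covering it are
skipped and counted as "incomplete CDS" rather than truncated — emitting a
partial locus would silently misrepresent the peptide's extent.

Total CDS length is reconciled against $3\times$ protein length: a surplus
of exactly 3 bp is trimmed as a stop codon (some GTF dialects include it in
CDS features, GENCODE does not) with a warning; a discrepancy beyond 3 bp
marks the entry unmappable.

## Finding peptides in the proteome

Leucine and isoleucine are isobaric and indistinguishable by standard MS, so
all matching operates on sequences with `I`/`L` collapsed to `J` (a 19-letter
alphabet). The proteome is indexed in a dictionary of k-mers (default
$k = 5$) overlapping by $k-1$; each key lists (protein, start) postings.

Searching a peptide of length $\ell$ with $m$ allowed substitutions uses two
strategies:

* $\ell \ge (m+1)k$: the peptide is split into $\lfloor \ell/k \rfloor$
  consecutive non-overlapping words, each looked up *exactly*. Substitutions
  can corrupt at most $m$ of those words, so at least one word of every true
  occurrence matches perfectly (pigeonhole). Residues past the last complete
  word need no word of their own — they are covered by validation.
* $\ell < (m+1)k$: only the first word is used, and every variant of it with
  at most $m$ substitutions over the 19-letter alphabet is generated and
  looked up (at $k=5$, $m=2$ this is 3,331 lookups). Generating the
  $\le m$-substitution superset rather than exactly-$m$ variants is harmless:
  validation filters the result either way.

Every candidate alignment is validated by Hamming distance on J-normalized
sequences against the full peptide, with bounds checks, and deduplicated on
(protein, start). Proteins shorter than $k$ cannot enter the dictionary and
are scanned linearly so no source is silently missed. The test suite checks
this machinery against `naive_peptide_scan()`, an independent all-alignments
scanner, over seeded random proteomes at $m \in \{0,1,2\}$, and asserts two
properties besides: I↔L exchanges anywhere never change results, and result
sets grow monotonically with $m$.

## Projecting to the genome

For a peptide occupying residues $[s_A, e_A]$ of protein $P$, the protein
exons overlapping that range (standard interval overlap) each contribute one
genomic block. With $S_E$ the exon's reading-direction start (genomic start
on `+`, genomic end on `-`):

$$dS_A = (s_A - s_P - 1) \times 3 + O(P(\mathrm{N_{term}})), \qquad
  dE_A = (e_A - s_P) \times 3 + O(P(\mathrm{N_{term}})) - 1,$$

giving $S_A = S_E + dS_A$, $E_A = S_E + dE_A$ on the forward strand and
$S_A = S_E - dS_A$, $E_A = S_E - dE_A$ on the reverse. At a shared junction
residue the raw distances would run past the exon boundary; they are clamped
to the exon, which is precisely what assigns the split codon's bases to the
two flanking blocks. Blocks are emitted in ascending genomic order and always
sum to $3 \times$ peptide length — a conservation law asserted both as a
runtime invariant and as a property test.

PTMs annotated in the peptide (PSI name in round brackets after the modified
residue; 0-based offsets internally) are projected with the same block
machinery applied to the modified residue range. Multiple sites of one
modification type on a peptide collapse to a single span from the first to
the last site's codon; different types map separately. A span crossing a
junction covers the intervening intron in coordinate terms — intended, as the
BED thick block is a display range.

### Uniqueness classes

All loci of one peptide (within one mismatch stratum) are gathered, identical
loci reached through several transcripts are merged with their transcript and
gene sets unioned, and each locus is classified for the BED color code:
red = unique to a single transcript (one locus, one transcript),
black = within a single gene (several transcripts and/or several loci, as for
tandem repeats), grey = mapping to multiple genes. Classification is
per-stratum, so a run allowing two mismatches leaves the exact-match track
byte-identical to an exact-only run; substitution-bearing mappings go to
`_1MM`/`_2MM` companion files.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 5 aa | dictionary word length; smaller = denser index, larger = fewer, longer words (peptides shorter than `k` are unsearchable) |
| `mm` | 0 | allowed substitutions (0–2), for peptides carrying non-synonymous variants |
| `transcript_id_pattern` | `ENST\d{11}` | regex pairing FASTA records to GTF transcripts (version suffixes ignored) |
| `gene_id_pattern` | `ENSG\d{11}` | likewise for genes |
| colors | red/black/grey + 10 PTM colors | `default_color_scheme()`, user-overridable |

The BED score column is fixed at 1000 and quantitative values print with 4
decimals so reruns are byte-identical.

## The synthetic worlds

`generate_world()` builds a deterministic toy universe from transcript
blueprints: a protein is drawn (or given — e.g. five tandem copies of
`VPEPGCTK` to create a repeat gene), reverse-translated with random
synonymous codons, split into exons of at least 3 bp, placed on a chromosome
with random introns (reverse-complemented for `-` strand blueprints), and
surrounded by random background sequence. The generator emits the genome
FASTA, a GTF (CDS features with correct frames, plus exon features the
reader must ignore), the protein FASTA, and a *truth table* giving every
residue's codon coordinates — derived by walking the exons base-by-base,
independently of the offset arithmetic it is later used to check.
`generate_peptides()` samples tryptic-like evidence with optional planted
substitutions and phosphosites, recording expected loci from the truth table.

What the worlds emulate: the GENCODE GTF/FASTA pairing, both strands,
multi-exon structure, missing start codons, tandem repeats, proteins shared
between genes, multiple transcripts per gene. What they do not: sequencing
or identification error, I/L composition biases, selenoproteins, ribosomal
slippage, micro-exons, overlapping genes, and realistic chromosome scale.
Passing tests therefore demonstrate coordinate correctness of the algorithm,
not robustness to malformed real-world annotation beyond the error paths
exercised explicitly.

Test problem sizes: the oracle-equivalence suite uses 20 seeded worlds of 50
proteins × 200 aa with 25 peptides each (500 peptides, three mismatch
levels); round-trip and conservation checks sample a few dozen peptides per
fixture world. These sizes give full coverage of the combinatorial cases
(both strategies of the search, 0–2 substitutions, both strands, 1–4 exons)
while keeping the default test run fast.

## Degenerate inputs and tie-breaks

* Malformed GTF lines are skipped with their line numbers; conflicting
  strands within a transcript are a hard error naming it.
* FASTA records without a recognizable transcript id are skipped with a
  warning; duplicate transcript ids keep the first record.
* A peptide below the word length is reported "below word length"; one found
  nowhere, "not found"; one whose only sources lack a GTF transcript,
  "sequence-database mismatch"; one whose only positions touch unannotated
  codon bases (or whose protein's CDS length disagrees grossly),
  "incomplete CDS". Read = mapped + unmappable always balances.
* A repeated (annotated peptide, sample) pairing is rejected outright, since
  it would no longer identify a unique quantitative value. The key includes
  the PTM annotation: the same bare sequence with different site
  localizations is two distinct peptide forms.
* A run in which nothing maps exits normally with empty outputs and a
  prominent warning — the common cause is a FASTA/GTF pair from different
  annotation releases.

## Known limitations

Only substitutions are modeled — no insertions or deletions, and no
probabilistic match scoring. Peptides spanning unannotated junctions or
novel ORFs cannot map: the projection is strictly within annotated CDS.
Mappings to incompletely annotated CDS termini are skipped rather than
truncated. The GCT row name convention
(`peptide@chrom:start-end(strand)`) is chosen for readability in IGV; other
tools may expect different row identifiers.
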