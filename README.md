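# pepmapr — peptide-to-genome coordinate mapping for proteogenomics

Mass spectrometry locates peptides in *protein* coordinates; genomics lives
on the reference genome. `pepmapr` bridges the two for proteogenomic
analyses: it maps peptides identified by MS — via an annotated proteome —
onto exact spliced genomic coordinates, and writes genome-browser-ready
tracks. It is aimed at proteomics/proteogenomics practitioners who want to
view peptide evidence, phosphosite positions, and multi-sample quantitation
next to gene models, RNA-seq, and variant calls, without reformatting their
reference annotation.

## The algorithm

Inputs are a gene annotation in GTF (GENCODE dialect, CDS features) and the
matching translated proteome in FASTA, paired by transcript identifier
(default `ENST`/`ENSG` + 11 digits, version suffixes ignored). No genome
sequence is needed — the mapping is pure coordinate arithmetic:

1. **Protein exons.** Each transcript's CDS exons $t_1 \dots t_n$ (reading
   order) are projected onto the protein as amino-acid ranges carrying
   N-/C-terminal codon offsets $O \in \{1,2,3\}$ — the bp of the first/last
   residue's codon inside that exon, with
   $O(p_i(\mathrm{C_{term}})) = ((L(t_i) \bmod 3) - O(p_i(\mathrm{N_{term}})) + 3)$
   (mod-3 normalized) and adjacent offsets congruent:
   $(O_C + O'_N) \bmod 3 = 0$. A codon split by a splice junction places its
   residue in both flanking protein exons.
2. **Peptide search.** The proteome is indexed as a dictionary of k-mers
   (default $k=5$, overlapping by $k-1$) over sequences with I/L collapsed
   to `J` (indistinguishable by MS). Peptides are found with up to two
   amino-acid substitutions: long peptides via non-overlapping exact words
   (pigeonhole guarantees one clean word), short ones via enumeration of
   first-word variants; all candidates are Hamming-validated.
3. **Projection.** A match at protein residues $[s_A, e_A]$ becomes genomic
   blocks via $dS_A = (s_A - s_P - 1)\times 3 + O_N$ and
   $dE_A = (e_A - s_P)\times 3 + O_N - 1$ from each exon's
   reading-direction start (added on `+`, subtracted on `-`). Block lengths
   always sum to $3\times$ peptide length. PTMs (PSI name in brackets after
   the modified residue) are projected the same way; same-type sites
   collapse to a first-to-last-site span.
4. **Tracks.** BED12 colored by uniqueness (red = single transcript,
   black = single gene, grey = multiple genes), a PTM BED12 whose thick
   block marks the modification span, GTF (`transcript` = mapped peptide,
   `exon` = its blocks, with per-sample PSM/quant attributes), and a GCT 1.2
   matrix of (peptide locus) × (sample) quantitation for IGV.
   Substitution-bearing mappings go to `_1MM`/`_2MM` companion files.

A fixtures module generates self-consistent toy genomes, annotations,
proteomes and evidence files (with a per-residue codon truth table), so the
entire pipeline is testable offline.

## Worked example

```r
library(pepmapr)

# a toy world: one two-exon gene, one reverse-strand gene, one tandem-repeat gene
world <- generate_world(list(
  transcript_blueprint(aa_len = 40, n_exons = 2, strand = "+", chrom = "chr1"),
  transcript_blueprint(aa_len = 35, n_exons = 2, strand = "-", chrom = "chr1"),
  transcript_blueprint(repeat_motif = "VPEPGCTK", repeat_copies = 5, chrom = "chr2")
), seed = 42)
paths <- write_world(world, "demo")

# evidence: a junction-spanning peptide, a reverse-strand phosphopeptide,
# and a missed-cleavage repeat peptide (two 8-residue repeat units)
pep_rev <- substring(world$transcripts[[2]]$protein, 10, 24)
writeLines(c(
  "tumor1\tDKEFPFYCIDALMR\t3\t1.27",
  sprintf("tumor1\t%s\t2\t-0.44", sub("^(....)", "\\1(phospho)", pep_rev)),
  "tumor1\tVPEPGCTKVPEPGCTK\t5\t0.88"
), "demo/peptides.tsv")

run_mapping(paths$fasta, paths$gtf, "demo/peptides.tsv")
#> peptide-to-genome run (k = 5, mm = 0)
#>   demo/peptides.tsv: 3 peptide(s) read, 3 mapped, 6 locus/loci written
```

`demo/peptides.bed` then contains (columns: chrom, 0-based start, end, name,
score, strand, thick, itemRgb, blocks):

```text
chr1  377  530   DKEFPFYCIDALMR    1000  +  377  530   255,0,0  2  1,41,  0,112,
chr1  985  1030  HLVPWSTNKMSIGAP   1000  -  985  1030  255,0,0  1  45,    0,
chr2  347  395   VPEPGCTKVPEPGCTK  1000  +  347  395   0,0,0    1  48,    0,
chr2  371  419   VPEPGCTKVPEPGCTK  1000  +  371  419   0,0,0    1  48,    0,
chr2  395  443   VPEPGCTKVPEPGCTK  1000  +  395  443   0,0,0    1  48,    0,
chr2  419  467   VPEPGCTKVPEPGCTK  1000  +  419  467   0,0,0    1  48,    0,
```

The junction peptide is red (unique to one transcript) and split into two
blocks of 1 + 41 coding bases — its first residue's codon has a single base
in the upstream exon. The repeat peptide maps **four times with the
occurrences overlapping each other** (starts 8 residues = 24 bp apart
against five tandem motif copies), all black: several loci, one gene. The
phosphosite lands in `demo/peptides_ptm.bed` as a 3-bp thick block inside
its reverse-strand peptide:

```text
chr1  985  1030  HLVP(phospho)WSTNKMSIGAP  1000  -  1018  1021  255,51,51  1  45,  0,
```

and `demo/peptides.gct` holds the quantitation matrix (6 loci × 1 sample,
`NAME = peptide@chrom:start-end(strand)`).

A thin command-line wrapper is installed under `exec/`:

```sh
pepmapr --fasta demo/proteins.fa --gtf demo/annotation.gtf \
        --in demo/peptides.tsv --mm 1
```

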