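---
title: "Predicting strain-specific gene, mRNA and protein sequences: methods and design"
author: "strainseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting strain-specific gene, mRNA and protein sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainseq)
```

## The problem

Many inbred laboratory mouse strains have dense SNP/indel catalogues but no
assembled genome. For a single gene of interest, those variant tables are
enough to reconstruct the strain's sequence: substitute the catalogued
variants into the reference gene, splice the result against the reference
transcript to find the exons, and translate the spliced product. `strainseq`
implements that pipeline offline: its inputs are a reference gene sequence
(FASTA), a reference mRNA (FASTA), and per-strain variant tables (a minimal
VCF dialect, or a delimited export with a configurable column map), and its
outputs are per-strain gene, mRNA and protein FASTA files plus per-strain
alignment statistics.

Because every stage is deterministic string processing, the pipeline is
testable end to end against synthetic genes whose exon structure, mRNA and
protein are known by construction. The package treats that simulator as a
first-class module.

## Imputation with an index-preserving edit map

Variants are applied through a per-index *edit map*: position `i` of the
reference maps to a replacement string, which is the reference base when the
position is untouched, the alternate base at a SNP, the anchor base plus the
inserted bases at an insertion anchor, and the empty string at a deleted
base. Flattening the map in index order yields the strain's gene. The point
of this representation is that reference indices stay addressable after any
number of indels — no annotation shuffling, and `project_index()` recovers
where any reference position landed in the imputed sequence.

Conventions pinned here, since variant formats are ambiguous about them:

* All edits are applied on the **forward genomic strand**, because VCF and
  the common strain-variation exports report forward-strand alleles. For a
  gene annotated on the complement strand, the flattened sequence is
  reverse-complemented as a final step, so downstream stages always see the
  gene in its sense orientation. If a variant source pre-flips alleles for
  complement-strand genes, they must be restored to forward-strand form
  before use — this contract is deliberately strict.
* VCF-style anchored indels are normalized on ingest: the shared anchor base
  is stripped, insertions store the bases and the reference index *after*
  which they insert, deletions store the removed index range. An insertion
  before the first base goes to a dedicated pre-sequence slot.
* One edit per reference index. Overlapping normalized edits are an input
  error, not a merge: homozygous inbred catalogues should never contain
  them, so their presence signals corrupted input. For the same reason a
  heterozygous call is a hard error by default, with an explicit
  `het_policy = "first_allele"` override.
* A deletion straddling the gene boundary (windowed exports do produce
  these) is clipped to the gene with a warning.

## Spliced alignment: seed, chain, refine, fill

The reference mRNA is aligned to the imputed gene in four stages.

**Seeding.** Every gene k-mer (default `seed_k = 16`) is indexed; an mRNA
k-mer seeds only where it occurs *exactly once* in the gene, and k-mers
containing `N` never seed. Overlapping and adjacent hits on the same
diagonal merge into maximal perfect blocks. Uniqueness rather than mere
matching is what lets a ~40 kb gene with repeated elements anchor reliably;
16 bp balances uniqueness against tolerance of SNP density (one SNP voids
only the k-mers crossing it).

**Chaining.** Blocks form a DAG: an edge joins two blocks when the second
continues the first in both mRNA and gene coordinates, with small overlaps
trimmed off the downstream block (a perfect-match run frequently extends a
few bases past the true junction when the next exon's first bases replicate
the intron start). Edge cost is the number of uncovered mRNA bases between
the blocks — each a potential mismatch — plus an intron penalty
(`intron_penalty`, default 8) when the gene-side gap qualifies as an intron.
Source and sink edges charge the uncovered mRNA prefix and suffix. The
minimum-cost path is found with Dijkstra's algorithm (all edge costs are
non-negative); ties break toward fewer introns, then leftmost gene
coordinates, making the output reproducible. A gene gap counts as an intron
when `gene_gap - mrna_gap >= min_intron` (default 20 bases); smaller gaps
are treated as deletions and handled by the fill stage. The intron penalty
must exceed the mismatch savings a spurious junction could buy; 8 does so
comfortably at the default scoring and is exposed in the parameters.

**Refinement.** When the bases flanking a junction match the gene on both
sides, the junction's placement is ambiguous within that window. Each
placement is scored +2 if the intron then starts `GT` and +2 if it ends
`AG`; the best placement wins, ties go to the leftmost junction, and a
window with no GT/AG keeps the chained placement. Only the gene's sense
strand is scored — strand is resolved before alignment, so the reverse
motifs never apply.

**Fill.** Residual mRNA segments are aligned with an affine-gap (Gotoh)
global aligner written in C++ (match +1, mismatch -1, gap open -4, gap
extend -1; a run of length L costs `open + (L-1)*extend`; traceback ties
prefer diagonal, then up, then left). Three cases:

* a gap between co-exonic blocks (e.g. around a SNP or small indel) is
  aligned both-ends-anchored and the blocks merge into one exon;
* the 5' prefix and 3' suffix are fitted into the gene window adjacent to
  the outer exons with the distal end free, and the exon extends only over
  the gene bases the alignment actually used;
* uncovered mRNA at an intron junction is split between the two flanking
  exons by maximizing, over all splits and per-side gene extents, the
  alignment score plus a splice-consensus bonus on the resulting intron
  ends. The fill-stage bonus is *stronger* (+6 per site) than the
  refinement bonus: these segments arise when an indel or SNP cluster sits
  near a junction, where a handful of chance matches against intronic
  sequence can outscore the true gapped placement at the default scoring
  (one mismatch costs less than extending a gap), and the canonical GT/AG
  signal is the only evidence that distinguishes the true junction. Both
  flanking blocks are also pulled back a few bases (up to 8) before the
  split is chosen, so a seed run that overhung the junction can be undone.

Mismatch counting is defined on the mRNA: a mismatched column or an mRNA
base opposite a gap counts 1; gene bases skipped by the alignment count 0
(they are simply retained or excluded from the exon span). The predicted
strain mRNA is then the concatenation of the gene-side exon substrings, so
exonic SNPs and intra-exon indels flow into the prediction by construction.

When no seeds exist at all (a very short query), the whole mRNA is
Gotoh-aligned to the whole gene, but only when `mRNA x gene` stays within a
configurable DP-cell budget (default 2.5e7 cells, roughly a 10 kb gene
against a 2.5 kb mRNA); beyond that the call fails loudly rather than
consuming quadratic memory. The same budget guards the pairwise identity
report, which offers a banded mode (`band`) for long nucleotide pairs.

## ORF selection and translation

Two policies mirror how a predicted transcript is read. `minimize_5utr`
takes the ORF at the very first ATG. `maximize_orf` evaluates the ORF at
every ATG and returns the longest, ties to the leftmost. ORF length is
measured in nucleotides from the start codon through the stop codon
inclusive; an ORF reaching the mRNA end without a stop counts its full
remaining length, is translated, and is flagged `has_stop = FALSE` — a
truncated transcript still yields its partial product rather than nothing.
Only ATG starts an ORF; stops are TAA/TAG/TGA; translation uses the
standard code, drops a trailing partial codon, and emits `X` for any codon
containing `N`. An mRNA with no ATG gives an empty protein with a warning.

## The synthetic-data generator

`generate_gene()` builds a transcript — an ATG-free 5'UTR (20–60 bases), a
CDS of uniformly sampled sense codons closed by a stop, a 3'UTR (20–60
bases) — splits it into exons (160–320 bases each), and joins them with
`GT..AG` introns (80–300 bases) and flanks (120–260 bases), all uniform over
`{A,C,G,T}`. Rejection sampling (cap 100 tries) enforces that every exon
k-mer occurs exactly once in the gene, which is the premise of
single-perfect-match seeding; failures are loud. These sizes are chosen so
a 2–8-exon gene spans roughly 0.5–5 kb — big enough to exercise every
stage, small enough that a test suite can run hundreds of them; the suite
and the acceptance checks use 200–250 such genes.

`generate_variants()` places SNPs, insertions (2–8 bases) and deletions
(1–6 bases) uniformly and non-overlapping, with ≥ `seed_k + 4` bases
between variants so no exon loses all its seeds. With `protect_splice`
(the default) the GT/AG dinucleotides plus a 3-base margin around every
junction and the start/stop codons are off limits, and exonic *indels*
additionally keep `seed_k + 4` bases clear of each exon boundary — an indel
closer than that leaves a sub-seed exon fragment whose placement is not
recoverable from sequence alone (any aligner must then guess between a gap
and chance matches), so such fixtures would test luck, not the method.
With `in_frame_cds`, insertions in the CDS sit at codon boundaries with
lengths a multiple of 3 and stop-free codon content. Ground truths
(imputed gene, mRNA, protein) come from direct right-to-left editing of the
sense sequence and the exon intervals — never from the pipeline under test;
truth translation is a six-line independent codon walk.

What the generator does **not** emulate: realistic mutation spectra and
transition/transversion bias, GC skew, repeat families, alternative
isoforms, non-canonical splice sites, and heterozygosity. Passing the
recovery suite therefore shows the pipeline is exact under its stated
premises (unique seeds, canonical splice sites, homozygous variants), not
that it is robust to pathological real-genome structure; the identity
report and per-strain statistics exist precisely so real runs can be
inspected.

## Numerical and degenerate-input choices

* Alignment scores are integers; there is no floating-point tie ambiguity
  anywhere in the DP.
* Deterministic tie-breaks throughout: Dijkstra (fewer introns, then
  leftmost gene starts), Gotoh traceback (diagonal > up > left), junction
  refinement (leftmost placement), ORF ties (leftmost start).
* Empty inputs: an empty variant set reproduces the reference exactly; an
  empty mRNA segment against a non-empty gene window contributes no
  mismatches; a non-empty mRNA segment against an empty window counts
  entirely as mismatched.
* Percent identity is computed over alignment columns (gaps count in the
  denominator) and rounded half-up to one decimal, so `36934/37023` prints
  as `99.8%`; the denominator convention is pinned because external
  aligners differ in end-gap handling.
* The batch pipeline isolates failures per strain: a strain whose variants
  fail validation is reported and skipped, the rest proceed, and the exit
  status of the CLI reflects whether all selected strains succeeded.

## Design decisions that were genuinely open

* **Seed length, cost weights, intron threshold.** No canonical values
  exist for this design; `seed_k = 16`, `intron_penalty = 8`,
  `min_intron = 20` are defaults chosen as argued above and are all
  configurable in `alignment_params()`.
* **Insertion anchoring.** Insertions anchor *after* a reference index
  (anchor base retained); a position-0 insertion gets an explicit
  pre-sequence slot rather than a sentinel index.
* **Adjacent indel conflicts.** An insertion anchored on a deleted index is
  rejected as an overlap rather than silently composed; inbred data should
  not produce it.
* **Stopless ORFs are translated** (with `has_stop = FALSE`) rather than
  rejected.
* **Offline-first.** Database querying is out of scope by design; the
  `fetch_gene_bundle()` stub documents the adapter contract a connected
  front end would satisfy, and the whole test suite runs without a network.

## Known limitations

Single isoform per run (the predicted protein inherits whatever isoform the
supplied reference mRNA represents); no heterozygous or structural
variants; GT/AG is the only splice consensus considered; imputed sequences
are only as complete as the variant catalogue, so they are predictions to
be confirmed by sequencing, not assemblies.
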