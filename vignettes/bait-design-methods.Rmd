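---
title: "Methods: single-copy ortholog discovery and bait design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-copy ortholog discovery and bait design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgbaits)
```

## The problem

Target enrichment (sequence capture) needs a set of short hybridization
probes ("baits") targeting loci that are single-copy, orthologous across
the study group, and long enough to be phylogenetically informative. For
clades without reference genomes the only broadly available input is de
novo transcriptome assemblies of very heterogeneous quality, possibly
contaminated — in parasitic plants, by transcripts of the host the plant
was grown on. `scgbaits` implements a complete semi-automated path from
such assemblies to a bait set, with every screening decision exposed as a
parameter.

## Model and procedure

### Single-copy reference construction

Orthology is anchored in one or two reference species with annotated
genomes. A reference gene is accepted as putatively single-copy when its
translated-search hit set against a compiled SCG database has cardinality
exactly one: "similar to a known single-copy gene, and to only one". The
same threshold triple used downstream (identity ≥ 40 %, E ≤ 1e-20,
alignment ≥ 100 aa) is applied here; no separate stringency is introduced
without evidence, keeping one coherent stringency ledger. All-vs-all
search within a species then removes **both** members of every similar
pair — keeping one representative of a pair would risk retaining a hidden
paralog, and the stricter reading costs only reference breadth. When a
secondary species is supplied, only its genes with no threshold-passing
hit against the primary set are merged in, so each biological locus is
represented once.

### Homology search engine

The package carries a desk-scale local search engine so the workflow is
self-contained; externally produced 12-column tabular (outfmt-6) hits can
be injected at any time and are treated identically. The engine is
seed-and-extend:

* exact word seeds (3-mers on protein, 11-mers on nucleotide);
* a candidate subject requires two word matches on one alignment diagonal
  spanning at least one word length within a 32-position window — a single
  3-mer is shared by essentially every random protein pair, so the
  classical two-hit refinement is what makes the candidate set sparse and
  the search affordable;
* candidates are scored by ungapped extension along the seeded diagonals;
  those reaching a trigger score of 40 proceed to the full dynamic
  program: the exact maximal ungapped segment pair (ungapped mode) or full
  affine-gap Smith–Waterman (gapped mode), both implemented in C++.

Scoring defaults are BLAST-like: BLOSUM62 with gap open 11 / extend 1 for
translated searches, +2/−3 with gap open 5 / extend 2 for nucleotide, a
gap of length *g* costing `open + g·ext`. Bit scores use fixed
Karlin–Altschul parameters (λ = 0.318, K = 0.13) and E-values the form
`E = m·n·2^(−bit)` with *m* the query length in search units and *n* the
total subject length. These constants are conventional, not fitted; the
engine is exact for the *alignment* given a seeded pair but heuristic in
*which* pairs are examined, exactly as seeded search tools are. The test
suite keeps exhaustive pure-R dynamic-programming oracles and checks the
engine against them on planted-homology pairs.

Translated searches examine all six query frames because transcriptome
assemblies are unstranded; reverse-frame hits are flagged by a descending
subject interval and the unigene is reverse-complemented before locus
alignment. Ambiguity symbols score −1 and never count as identities.

### COS assignment and screens

Per unigene only the best threshold-passing hit is kept (bitscore, then
lower E, longer alignment, lexicographic subject id). All three thresholds
are read inclusively ("at least 40" ⇒ ≥ 40, "better than 1e-20" ⇒
≤ 1e-20); the boundary tests pin this convention. The search reporting
cutoff (1e-10) is deliberately looser than the assignment cutoff (1e-20),
mirroring a search-then-parse workflow where the parser owns stringency.

The host screen removes assigned unigenes with ≥ 95 % nucleotide identity
to any host-database sequence, with no minimum alignment length — the
source procedure specifies only the identity rule. The paralog screen
works on reference (subject) coordinates in amino-acid units: same-taxon
unigenes on one reference gene that overlap by more than `paralog_overlap`
(default 30 aa, user-adjustable) are all removed for that taxon. Subject
coordinates distinguish fragments of one transcript (disjoint on the
reference) from paralogs (overlapping); whole-group removal is chosen over
best-member retention because the goal is paralog exclusion, not locus
maximisation. The default of 30 aa is our choice where the source leaves
the cutoff user-defined: roughly a protein domain's worth of overlap,
small enough to catch genuine duplicates, large enough to tolerate ragged
fragment ends.

### Locus assembly and alignment

Loci (bundles) are one reference gene plus all surviving assignments. The
optional anchor filter keeps only loci containing the best-assembled
taxon, judged by assembly N50 — a quality gate that trades completeness
for per-locus reliability and is off by default (`anchor = NULL`) because
single-taxon sorting can bias locus choice.

Every locus alignment contains the reference CDS as its first row, because
exon projection needs the reference's gap structure. Two backends exist.
The recommended external backend shells out to MAFFT with
`--genafpair --maxiterate 1000` (the E-INS-i strategy, suited to sequences
with multiple conserved domains and long gaps). The internal backend is a
reference-anchored star alignment: each member is aligned to the reference
CDS by overlap (free end gap) affine dynamic programming, and the pairwise
gap structures are merged by taking, per reference position, the longest
insertion observed. We chose this over a guide-tree progressive aligner
because the reference row is the downstream coordinate system anyway, the
construction guarantees the degap round-trip invariant (no residue
invented or lost), and it is deterministic — at the cost of ignoring
member–member signal, which E-INS-i exploits. Both backends are tested for
the round-trip invariant.

### Exon projection

Gene models are read from GFF3, using CDS features (not `exon` features:
the aligned sequences are CDS, and UTR-bearing exons would misalign). For
multi-mRNA genes the longest summed CDS is chosen, ties broken by mRNA id
— a deterministic rule where the source is silent. Segment lengths are
emitted in transcript orientation (reversed for minus-strand genes) and
validated against the CDS length. Cumulative exon ends are mapped to
alignment columns by counting non-gap reference characters; the final
breakpoint is extended to the alignment width so member insertions beyond
the reference 3' end stay with the last exon and slices tile the alignment
exactly. Exon slices are degapped per member; pieces shorter than the bait
length (120 bp) are dropped **per taxon per exon**, not per block — the
wording "exon sequences were degapped and exons < 120 bp removed" is read
as acting on the degapped per-taxon sequences. The assumption that focal
gene structure matches the reference is surfaced in the per-locus exon
counts of the run report so users can audit it; splitting before alignment
when focal exon boundaries are known is out of scope.

### Bait tiling and probe-set hygiene

Tiling places 120-bp baits at offsets 0, 60, 120, … while they fit, then
one terminal bait flush with the 3' end iff its overlap with the last
regular bait is ≤ 80 bp. This is the unique simple rule consistent with
both stated anchors: a 160-bp fragment yields two baits overlapping by
80 bp, and 280 bp is the smallest single exon yielding four baits (the
minimum locus length retained by the fewer-than-four-baits filter — both
are asserted in the acceptance tests, and an exhaustive placement oracle
checks every length to 1 kb).

Redundancy clustering is cd-hit-style greedy clustering specialised to
equal-length probes: deterministic sort (locus, exon, taxon order, start),
each bait joins the first representative it matches at ≥ 90 % — exact
position-wise comparison over the 120 columns, forward and
reverse-complement, no gaps. Equal-length probes make alignment-free
comparison sound; word size and short-sequence identity conventions of
general-purpose clustering tools are moot here. Finally, any locus
containing one bait with ≥ 90 % identity to an organelle database is
removed wholesale (plastid DNA dominates total-DNA extracts, and one
promiscuous bait contaminates the whole locus's capture). The screen runs
on post-clustering baits, matching the stated order (yield filter →
redundancy removal → plastid filter); mitochondrial screening is the same
operation with a different database and is off by default.

## The simulator: what it emulates, and what it does not

`simulation_config()` plants a fully known study system: `n_scg` true
single-copy genes (1–4 exons of 120–600 bp, total ≥ 330 bp), `n_paralog_pairs`
duplicated pairs at ~5 % intra-pair divergence, per-taxon substitution
divergence, in-frame indels, fragmentation, host contaminants (≤ 2 % from
a host gene set that is itself ≥ 10 % diverged copies of reference genes,
as when a parasite is grown on a related host) and plastid-derived
transcripts from a toy plastid genome. Unigenes are emitted on random
strands, as in an unstranded assembly. Defaults are 50 SCGs, 5 pairs, 4
taxa with divergences 2–6 % and fragmentation 0–40 % — a desk-scale
dataset the whole pipeline traverses in well under a minute.

Two constructional choices matter for interpreting test results. First,
gene structures are resampled until each gene's exons support at least
four baits, so planted loci are recoverable by construction and recovery
metrics measure the pipeline rather than the lottery of gene lengths.
Second, indels are planted in multiples of three, keeping reading frames
intact: this isolates the gapped-versus-ungapped contrast from frameshift
handling, which the pipeline does not model. The simulator does **not**
emulate expression-level variation, sequencing error, chimeric assembly
artifacts, alternative splicing, or genuinely missing loci — so a perfect
score on fixtures demonstrates correctness of the decision logic, not
performance on real assemblies.

## Gapped versus ungapped search

On indel-bearing fixtures the acceptance suite asserts the directional
claim: gapped search retains at least as many loci, and at least as long
average loci, as ungapped search, across five seeds (20 genes, 2 taxa,
2 % divergence, indel rate 0.004/site). Locus length is measured as the
aligned (COS) span of the retained best hit: the search mode acts on the
recoverable aligned region — ungapped search truncates an indel-bearing
locus to its best clean flank or loses it entirely, while gapped search
spans the indel — whereas the raw unigene length is insensitive to mode at
desk scale because whole unigenes are retained either way. Loci counts are
structurally monotone (a gapped alignment scores at least as high as the
best ungapped segment of the same pair), so the direction, not the
magnitude, is the reproducible content of the claim; absolute counts
depend on full-scale data that is out of scope here.

## Numerical and degenerate-input conventions

* All thresholds inclusive; percent identity is computed over alignment
  columns (gaps included) and rounded to 0.01 at hit creation, bitscores
  to 0.1, E-values to three significant digits — the tabular writer emits
  exactly these, so parse ∘ write is the identity.
* Coordinates are 1-based inclusive in hit tables (reverse orientation:
  descending subject interval); all internal slicing is 0-based half-open;
  bait starts are 0-based.
* Ties in best-hit selection break by E-value, then alignment length, then
  subject id; multi-mRNA genes by CDS length then mRNA id; clustering by
  the deterministic bait sort. Every run is byte-reproducible from its
  config.
* Empty inputs: empty query/subject sets give empty hit tables; an empty
  host or organelle database leaves the input unchanged with a warning
  (the step was requested but cannot act); an empty transcriptome has no
  N50 and errors.
* Problem sizes in the shipped tests — 8–50 genes, 2–4 taxa — were chosen
  so the full suite, including ten end-to-end runs, completes in a few
  minutes on one core.

## Known limitations

* The engine's candidate generation is heuristic (two-hit seeding); a true
  hit with no two same-diagonal word matches is invisible, as in any
  seeded search tool. Oracle tests quantify this only on planted pairs.
* One hit per query–subject pair is reported (the best frame); multi-HSP
  chaining is not modelled.
* The internal aligner ignores member–member homology; for publication
  alignments use the MAFFT backend.
* Exon boundaries are always projected from the reference; focal-species
  intron gain/loss violates the similarity assumption silently (audit via
  the exon-count report).
* No thermodynamic bait QC (melting temperature, GC, hairpins): the output
  is a candidate probe set, and synthesis-vendor screening is expected
  downstream.
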