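---
title: "Refining a genome annotation from assembled transcripts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining a genome annotation from assembled transcripts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txrefine)
```

## The problem

Many genome annotations — particularly of compact fungal genomes — consist
essentially of computationally predicted ORFs: no UTRs, few experimentally
confirmed intron–exon boundaries, almost no noncoding genes. Deep RNA-seq
followed by per-sample transcript assembly produces evidence for all of
these, but turning a pile of per-sample GTFs into a refined gene catalogue
requires a chain of non-trivial decisions: when are two assembled
transcripts the *same* model, how does a transcript relate structurally to
the old annotation, which transcripts code for protein, how do noncoding
RNAs sit relative to coding genes, which transcripts at a locus are
isoforms of one gene, and what exactly changed per gene relative to the old
annotation. `txrefine` implements that chain as a deterministic, testable
pipeline. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology was
genuinely open.

## Transcript identity and merging

The universal data structure is the *transcript table*: a tibble with one
row per exon (1-based, inclusive coordinates — the native convention of
GTF and of the IRanges machinery that performs all interval arithmetic, so
no coordinate shifting exists anywhere in the package). A multi-exon
transcript's identity is its **intron chain**, the ordered list of intron
coordinate pairs. Merging (`merge_samples()`) collapses transcripts with
identical (chromosome, strand, chain) into one model and takes the
minimum start / maximum end over the contributors: per-sample variation in
assembled UTR ends widens the model but never duplicates it. Mono-exon
transcripts have no chain; they collapse when they overlap on the same
strand by at least 1 bp (no gap tolerance), taking the union interval.
Distinct chains are never collapsed, whatever their overlap — a deliberate
conservative choice: collapsing near-identical chains would require a
junction-tolerance model for which assembled GTFs alone carry no error
estimate. Merged transcripts get locus-scoped serial identifiers
(`XLOC_000012.3`); original (sample, transcript) pairs are kept as
provenance.

After merging, transcripts with spliced length below `min_length` (default
200 nt) are excluded. The comparison is strict: a 199 nt transcript is
dropped, a 200 nt transcript kept. Sub-200 nt fragments are the typical
debris of short-read assembly and also the size range of structural RNAs
that this kind of poly(A)-selected data cannot quantify reliably.

## Structural class codes

`assign_class_codes()` relates each merged transcript to the old
annotation with one of nine symbols, evaluated in a fixed precedence order
(most specific first): `=` (identical intron chain), `c` (contained, chain
a contiguous sub-chain), `k` (containing the reference's full chain),
`j` (at least one shared splice junction, chains not identical), `o`
(other same-strand exonic overlap), `i` (inside a single reference
intron), `y` (reference gene inside a query intron), `x` (opposite-strand
exonic overlap), `u` (intergenic). Codes `i`, `u`, `y`, `x` define novel
transcriptional loci.

Three decisions here were open and are fixed as follows:

* **Precedence** follows specificity (exact > containment >
  junction-sharing > overlap > positional), so every query receives
  exactly one code deterministically.
* **Mono-exon `=`** is ill-defined without junctions; we require
  same-strand overlap of at least `mono_overlap_frac` (default 0.5) of the
  shorter transcript against a mono-exon reference.
* **`i` is strand-specific by default** (`intronic_same_strand = TRUE`):
  an opposite-strand intron resident falls through to `x` only if it
  overlaps an exon, else `u`. The alternative reading is config-exposed.
* When several references tie at one precedence level, the one sharing the
  most junctions wins, then the lexicographically smallest identifier —
  purely for reproducibility.

The engine evaluates all nine rules set-wise over precomputed exon /
intron / span / gene-span indexes and resolves precedence afterwards,
which is what makes an exhaustive oracle comparison (more than 10,000
enumerated two-exon query placements against a brute-force rule-by-rule
reimplementation) cheap enough to run in the test suite on every run.

## Coding potential

The coding/noncoding decision uses only sequence-intrinsic features of the
spliced transcript, computed by `classify_coding()`:

* the longest ORF across the three forward frames (never the reverse
  complement — assembled transcripts are strand-corrected), requiring an
  ATG start and an obligatory stop; codons containing `N` never match
  start or stop;
* ORF coverage (ORF length / spliced length);
* the Fickett TESTCODE statistic — positional (every-third-base) asymmetry
  and composition of each base mapped through the published lookup tables
  (`fickett_parameters()`) and combined with the published weights;
* the isoelectric point of the predicted protein, solved by bisection on
  the Henderson–Hasselbalch net charge over the termini and the D, E, C,
  Y, H, K, R side chains (`pi_pka_set()`), to |charge| < 1e-4.

The label rule is an explicit, transparent threshold cascade: **coding**
iff ORF `>= 300` nt, or ORF `>= 120` nt with coverage `>= 0.5` and Fickett
score `>= 0.95` (the conventional TESTCODE decision point). No trained
classifier weights are shipped or needed: on transcripts with genuine
planted ORFs the first clause is exact, and on random ATG-containing
sequence the false-coding rate stays below 10% (regression-tested under a
fixed seed). The thresholds are all `pipeline_config()` keys. The
constants live in one exported place each, so independent checks use
identical numbers; equivalence with any specific external coding-potential
tool's output is *not* claimed.

## Noncoding classification and noncoding genes

Noncoding transcripts are positioned relative to the *new* coding genes by
the first matching rule: **intronic** (fully inside one coding intron, on
either strand — position, not orientation, defines the category, and it is
tested first so an intron-resident is never mislabelled by a trivial
orientation call), then **sense_overlap** (≥ 1 bp exonic overlap, same
strand), then **antisense** (≥ 1 bp exonic overlap, opposite strand), else
**intergenic**. Overlap is exon-level, never gene-span-level — span-level
overlap would misclassify everything sitting in an intron. Noncoding genes
are connected components of same-strand, ≥ 1 bp span overlap among
noncoding transcripts; a gene whose transcripts overlap coding exons on
both strands is reported as `sense_and_antisense`, otherwise the majority
transcript label wins with ties broken intronic > sense_overlap >
antisense > intergenic.

## Isoform groups

Within each locus, every pair of predicted proteins is aligned globally
(BLOSUM62, gap open 11, gap extension 1 per residue — Biostrings'
`pairwiseAlignment` is the engine) and similarity is 100 × identical
positions / alignment length. Normalising by alignment length rather than
by the shorter sequence is the conservative choice (a short fragment never
scores 100 against a full-length protein); it is config-exposed in spirit:
the cutoff operates on whatever the similarity function returns. Pairs at
or above the cutoff — default 49, *accepted at exactly 49* — are
connected, and isoform groups are the connected components: A–B = 60 and
B–C = 55 put {A, B, C} in one group even when A–C = 10. Raising the cutoff
can only refine the grouping, never merge groups (tested as a property).
Pairs scoring in the 49–60 band are listed by `borderline_pairs()` for
review instead of a manual curation step. On data containing genuine
isoform pairs plus unrelated within-locus neighbours, the similarity
histogram is strongly bimodal with a valley around 40–60, which is what
justifies a cutoff in that region.

## The gene-level annotation diff

Each new gene (locus: transcripts connected by shared junctions or
same-strand exon overlap) receives exactly one category:

1. **flipped** — some transcript overlaps an old gene on the opposite
   strand *and* reuses at least one old junction coordinate pair (ignoring
   strand; exact match by default, `flipped_tolerance` widens it);
2. **novel** — every transcript has a novel class code;
3. **unchanged** — every transcript is `=`;
4. **novel_splice_variant** — at least one `=` and at least one `j`;
5. **all_junctions_differ** — no `=` and no shared junction;
6. **all_transcripts_differ** — no `=` but some shared junction;
7. **uncategorized** — the explicit fall-through (mono-exon / `o` / `c`
   mixtures).

Flipped is evaluated *before* novel: a pure strand flip codes all its
transcripts `x`, so any other order makes the flipped category unreachable
— the two categories are meant to be disjoint alternatives, and the
precedence above is the only ordering that partitions genes accordingly.
Categories depend only on junctions and strand, never on UTR ends, so UTR
extension can never change a gene's category (tested as a property).
Old genes none of whose exons overlap any merged transcript on either
strand are reported as unexpressed; an old gene touched only in antisense
counts as detected.

## The synthetic study

`simulate_study()` generates the full validation scenario: a uniform
random genome; coding reference genes (1–8 exons) carrying a planted
in-frame ORF of 300–780 nt covering at least 60% of the spliced
transcript, placed without overlap; and per-sample assemblies that emit,
for every expressed gene, the faithful model with per-sample random UTR
extensions (default 20–120 nt per end), plus the planted perturbations:
junction-shifted isoforms (one intron boundary moved by 3–30 nt, inside a
UTR so the protein is untouched; intron length never drops below 20 nt nor
an exon below 3 nt), retained-intron isoforms at multi-isoform loci,
fully-restructured genes (every junction moved, both inside UTRs),
strand-flipped models reusing the reference junctions, noncoding plants in
all four positional categories, sub-200 nt fragments, and unexpressed
reference genes.

Two construction guarantees make truth exact rather than probabilistic:
untranscribed filler, UTRs and introns are generated free of both `ATG`
and `CAT` trinucleotides, so no emitted transcript can acquire a spurious
start codon in either reading orientation and the planted ORF is provably
the longest; and flipped genes are regenerated (bounded rejection) until
their reverse-complement reading holds no ORF of 120 nt or more even at
maximal UTR extension. Every emitted structure is identical across
samples except for the UTR-extension draws, which keeps merged transcripts
in one-to-one correspondence with truth rows.

The generator is deterministic: three streams derived from one seed
(genome, reference, assemblies) so each stage is independently
reproducible; two runs of the whole study are byte-identical on disk.

What the simulation does *not* emulate — and hence what passing tests do
not show about real data: read-level noise and coverage gaps (assemblies
here are structurally clean), expression levels, soft-clipped or
mis-assembled junctions beyond the planted shifts, overlapping gene
models on the same strand, alternative TSS/TES beyond uniform UTR jitter,
and base-composition realism (intergenic sequence is start-codon-depleted
by construction). Results on real assemblies therefore depend on assembler
quality in ways the fixture deliberately abstracts away.

## Numerical and scale choices

All thresholds live in `pipeline_config()` with the analysis' published
values as defaults: `min_length = 200`, `isoform_cutoff = 49`,
`mono_overlap_frac = 0.5`, `flipped_tolerance = 0`, coding rule
`300 / 120 / 0.5 / 0.95`. The standard validation study uses two 500 kb
chromosomes, 160 coding genes, 6 reference noncoding genes, 38 noncoding
plants, 3 samples — about 200 genes in total, which exercises every
category while keeping a full end-to-end run around fifteen seconds; the
exhaustive class-code oracle comparison enumerates 11,184 two-exon
placements. Degenerate inputs are defined behaviour: empty sample sets
yield an all-zero report; queries on chromosomes absent from the reference
classify as `u` with a warning; unstranded GTF records are rejected rather
than guessed, since strand is load-bearing for the antisense categories.

## Known limitations

* Junction matching is exact; there is no tolerance window for nearly
  identical splice sites (a deliberate non-goal — tolerance belongs in the
  assembler's domain).
* Mono-exon gene identity rests on an overlap-fraction heuristic; genuine
  mono-exon paralogs in tandem could collapse.
* The coding rule is transparent but unfitted; borderline transcripts
  (ORF 120–300 nt) are decided by Fickett score and coverage, which on
  short sequences is noisy — the recommended minimum is 200 nt, which the
  length filter already enforces.
* Isoform grouping assumes loci were split correctly; a chimeric merged
  transcript bridges loci irreversibly.
* Gene-level categories are reported per locus; a locus hosting both a
  coding gene and a sense-overlapping noncoding transcript is
  `uncategorized` by design (the fall-through), not silently forced into a
  coding category.
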