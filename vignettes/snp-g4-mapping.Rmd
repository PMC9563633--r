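---
title: "Mapping cDNA-level SNPs to predicted G-quadruplex regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cDNA-level SNPs to predicted G-quadruplex regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4snp)
```

## The problem

G-quadruplexes (G4s) are four-stranded secondary structures that form in
guanine-rich DNA and RNA tracts and participate in gene regulation. A
single-nucleotide polymorphism (SNP) falling inside or near a G4-forming
tract can change the tract's folding propensity and, with it, expression of
the gene. Deciding whether a clinically reported variant does so requires
two coordinate gymnastics that are easy to get wrong by hand:

1. Variants are reported in HGVS cDNA notation (`c.506-1G>A`), anchored to
   coding positions of a spliced transcript, while G4 predictions live in
   genomic coordinates of the gene's sequence. Converting between the two
   means walking the exon structure.
2. Each variant must then be matched to the overlapping or nearest
   predicted G4 region, with distances expressed relative to a common
   origin.

`g4snp` implements both steps for a single gene at a time: an exon-walking
locator, a built-in G4Hunter-style scanner (so no web service is needed),
and a nearest-region annotator, together with readers and writers for the
plain-text file dialects the original two-program workflow used.

## The coordinate model

A `gene_model()` is the frame everything maps into: the genomic sequence of
one gene (its coding strand, 5'→3'), an ordered list of exon intervals in
0-based half-open coordinates, and the 0-based offset of the A of the ATG
start codon. All reported distances are signed offsets from that A, which
sits at 0; negative distances are upstream. This origin-at-ATG convention
is chosen because it makes the conversion invertible and matches how the
locator's output distance is consumed downstream.

HGVS cDNA anchors are interpreted as follows:

* `c.K` — the K-th coding base counted along the spliced exons, `c.1` being
  the A of ATG. With no CDS-end annotation in the model, coding positions
  simply continue to the last exonic base.
* `c.K+N` / `c.K-N` — N genomic bases into the intron after/before coding
  base K, which must be the last/first coding base of its exon; a variant
  violating that signals a gene model inconsistent with the variant and is
  a structure error, not silently remapped.
* `c.-M` — M bases upstream of the ATG along the spliced transcript. When M
  exceeds the transcribed bases available, counting continues contiguously
  into the genomic sequence upstream of exon 1. HGVS has no standard
  notation beyond the transcript; this contiguous extension is what lets
  promoter and upstream regulatory variants be located at all.
* `c.*M` — M bases downstream of the last exonic base, continuing
  contiguously into the 3' flank by the same rule.

`genomic_to_cdna()` classifies *every* base of the sequence. Intron bases
follow the HGVS midpoint rule: the 5' half of an intron is anchored `+N` to
the preceding exon, the 3' half `-N` to the following exon, with the middle
base of an odd-length intron assigned to the `+` side. Consequently
`genomic_to_cdna(cdna_to_genomic(v))` is the identity on canonical
descriptors; a non-canonical but HGVS-legal descriptor such as `c.K+N` past
the intron midpoint still maps to the correct base and simply
re-canonicalises to the `-` form. One representational corner is worth
noting: an intron flanked by an entirely non-coding exon would need an HGVS
form (`c.-M+N`) that plain substitution grammar does not cover; the
classifier emits a negative-anchor intronic descriptor for such bases, but
the parser deliberately accepts only the five substitution forms.

The FASTA is assumed to be the coding strand read 5'→3'. Minus-strand genes
must be supplied reverse-complemented; if reference-base checks fail
systematically, that is the first thing to suspect, and
`verify_ref_base()` exists precisely to surface it. The check is lenient by
default (a warning) because variant nomenclature and reference sequences
drift out of sync routinely; `strict = TRUE` makes a mismatch fatal. An `N`
at the target position is reported as indeterminate, never as a match.

## The scanner

The built-in scanner reproduces the G4Hunter scoring idea: each base in a
maximal run of *n* consecutive G scores +min(*n*, 4), each base in a run of
*n* C scores −min(*n*, 4), A/T/N score 0 (N breaks runs). A window of
means is slid along the sequence and windows whose |mean| reaches the
threshold are kept; same-sign windows that overlap or abut merge into
maximal regions. A region's score is the mean of per-base scores over the
merged span, and its most extreme window mean is reported alongside.
Positive regions are G-rich on the given strand, negative regions C-rich
(G-rich on the opposite strand); reverse-complementing a sequence exactly
negates and reverses its base scores, and the tests assert this
antisymmetry.

Defaults are window 25 and threshold 1.2 — the conventional G4Hunter
operating point. The original workflow never recorded which parameters it
used, so these defaults are a declared choice, not a reproduction; both are
exposed on `find_g4_regions()` and the `scan` subcommand. Because merging
extends a region to the full span of its hit windows, a planted 21-mer
motif is typically reported inside a slightly wider region; containment,
not coordinate equality, is the right expectation when validating against
planted motifs.

The merge rule (overlap-or-abut, same sign only) and the region-score
definition are fixed here for determinism; the web tool's exact
post-processing is not documented and no attempt is made to mimic it beyond
the scoring rule itself.

## Nearest-G4 annotation

Two distance modes are provided, and every output row records which one
produced it:

* `start_only` (default) reproduces the original procedure exactly: each
  region's start is expressed as a signed distance from the start codon,
  the absolute difference to the variant's distance is taken, and the
  minimum wins — i.e. distance to the G4 *start*, ignoring its extent.
* `interval` treats regions as intervals: distance 0 with relation
  `overlapping` when the variant lies inside `[start, end)`, otherwise the
  gap to the nearer edge. This is added because "overlap" implies
  containment, which a start-only distance cannot express; a variant in the
  middle of a long G4 can be tens of bases from its start.

Distances are reported as absolute values with a separate relation field
(`upstream` / `downstream` / `overlapping`, the G4 relative to the SNP),
since the original minimum-extraction step does not state a sign
convention and a signed minimum would conflate the two sides. Ties are
broken toward the smaller genomic start so output is deterministic; batch
output is sorted by gene and variant text so it is independent of input
order.

## The synthetic fixture generator

`simulate_gene()` emulates a compact gene: i.i.d. background sequence at
40% GC, four exons of 80–200 bp, introns of 60–300 bp, 400 bp flanks, a
30 bp exonic 5'UTR with a literal ATG written at the start codon. These
defaults were chosen once as a realistic compact-gene geometry (they keep
every region class — exon, intron, 5'UTR, upstream flank — large enough to
plant variants in) and are not tuned to any test outcome. `plant_g4()`
splices the human telomeric repeat `GGGTTAGGGTTAGGGTTAGGG` (a canonical
quadruplex former) over existing bases so coordinates stay fixed;
`plant_variants()` samples truth positions per region class, naming each as
an HGVS substitution whose reference base is read from the final sequence.
The default 4-gene, 31-variant fixture mirrors a validation design of 31
substitutions spread over all four region classes.

What the generator does *not* emulate: real exon/intron length
distributions, GC isochores, repeat structure, splice-site motifs, allele
frequencies, or minus-strand genes. A green end-to-end test therefore
establishes that the coordinate arithmetic, scanning and joining are
correct on plausibly shaped inputs — not that any particular human gene is
handled, and not that the scanner's threshold is biologically optimal.
One consequence of an honest i.i.d. background is that it occasionally
contains genuine G/C tracts above threshold; these are correct predictions,
so pipeline validation compares the annotator against an independent
brute-force minimum over the *predicted* region set, while separately
asserting that every planted motif is recovered.

## Numerical and degenerate-input choices

* Sequences shorter than the scan window yield an empty result with a
  warning, not an error (a short promoter fragment is a legitimate input).
* An empty region list passed to the annotator is a distinct error
  ("no regions") rather than an empty annotation, so "no G4s predicted" is
  never confused with "no overlap".
* The G4-table dialect stores 1-based inclusive starts (the convention of
  the web tool's R-based output); they are converted to 0-based on read,
  and rows lacking an `end` column derive it from the sequence length.
  Unknown trailing columns are ignored. Malformed rows are rejected with
  their line number; nothing is silently skipped.
* Writers emit a canonical tab-separated form whose write→read→write cycle
  is byte-identical, which the tests assert on random record sets.
* All randomness is seed-controlled, and seeded helpers restore the global
  RNG state on exit.

## Known limitations

Single transcript per gene; substitutions only (indels, duplications and
delins are rejected loudly rather than mis-mapped); plus-strand input
assumed; one gene per FASTA record; no statistical enrichment testing of
SNP–G4 co-occurrence, which is a question about study design rather than
coordinate arithmetic.
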