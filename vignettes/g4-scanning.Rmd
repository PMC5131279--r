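---
title: "Scanning for putative G-quadruplexes: grammar, scores and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for putative G-quadruplexes: grammar, scores and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scan)
```

## The model

A G-quadruplex is a four-stranded nucleic-acid structure built from stacked
G-tetrads — planar arrangements of four guanines held by Hoogsteen hydrogen
bonds and stabilized by monovalent cations. A *putative quadruplex sequence*
(PQS) is the sequence-level signature of an intramolecular quadruplex: four
guanine tracts separated by three loops,

$$\mathrm{G}^{Y_1}\,\mathrm{X}^{Y_2}\,\mathrm{G}^{Y_1}\,\mathrm{X}^{Y_2}\,
  \mathrm{G}^{Y_1}\,\mathrm{X}^{Y_2}\,\mathrm{G}^{Y_1},$$

where each tract length $Y_1$ ranges over 2..7 nucleotides, each loop length
$Y_2$ over 1..7, and every loop position X is an arbitrary nucleotide
(including G). The number of tracts is fixed at four — that is what the
grammar means — so regions with five or more tracts yield one (leftmost)
call, not an enumeration of alternatives. With the default ranges the
longest acceptable motif is $4 \cdot 7 + 3 \cdot 7 = 49$ bases; this ceiling
is implied by the ranges, not applied as a separate filter. Both strands are
scanned, because a quadruplex may form on either; the antisense scan runs on
the reverse complement, and antisense hits are mapped back to input
coordinates (a reporting convention this package fixes explicitly, since
either convention is defensible).

Matching a PQS says the sequence *can* fold, not that it does: folding in
vivo depends on cation conditions, tract number beyond four, loop lengths
and competing structures. The companion cG/cC score addresses the most
common source of false positives — G-rich calls sitting inside regions that
are equally C-rich, where the complementary strand competes for the duplex.

## Scanning semantics

Hits are **leftmost and non-overlapping per strand**: the scanner takes the
earliest position where any tract/loop assignment matches, reports it, and
resumes immediately after the hit's end. Non-overlap is enforced per strand
only; a sense hit and an antisense hit may overlap in input coordinates
because the two scans are independent.

Within a match the decomposition is made deterministic by a stated
tie-break: **tracts greedy (longest first), loops lazy (shortest first)**,
with full backtracking. The scanner is implemented as a backtracking regular
expression whose engine explores exactly that preference order, so the
reported decomposition is the first success in lexicographic order over
$(t_1\downarrow, \ell_1\uparrow, t_2\downarrow, \ell_2\uparrow,
t_3\downarrow, \ell_3\uparrow, t_4\downarrow)$. Greedy tracts maximize the
guanines assigned to tetrads, which is the conservative PQS reading; a G-run
longer than seven contributes its leftmost seven guanines to a tract, with
surplus guanines available to the adjacent loop or a later tract through
backtracking. The test suite checks the scanner hit-for-hit against an
independent exhaustive enumerator of all assignments that applies the same
selection rule.

Coordinates are 1-based and inclusive, the display convention of sequence
analysis tools in this area. The scanner itself is fully deterministic: no
randomness, no seeds.

### Alphabet and degenerate inputs

Only A, C, G, T, U, N are accepted; other IUPAC ambiguity codes are rejected
with a position-reported error rather than silently matched, because a
two-valued code in a loop would make "any nucleotide" ambiguous. N may
appear in loops (it is some nucleotide) but never counts toward a tract and
breaks scoring runs. U is mapped to T internally so one engine serves DNA
and RNA; reported hit sequences restore U for RNA records. A sequence with
both T and U is rejected as unclassifiable. Empty sequences are legal and
yield empty scans.

## The cG/cC score

The cG scoring rule is usually stated verbally — 10 for each G, 20 for each
GG pair, 30 for each GGG triplet, and so on — which leaves the algebra
open. This package adopts the cumulative overlapping-window reading: every
window of $k$ consecutive guanines
contributes $10k$, so a maximal run of $L$ guanines scores

$$\mathrm{cG}(L) = \sum_{k=1}^{L} 10\,k\,(L-k+1) = \frac{10\,L(L+1)(L+2)}{6},$$

giving 10, 40, 100, 200, ... for runs of 1, 2, 3, 4. The alternative
non-cumulative reading (a run of three scoring only 30) would make the score
linear in run length and no more discriminating than G-counting; the
cumulative reading rewards long runs superlinearly, which is the point of
the score. cC is defined symmetrically on cytosines, so
$\mathrm{cC}(s) = \mathrm{cG}(\bar{s})$ for the base-paired complement
$\bar s$, and the cG/cC ratio compares the two strands' quadruplex-forming
potential at a locus. Sentinels keep the ratio total: `Inf` when there are
guanines but no cytosines, `NA` when there are neither (serialized as
`inf` and `NA` in TSV output).

Hits are scored over the motif plus a symmetric flank, clipped at the
sequence ends, because nearby C-richness is exactly what the ratio is meant
to detect. The flank default is **15 nt per side** — enough context to cover
a competing C-tract cluster immediately up- or downstream without diluting
the motif's own contribution; it is configurable, and `flank = 0` reproduces
motif-only scoring. Antisense hits are scored on the reverse-complement
window — the strand the motif actually lies on — not on the sense text.

## The interaction record store

The record store is a flat-file stand-in for a relational catalogue of
curated G4–protein interactions: one row per interaction, keyed by a
free-form interaction id, carrying protein identity (name, synonyms,
UniProt id and entry name, gene, organism, FASTA), the nucleic-acid target
(name, sequence, DNA/RNA category), binding parameters ($\Delta T_m$ in
°C, $K_a$ in M$^{-1}$, $K_d$ in M), provenance (PMID, authors, technique)
and structure pointers (PDB ids, interacting residues). TSV (with `;` as
the list delimiter) and JSON are read and written losslessly.

Search semantics were genuinely open, so they are fixed as the most
permissive deterministic choice and documented: **case-insensitive
substring** matching for every field including PMIDs and sequences, quick
search as a disjunction over all text fields, and advanced search as a
conjunction (AND) over its ten criteria fields. Both are tested against a
naive per-record filter oracle. Numeric invariants (positive $K_a$/$K_d$,
all-digit PMIDs, category-consistent target alphabets) are enforced at load
time, with violations named per record and field.

## Synthetic data

The generators exist so that every claim the package makes is checkable
offline, with no downloads.

`generate_sequence_with_motifs()` plants a known number of motifs into a
background built to be motif-free *by construction*: i.i.d. A/C/G/T with
every GG and CC dinucleotide broken, so at the default minimum tract of two
neither strand can host a single tract, let alone four (the generator
refuses `min_tract = 1` for this reason). Planted motifs draw their tract
and loop lengths uniformly over the allowed ranges; loops use A/T only and
the single background position flanking each motif is forced to A/T, so
greedy tract matching cannot absorb a neighbouring guanine and shift the
reported coordinates. Antisense plants are inserted as reverse complements.
As a belt-and-braces check the assembled sequence is re-scanned and must
reproduce the planted truth exactly before it is returned. All randomness is
seeded and local — the caller's RNG state is saved and restored — so a
fixture is a pure function of its arguments.

What this emulates is the *geometry* of real PQS-bearing sequence: motif
density, strand mixture, tract/loop variability. What it deliberately does
not emulate: realistic genome composition (GC skew, repeats, G-runs of two
that almost form motifs), overlapping or bulged quadruplexes, and borderline
cases like five-tract regions. Passing the recall tests therefore shows the
scanner is exact on its grammar, not that the grammar captures every
biological quadruplex.

`generate_records()` produces schema-valid interaction records with
field values in realistic ranges — $K_d$ log-uniform over $10^{-9}$ to
$10^{-6}$ M, $K_a$ log-uniform over $10^{6}$ to $10^{9}$ M$^{-1}$,
$\Delta T_m$ uniform over 0–25 °C, categories split evenly — plus, on
request, three fixed anchor records (a Nucleolin entry under id G4DIP1, an
NDPK1/NM23-H2 entry with PMID 25679041, and an FMRP entry) that the search
tests use as known ground truth. Anchor records are synthetic reconstructions
for testing, not curated data.

## Validation problem sizes

The shipped test suite checks, among other things: scanner equivalence with
the exhaustive enumerator on 1,000 seeded random sequences of up to 200 nt
across GC contents from 15–85%; exact-coordinate recovery of 5 planted
motifs per 1,000-nt fixture across 100 seeds, with zero false positives on
100 motif-free backgrounds; the scoring algebra exhaustively on all strings
of length ≤ 8 over {A, G} and on 10,000 random strings; and search
equivalence with the naive filter oracle on a 200-record synthetic store.
These sizes were chosen to exercise every boundary of the grammar (motifs at
sequence ends, adjacent motifs, maximal spans) while keeping a full test run
in the minutes range on a laptop.

## Command-line interface

The `g4scan` launcher exposes `scan`, `score`, `db-search`, `db-validate`
and `fixtures` subcommands. Results go to stdout or `--out` (written via a
temporary file, so failed runs leave no partial output); logs and
per-sequence summaries go to the error stream; exit codes are 0 for success
(an empty result set is success), 1 for usage errors and 2 for
data/validation errors. Identical invocations produce byte-identical
output.

## Known limitations

- The grammar is the classic four-tract pattern: bulged tracts, two-tetrad
  quadruplexes with mismatches, and intermolecular quadruplexes are out of
  scope, as are sliding-window propensity scores and thermodynamic
  stability estimates.
- Only one non-overlapping hit is reported per covered region and strand;
  there is no mode enumerating alternative overlapping placements.
- The cG/cC score has no calibrated fold/unfold threshold here; it is a
  comparative score, and its cumulative-window algebra is an interpretation
  of a verbal definition (documented above).
- Scanning is in-memory; chromosome-scale inputs work but are not streamed.
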