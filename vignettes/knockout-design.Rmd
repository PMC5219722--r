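---
title: "Designing knockouts of overprinted genes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing knockouts of overprinted genes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overko)
```

## The problem

Overprinted genes share nucleotides with a second coding sequence read in
a different frame or on the opposite strand. Excision knockouts are
impossible at such loci, so the standard design is a minimal substitution
set that truncates the *target* gene — a premature stop codon, or loss of
the initiation codon — while leaving the *overlapping* gene's amino acid
sequence exactly unchanged. The degeneracy of the genetic code makes this
possible surprisingly often: a substitution that creates TAA, TAG or TGA
in the target frame frequently lands in a synonymous position of the
shifted overlapping frame.

`overko` models exactly this search, plus the practical cloning
companion: each candidate is annotated with the restriction-enzyme
recognition sites it adds or removes, so the mutation can be traced by a
diagnostic digest rather than sequencing.

## The procedure

For a validated pair (target, overlapping, geometry):

1. **Geometry.** `find_overlap()` finds the longest exact common
   substring between the target and either strand of the overlapping
   gene. The result records the shared interval in both coordinate
   systems, the strand, and `frame_shift` — the overlapping gene's codon
   phase at the start of the shared region (always `overlap_start mod 3`).
   `map_position()` bridges a target nucleotide position to the
   overlapping gene's (codon, offset), reversing and complementing on the
   opposite strand.

2. **Candidate enumeration.** For each target codon index
   `i` in `[1, codon_window)` that is not already a stop,
   `stop_substitutions()` lists the stop codons within
   `max_edits_per_codon` Hamming distance. Codon 0 is handled separately:
   any mutation of ATG to a non-ATG codon is a start-loss candidate
   (premature stops and start losses are kept disjoint by construction).
   Edits are confined to a single codon per candidate — the design unit
   of site-directed mutagenesis — and compound multi-codon mutants are
   deliberately out of scope.

3. **Preservation check.** An edit set passes if every overlapping-gene
   codon it touches (through the geometry map) translates to the same
   amino acid as the wild type. Edits falling outside the shared span are
   unconstrained. Only the touched codons need re-translation — untouched
   codons are bitwise identical — but the test suite independently
   verifies full-protein equality with a third-party translator for every
   emitted candidate.

4. **Tracer annotation.** Site changes are the keyed set difference
   (enzyme, position, strand) of scans of the full wild-type and mutant
   target — the construct being cloned — not just the overlap region.
   Internally the scan is restricted to windows of one recognition length
   around the edits, which is provably equivalent for substitution-only
   mutants and is enforced against the whole-sequence scan in tests.

Candidates are ordered by (codon index, edit count, mutant codon
alphabetically), start losses first, making every report byte-for-byte
reproducible.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_edits_per_codon` | 1 | Substitutions per candidate (1 = point mutation). 2–3 widen the search monotonically. |
| `codon_window` | whole gene | Premature stops are searched in codons `[1, W)`. The survey statistic "knockable within the first 20 codons" is `first_knockout_codon(...) < 20`, i.e. 0-based index ≤ 19; we document this reading because "within the first 20 codons" is ambiguous between 0- and 1-based counting. |
| `allow_start_loss` | TRUE | Also report codon-0 knockouts. Start losses are never filtered by plausibility; candidates whose mutant codon is a known near-cognate start (ACG, GTG, TTG, CTG, ATT, ATA) are *flagged*, since some viruses initiate from such codons — the tool reports, the experimenter decides. |
| `site_change_mode` | "none" | Tracer filter: keep candidates that add, remove, or either. |
| `min_len` (overlap) | 15 nt | Minimum accepted overlap; below ~15 nt chance matches between unrelated sequences become likely. |

A wild-type target with an internal stop triggers a warning rather than
an error: annotation errors are common in harvested genomes, and the
search result is still well defined.

## Numerical and representational choices

* Coordinates are 0-based and half-open throughout, and codon indices are
  0-based (the initiation codon is index 0), matching how interactive
  knockout reports are conventionally indexed.
* Input is normalised: uppercase, RNA `U` → `T`. The 15-letter IUPAC
  alphabet is accepted everywhere except where a contract requires
  concrete bases (translation spans, scanned sequences). Validation
  errors name the offending position.
* Translation is full-length: stop codons emit `*` and translation
  continues, so internal stops are visible to the verification logic. A
  trailing partial codon is ignored.
* Overlap detection requires *exact* substring identity. The two inputs
  describe the same genomic region, so a mismatch indicates user error
  and must surface rather than be smoothed over. Ties (two maximal
  matches of equal length on the preferred strand) are an explicit
  ambiguity error; callers with repetitive sequence pass an
  `overlap_geometry()` directly. Same-strand matches are preferred over
  opposite-strand matches of equal length.
* Degenerate pattern matching is implemented as bitmask intersection over
  {A,C,G,T} bits, with non-palindromic recognition sequences scanned on
  both strands and palindromic ones reported once.
* The genetic code is a plain named vector; alternative codes can be
  passed to `translate()` programmatically, but only the standard code is
  bundled and used.
* The bundled hydrophobic residue class {A, V, L, I, M, F, W, P} used by
  `constrained_codon_mutagenesis()` is a documented convention, not a
  universal definition; pass your own predicate to change it.

## What the synthetic generator emulates

`generate_pair()` plants a contiguous shared region between two freshly
sampled ORFs. Both genes are valid ORFs in their own frames — ATG start,
exactly one terminal stop — and construction is by repair sampling:
codons whose projection into the partner frame creates a stop are
resampled until both frames are clean, and the flank bases adjacent to
the planted span are forced to mismatch their continuation so that the
planted geometry is exactly the longest common substring and detection
can be tested as an exact round trip.

Defaults, chosen once as plausible for small viral overprinted loci:
target length 30–150 codons, overlap fraction 0.4–1.0 of the target,
probability 0.25 of an opposite-strand partner, same-strand frame shift
uniform on {1, 2} (shift 0 would collapse both genes into one frame),
uniform base composition.

What this does **not** emulate: real codon-usage and GC-content biases,
spliced overlaps, overlaps with indels, loci shared by three or more
genes, or the length and composition distributions of any particular
virus collection. Survey numbers computed on synthetic pairs therefore
support *ordering and stability* statements — e.g. requiring a tracer
site change can only delay the first reachable stop — but not the
absolute percentages one would measure on harvested genomes, and the
package makes no such claim.

One analytic anchor exists in the degenerate no-overlap limit: when the
shared region shrinks to nothing, the probability that a uniform-composition
ORF is knockable within its first 20 codons approaches
$1 - (1 - p_1)^{19}$, where $p_1$ is the chance that a uniform non-stop
codon lies one substitution from a stop ($p_1 = 18/61$ by enumeration).
The test suite checks the simulated fraction against this closed form
within three binomial standard errors at 2000 pairs.

## Problem sizes used in the test suite

The suite verifies the search against a brute-force oracle (all `9L`
single-base variants, third-party translation) on 200 generated pairs of
12–35 codons across both strands and both frame shifts; restriction
scanning against an expand-degenerate-and-scan oracle on 100 random
500-mers with the full builtin table; geometry recovery on 500 planted
pairs with overlaps ≥ 30 nt; and survey stability at 1000 pairs per seed.
These sizes were chosen to exercise every code path with comfortable
statistical resolution while keeping the default test run fast.

## Known limitations

* Substitution-only model: insertion/deletion (frameshift) knockouts are
  out of scope, as is codon-usage optimisation of the mutants.
* One contiguous overlap per pair. A gene overlapping two partners is
  handled by running each pair separately.
* Restriction modelling covers recognition-site presence only — no cut
  positions, overhangs, methylation sensitivity or star activity.
* Start-loss efficacy is biology, not arithmetic: near-cognate initiation
  means ACG-type mutants need experimental validation, which is why they
  are flagged rather than suppressed.
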