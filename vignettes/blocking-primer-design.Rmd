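---
title: "Designing elongation-arrest blocking primers with bpdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing elongation-arrest blocking primers with bpdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpdesign)
```

## The model

Host-associated samples sequenced with a universal eukaryotic marker (here
the 18S rRNA V9 region, amplified by 1389F/1015R) yield libraries dominated
by the host's own rRNA genes. A blocking primer suppresses this: an oligo
complementary to a host-specific stretch of the amplicon *interior* — the
region strictly between the two amplification-primer footprints — whose 3'
end carries a C3 spacer. The spacer permits annealing but not enzymatic
extension, so the polymerase extending from either amplification primer is
physically arrested at the bound blocker. This is *elongation-arrest*
blocking; it is distinct from anneal-inhibiting blockers that compete with
an amplification primer for its own binding site, which is why a candidate
may never overlap a primer footprint.

`bpdesign` treats blocker design as a deterministic rule-filtering problem
over candidate windows of the host interior:

1. **In-silico PCR.** Both amplification primers are located on the host
   by exhaustive degeneracy-aware scanning of every offset on both strands.
   Two IUPAC codes *match* iff their base sets intersect (`R` matches `A`;
   `N` matches everything): this is how a degenerate primer behaves during
   annealing, and it makes the packaged degenerate primers self-consistent.
   A unique productive forward/reverse pairing is required; ambiguity is an
   error rather than a silent first-hit choice, because blocker placement
   is meaningless on a non-unique amplicon.
2. **Enumeration.** Every window of `min_len`–`max_len` nt fully inside
   the interior, in both orientations.
3. **Screening.** Each window must (a) occur exactly once on the host
   (degeneracy-aware, both strands, counted as distinct plus-strand
   intervals), and (b) sit at least `min_offtarget_mismatches` mismatches
   from every off-target under an ungapped semi-global comparison: the
   candidate slides along the off-target at every offset on both strands
   and the minimum mismatch count is taken. Off-targets *shorter* than the
   candidate are compared over all full-overlap diagonals with uncovered
   candidate positions counted as mismatches, so short decoys cannot pass
   trivially.
4. **Ranking and emission.** Survivors are stably sorted by descending
   off-target minimum, then GC closest to 0.5, then shorter length, then
   5'-most start, and the top *k* become C3-spacer oligos. The ranking is
   a tool convention (the selection rules define acceptability, not an
   order) and is flagged as advisory in every report header.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_len` | 20 | nt | minimum gene-specific blocker length |
| `max_len` | 30 | nt | enumeration cap; typical upper bound for synthesized blocking oligos |
| `min_offtarget_mismatches` | 3 | mismatches | minimum distance to every off-target |
| `require_host_unique` | TRUE | — | candidate must occur exactly once on the host |
| `footprint_overlap_allowed` | FALSE | — | elongation-arrest placement: no footprint overlap |
| `max_primer_site_mismatches` | 0 | mismatches | amplification-primer annealing tolerance |
| `t_block` (simulator) | `min_offtarget_mismatches − 1` = 2 | mismatches | threshold at or below which a blocker is considered bound |

`max_primer_site_mismatches = 0` because degeneracy-aware matching already
encodes the intended wobble of the degenerate primers; no further annealing
model is assumed. The simulator default `t_block = 2` makes design and
simulation mutually consistent: anything the design rules kept ≥ 3
mismatches away can never be collaterally bound.

The binding model is deliberately minimal — an oligo binds iff it matches
with at most `t_block` mismatches, outcomes are binary per template, and no
melting temperatures, PCR efficiencies or cycle counts are modelled. Any
richer model would be invented thermodynamics; GC fraction is therefore
reported as advisory metadata only and plays no part in acceptance.

## Orientation

Which strand a blocking primer should target is left open by the
elongation-arrest mechanism itself: a blocker annealed to the plus strand
arrests extension from one amplification primer, a minus-strand blocker
the other. The tool therefore enumerates and validates both orientations
and records the strand explicitly; emitting the top window in both
orientations (the default `k = 2`) blocks both extension passes, mirroring
the common practice of pairing a forward-blocking and a reverse-blocking
oligo.

## Coordinates and numerical conventions

All coordinates are 0-based half-open on the plus strand; `end − start` is
always the slice length. Ties in ranking preserve input order (stable radix
sort). Reports are written with fixed column order and fixed numeric
formatting so identical inputs give byte-identical files. An empty
off-target library yields an explicit "unscreened" status — never a silent
pass — and a candidate set designed without screening is rejected
wholesale with reason `unscreened_specificity`.

## What the synthetic fixtures emulate

Tests and the acceptance script run on seeded synthetic data built by the
`fixture_spec()` generator family, with defaults chosen once as a realistic
desk-scale study: a 500 nt host region (the scale of a partial 18S
reference) containing the real 1389F/1015R binding sites around a 120 nt
interior (the V9 hypervariable region is ~120–130 nt), uniform 50% GC
background, six off-targets at interior distances 3–8, and a 20-template
mock community with an expected host share of 0.5 (host rRNA dominance is
the motivating regime; 0.5 keeps both outcome classes well populated at
this community size).

Two structural choices matter for interpretation:

* Off-targets share the host's amplicon scaffold and differ only inside
  the interior, at an *exact*, generator-verified mismatch distance. This
  makes them maximally adversarial for specificity screening (they
  amplify, and they are nearly identical to the host) and makes the
  distance a controlled dial for parameter-recovery tests.
* Each off-target's divergence is drawn within one shared focal stretch of
  the interior rather than scattered uniformly. Relatives whose divergence
  from the host concentrates in a short diagnostic stretch of the
  hypervariable region are precisely the situation in which a
  species-specific blocking site exists; scattered single differences
  would (correctly) leave no acceptable window, since no 20–30 nt window
  could cover three of them for every off-target.

The generator does **not** emulate indels (the screen is ungapped by
design), phylogenetically realistic 18S evolution, rRNA secondary
structure, chimeras, or abundance-weighted PCR kinetics. Passing tests
therefore demonstrate that the rules, coordinates and screening mathematics
are implemented correctly — not that a blocker designed on real references
will achieve any particular wet-lab suppression efficiency, which depends
on annealing thermodynamics this tool intentionally does not model. The
published fly blockers are validated against the *rules* here;
reproducing them as the top-ranked design would require the original
curated eukaryote reference library, which is not part of the package.

## Degenerate-base bookkeeping

The packaged 1015R primer contains one `Y`, so it denotes exactly two
concrete oligos; the synthetic host embeds its binding site with `Y`
resolved to `C` (a fixed, documented choice) and the degeneracy-aware
matcher finds it at zero mismatches. Host-uniqueness counts distinct
plus-strand intervals, so a palindromic candidate matching both strands of
one locus counts once.

## Problem sizes

The test suite screens ~2,100 candidate windows against six off-targets on
a 500 nt host in seconds; oracle-equivalence suites compare the sliding
implementations against naive double-loop references on 500 random
instances with targets up to 2,000 nt, and the fixture generators are
exercised over hundreds of seeds. These sizes were chosen as the smallest
that exercise every code path and boundary (footprint abutment, short
off-targets, palindromes, ambiguous amplicons) while keeping the default
`R CMD check`-style run comfortably interactive.

## Known limitations

* Ungapped screening only: an off-target that aligns to a candidate with
  an indel is scored at its best ungapped diagonal, which overestimates
  its distance. Gapped screening is out of scope.
* The mismatch-threshold binding model ignores position within the oligo
  (a 3'-terminal mismatch counts the same as a 5' one) and temperature.
* One primary host reference at a time; additional host sequences can be
  supplied as mandatory-match references but multiplex design across hosts
  is not attempted.
* The real host 18S accession recorded in the fixture metadata is never
  fetched; validation against it requires the user to supply the FASTA.
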