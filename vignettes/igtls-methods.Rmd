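---
title: "Methods: event classification, bypass calling and count statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event classification, bypass calling and count statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtls)
```

This vignette documents the models and procedures the package
implements, the parameters that matter, the numerical conventions, and
the design decisions taken where the problem left genuine latitude.

## 1. The biological readouts

DT40 B cells constitutively diversify their rearranged Ig V&lambda;
segment. AID deaminates cytosines in the locus; uracil excision leaves
abasic sites whose bypass produces either single-base substitutions
(mutagenic TLS) or gene-conversion tracts copied from the upstream
array of V&lambda; pseudogenes (homologous recombination). Sequencing
clonally expanded cells and classifying each change against the donor
array therefore reads out the balance between the two pathways.

A complementary readout replicates episomal plasmids carrying
site-specific T-T (6-4) photoproducts. In the staggered construct the
two strands each carry one lesion, 28 nt apart, each placed opposite a
`GC` marker dinucleotide, so the replicated product's sequence at the
two sites encodes the bypass route: template switching copies the
marker, TLS inserts bases (most often `AA`) opposite the lesion. In
the opposing construct both lesions occupy the same site, template
switching cannot yield a full-length product, and replication is
either TLS or associated with deletion across the site.

## 2. Mutation calling

Clones are aligned to the parent with end-to-end Needleman–Wunsch
(affine gaps, via `Biostrings::pairwiseAlignment`). Defaults: match
+1, mismatch −2, gap open −6, gap extend −1 (a gap of length L costs
`open + L·extend`). These favor isolated substitutions over
compensating indels in near-identical V segments, which is the right
bias for amplicons a few percent diverged from their reference.

Calls are emitted per alignment column; adjacent gap columns merge
into one indel. Columns containing `N` are uncallable and skipped.
Indels are **left-normalized** against the parent (shifted to the
smallest equivalent position, never across another call), the standard
variant-normalization convention: equivalent alignment optima then
yield identical call sets, and applying the calls to the parent
reconstructs the clone exactly (a property the test suite asserts over
randomized cases). Clones whose changed footprint exceeds 10% of the
parent (configurable) are flagged as likely mis-tracked sequences and
excluded.

## 3. The three-category classifier

Every called mutation is assigned to exactly one event:

* **PM** — no donor contains a contiguous exact match to the clone of
  length ≥ `min_donor_string` covering the mutated position.
* **GC** — such a donor string exists and the same donor *explains* at
  least one further mutation of the clone; all mutations that donor
  explains form a single conversion event.
* **Amb** — a qualifying string exists but nothing else is
  co-explained.

Interpretation choices, fixed here and applied consistently:

* "More than 9 bp" means a single contiguous clone–donor match of
  ≥ 10 nt covering the mutation; the flanks need not be symmetric.
  `min_donor_string` defaults to 10 and is configurable.
* "Explained by the same donor" requires only base agreement between
  clone and donor at the homologous position — the ≥ 10 nt string is
  demanded of the seed mutation, not of every member.
* Homology is positional: donors are aligned to the parent once (same
  aligner) and read through that alignment, so donors of unequal
  length are handled uniformly.
* Mutations are visited in parent order. When several donors qualify,
  the winner explains the most mutations, then has the longest donor
  string, then the lexicographically smallest id — classification is
  therefore independent of donor file order. All qualifying donors are
  retained for audit.
* Indels are eligible for GC/Amb like substitutions (a deletion
  matching a donor deletion is templated evidence), but spectra count
  substitutions only.
* The reported GC tract is the minimal interval covering the members,
  extended while clone, donor and parent all agree — a "maximal
  credible tract" that affects reporting only, never category counts.
* Donors are searched in sense orientation by default;
  `search_revcomp = TRUE` adds the reverse complement.
* Amb calls are reported as Amb; the package never relabels them as
  short-tract conversions, however plausible that reading is.

Raising `min_donor_string` can only move events toward PM
(monotonicity), and the partition property (every mutation in exactly
one event) holds by construction; both are asserted as properties in
the tests, and the whole classifier is checked against a brute-force
substring-enumeration oracle on hundreds of random small instances.

## 4. Bypass-product classification

Products are first oriented: both the read and its reverse complement
are aligned to the reference and the better score wins (ties go
forward). Reads below 90% identity outside the lesion region
(configurable) are counted as unclassifiable and excluded from
denominators. The staggered decision table on the two site
dinucleotides, as read from the product:

| top site | bottom site | call |
|---|---|---|
| marker | marker | error-free (template switch) |
| other/del | marker | TLS on the top strand |
| marker | other/del | TLS on the bottom strand |
| other/del | other/del | other (flagged for review) |

For a top-strand lesion the nascent strand is the bottom strand, so
the inserted bases are the complement of the product read, taken in
synthesis order 3′ T, 5′ T, +1, +2 (right to left along the
reference); for a bottom-strand lesion they are the product read taken
left to right. The accurate flag records whether the inserted
dinucleotide equals `AA`. In the opposing arrangement a full-length
site is TLS, a deletion of ≥ 2 nt covering the site is the
deletion-associated class, and a 1-nt deletion stays TLS (below the
threshold); error-free is never emitted. In mode fractions,
deletion-associated TLS at a staggered site counts as TLS — consistent
with scoring every TLS event in extension-deficient cells, where all
observed TLS carried deletions at the damaged sites.

Two deletion conventions deserve emphasis because they are easy to get
wrong:

* **Placement equivalence.** A deletion's position is only defined up
  to the placements that leave the product sequence unchanged (a gap
  slides freely through repeats). Site logic therefore evaluates the
  deletion over its entire equivalence range and then repositions it
  canonically at the placement maximizing overlap with a lesion site
  (tie-break: covering the 3′ T, then leftmost). Without this, a
  deletion made at the lesion can slide off the site through an
  adjacent repeat and be miscounted.
* **Within-site attribution.** When exactly one base of the site
  dinucleotide is missing, sequence alone cannot attribute the loss to
  the 3′ T or the 5′ T. Such deletions are scored at the 3′ T — the
  first position synthesized past the lesion — and the generator
  follows the same convention (its default preference puts deletion
  mass only at the 3′ T).

Incorporation profiles are per-position frequencies over
`{A, C, G, T, del}` across TLS reads only; error-free reads are
excluded by construction.

## 5. Count statistics

* **Aberration rates.** For x aberrations over N cells the rate is
  `x/N` with SE `√x/N` (Poisson). Reported tables print the half-up
  2-decimal rounding beside full precision, matching the
  `0.12 ± 0.03` presentation style (√12/100 = 0.0346 → 0.03). The
  identity SE²·N = mean holds for all inputs and is asserted as a
  property.
* **Mann-Whitney U.** Exact two-sided p (twice the one-sided tail,
  capped at 1) when the smaller sample has ≤ 8 observations and there
  are no ties; otherwise the normal approximation with tie and
  continuity corrections. Both modes can be forced. The computation
  is delegated to `stats::wilcox.test`; the test suite validates it
  exhaustively against a label-permutation oracle for all small
  splits. The exact/approximate choice is exposed because either
  could have been used in the original analyses.
* **Induced SCE.** Mean(treated) − mean(control), SE combined in
  quadrature from the two standard errors of the mean.

Percentages in reports are rounded half away from zero to integers
(so 12/25 prints as 48% and 2/18 as 11%); numerators and denominators
are always written next to them.

## 6. The synthetic-data generator

The generator stands in for the assays' undeposited raw reads and is
first-class, tested code. What it emulates:

* **Donor arrays** — donors diverge from the parent by a substitution
  rate (default 3%, in the range typical of V&lambda; pseudogene
  homology), pairwise ≥ 3 differences apart.
* **Clone sets** — per clone, a Poisson number of events (default mean
  8, the order of magnitude seen per clone in AID-overexpressing
  cells), a GC fraction (default 0.2), geometric conversion-tract
  lengths (default mean 25 nt), PM positions drawn with a 4-fold G/C
  weight (a deliberately simple AID-hotspot proxy; no sequence-motif
  model is attempted) and alternatives from a 4×4 spectrum whose
  per-reference totals also weight position choice (a pure C→T
  spectrum mutates only C positions). Three clones per set mirrors the
  original experimental design. Sequencing error (default 0,
  reflecting high-fidelity amplification and Sanger reads) is uniform,
  substitution-only, applied last and recorded separately from event
  truth.
* **Bypass products** — a mode mixture over TLS-top / TLS-bottom /
  error-free / other (opposing: TLS / deletion), per-position
  incorporation preferences (default 90% accurate A), and a deletion
  length distribution (default uniform on 2–6 nt) for the opposing
  deletion class.

Events are placed without overlap (rejection sampling); a clone whose
drawn events cannot all fit the locus under the spacing constraints is
redrawn, so event counts are implicitly conditioned on fitting — as
they are in a real locus. All generators are byte-deterministic under
their seed and restore the caller's RNG state.

**Identifiability.** Exact truth recovery is only a fair demand when
the truth is identifiable, which requires: zero sequencing error;
conversion tracts copying ≥ 2 donor differences with ≥ 10 nt clear of
any other donor difference on both flanks (`gc_min_diffs = 2`,
`min_flank = 10`); PM alternatives that match no donor at their
position (`pm_avoid_donor = TRUE`); and donors whose difference
positions are pairwise disjoint (`unique_diff_positions = TRUE`).
The last condition is easy to overlook: two donors that share a
difference can both explain the same copied tract, and a donor that
explains *more* of the clone's mutations legitimately absorbs them
into its own event — the classification is then correct under the
rule but differs from the generating labels. Under all four
conditions, recovery of simulated categories is exact; with 0.1%
sequencing error it degrades only by the occasional error landing in
a tract flank. What passing these tests does **not** show: performance
on real data with PCR chimeras, alignment-ambiguous tandem repeats,
heterozygous templates, or donors more diverged than the generator's
range.

## 7. Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problems
chosen to exercise every code path with comfortable statistical power:
parents of 300–600 nt, 2–5 donors, 3 clones per set (8 sets pooled for
the error-rate study), 200 random instances for the oracle-equivalence
check, and 1000 products per bypass mixture with recovery asserted
inside binomial 99% intervals. Alignment tie-breaking is delegated to
the deterministic optimum of `pairwiseAlignment`, with left-normalized
calls guaranteeing that tie-broken equivalent optima produce identical
mutation lists — which is the property downstream code relies on.
Reports print floats at fixed precision and embed their provenance
(inputs, parameters, seed, package version), so identical runs are
byte-identical.

## 8. Known limitations

* The donor-string search assumes donors co-linear with the parent
  after one global alignment; donors with internal rearrangements
  would need a local-alignment donor model.
* Amb is a reported category, not a probabilistic assignment; no
  attempt is made to estimate the templated fraction within it.
* The bypass classifier reads single lesion-site dinucleotides; it
  does not model multi-site complex products beyond the `other` flag.
* Tract-length inference and hotspot-motif modeling are out of scope;
  the generator's G/C weight is a stand-in, not a mechanism model.
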