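---
title: "Reconstructing haploid DNA molecules from tagmentation junctions"
author: "tagphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing haploid DNA molecules from tagmentation junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagphase)
```

## The physical model

Tn5 transposase is a homodimer with two reaction centres that nick
opposite strands of a double-stranded DNA substrate 9 bases apart
(uncanonically 8 or 10). After gap repair and amplification, the two
fragments flanking a cut each carry a copy of the intervening bases: the
downstream fragment starts exactly *k* bases before the upstream fragment
ends, and the *k* overlapping bases are identical. Two consequences drive
everything in this package:

* **A molecule is a chain.** Trimming the *k* duplicated leading bases
  from every non-first fragment of a tagmented molecule and concatenating
  reproduces the molecule sequence byte-exactly; equivalently,
  Σ fragment lengths = molecule length + Σ *k* over interior cuts. This
  is a hard invariant of the simulator and is asserted as such.
* **Distinct molecules rarely share junctions.** Fragments from different
  molecules may overlap, but the probability that one ends exactly
  *k* ∈ {8, 9, 10} bases past the start of the other is small, so a shared
  junction is strong evidence of common molecular origin. This justifies
  the two phasing rules: *exclusivity* (overlapping fragments without a
  shared junction must belong to different molecules) and *greediness*
  (assign as much as possible to the first molecule, then the second, and
  so on).

Reconstruction proceeds: read-pair merging → UFI deduplication → primer
remnant repair → archipelago clustering → junction detection → shared-end
artifact filtering → island chaining → greedy phasing → integer copy
number.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `merge_max_len` | 150 | bases | fragments at or below the combined read length are covered entirely by their reads; longer ones need reference gap fill |
| `fragment_max_len` | 1000 | bases | mapper's valid-pair cap; longer pairs are rejected |
| `min_fragment_len` | 25 | bases | below this a mapped fragment is indistinguishable from adapter debris |
| `k_set` | {8, 9, 10} | bases | the canonical 9-base duplication plus the two observed uncanonical cuts; nothing outside this range is biologically produced |
| `gap_threshold` | 1000 | bases | separates within-archipelago dropout gaps (hundreds of bases at ~80% coverage) from the kilobase blanks between molecules; matches the mapper's fragment cap |
| `solo_max_len` | 200 | bases | contamination fragments are observed below ~200 bases; junction-less, shared-end-free fragments under this length are excluded from phasing |

Simulator defaults describe the targeted library regime: molecules
lognormal with mean 10 kb (CV 0.7, reproducing a broad 1–30 kb spread with
median below the mean) totalling 10% of the genome; inter-cut distances
geometric-like with mean 230 bases; junction lengths drawn 97 : 1889 : 139
for *k* = 8 : 9 : 10; PCR copies 1 + Poisson(mean − 1) with mean 6.4;
primer-tail probability 0.005 (remnant tails are rare after adapter
trimming); dropout 0.2 so per-molecule coverage centres near 80%; solo
contamination at 0.1 per primary fragment (solos make up ~10% of a
deduplicated library). The per-cut defect probability has no independently
established value; 0.10 is used because it makes shared-end artifacts ~15–20% of
deduplicated fragments, the regime the two-molecule worked example
exhibits, and it is deliberately configurable.

## Defective transpososomes

A dimer with one inactive centre nicks only one strand. After extension
and amplification the suppressed cut yields, for an isolated event, two
indistinguishable long pieces spanning the cut plus a short piece sharing
the long pieces' 5′ end (scenario 0/1) or 3′ end (1/0). Two adjacent
defective cuts yield 00/11 and 11/00 (four fragments, three unique
lengths, one shared end), 01/10 (two identical long pieces whose 5′ and 3′
ends are each shared by a shorter piece) or 10/01 — exactly two
overlapping fragments with **no** shared end, indistinguishable from two
separate molecules. The filter therefore groups fragments by exact shared
start or end, classifies the group geometry, and marks every member but
the longest redundant. 10/01 is left undetected by design; the simulator
still generates it so its cost (one spurious extra molecule per surviving
event) is measurable, and the test suite measures it.

Two deliberate consequences of the exact shared-end rule: a genuinely
homologous fragment that coincidentally shares one end with a longer
fragment is wrongly flagged (counts survive, spans may not — the
reconstruction tests separate these two claims), and an exact length tie
within a group is ambiguous, so both members are retained with a warning.

## Numerical and algorithmic choices

* **Coordinates** are 0-based half-open everywhere; BED output is native.
  Strand is ignored: a double-stranded fragment is fully indexed by its
  cut coordinates, which is also why the UFI is `(chrom, start, end)`.
* **Junction candidates** are all emitted at detection time, including
  coincidental inter-molecule adjacencies (the detector has no molecule
  knowledge). Chaining resolves them by maximum-cardinality matching
  between upstream and downstream partners (augmenting paths); among
  equal-cardinality resolutions a canonical 9-base candidate is preferred
  over an uncanonical one (canonical cuts outnumber uncanonical ~8:1, so
  a competing uncanonical candidate is most likely a coincidence), then
  the longest candidate. Plain
  longest-first greediness was rejected: when two homologous molecules
  overlap, a coincidental cross-molecule candidate — which the sequence
  test cannot reject, both fragments matching the same reference — could
  steal a downstream fragment from its true partner and sever both
  chains, whereas the matching formulation restores the chain-maximal
  resolution.
* **Sequence identity** at junctions is strict when sequence is
  available: one mismatch voids the junction. Coordinate-only evidence
  (e.g. BED input) falls back to geometry, which reference-mapped
  fragments satisfy trivially.
* **Primer repair** trims 1–3 terminal bases, longest first, only when
  the bases match the primer remnant (`CAG` 5′ / `CTG` 3′), mismatch the
  reference, and removal restores a junction; repairs below
  `min_fragment_len` are refused. A repair can re-create a UFI duplicate
  (the untailed sibling of a defect duplicate), so deduplication runs
  again after repair.
* **Greedy phasing determinism**: elements are scanned by (start,
  islands before loose fragments, decreasing length, id), and each is
  placed in the lowest-numbered molecule it does not conflict with. A
  brute-force minimum-partition oracle (exhaustive assignment, ≤ 12
  elements) is part of the package: on interval-structured conflicts the
  greedy count equals the optimum, which the test suite checks on random
  instances.
* **Copy number** is the count of molecule spans covering each base,
  emitted as maximal constant-copy intervals per chromosome, including
  interior zero-copy stretches.

## What the simulator does and does not emulate

It emulates the mechanism the pipeline exploits — junction duplications
with configurable 8/9/10 proportions, all six defect scenarios, PCR
duplication, primer tails applied only where they are observable
(mismatching the reference), dropout, and short junction-less
contamination — under one seed with byte-identical reruns. An optional
cut-site preference weight enriches G at the first duplicated base and
A/T just outside the cut, qualitatively reproducing the observed logo.

It does not emulate mapping error, GC-biased amplification, sequencing
error, chimeric PCR products, or structurally variant genomes: passing
tests show the algorithm is correct for correctly mapped fragments, not
that mapping is easy. Real libraries are mapped first; the package
consumes SAM/BAM or fragment BED.

Problem sizes in the checked properties were chosen to exercise the
asymptotics while staying desk-scale: a 1 Mb perfect-tiling region, 1000
molecules for the concatenation round-trip, 200 random phasing instances
against the exhaustive oracle, and 120 noisy + 20 noise-free simulated
archipelagos for molecule-count recovery.

## Known limitations

* 10/01 defect events and true homologous two-molecule overlaps are
  mutually indistinguishable; counts are biased upward by surviving 10/01
  events, and the bias is measured, not hidden.
* Molecules whose spans do not mutually overlap cannot be counted
  separately even in principle (greediness packs disjoint spans into one
  molecule, as the minimum partition demands).
* A dropout gap wider than `gap_threshold` splits one molecule into two
  archipelagos, each reconstructed separately.
* Phasing does not link archipelagos into chromosome-scale haplotypes,
  and no SNV evidence is used.
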