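---
title: "tc1scout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tc1scout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

IS630/Tc1/mariner elements are class-II DNA transposons of the terminal
inverted repeat (TIR) order. An intact element has a five-segment anatomy --
5'TIR, 5'UTR, a transposase ORF, 3'UTR, 3'TIR -- inserts at a `TA` target
site that is duplicated on integration, and encodes a transposase whose
catalytic pocket is formed by two aspartates and a glutamate (or a third
aspartate). The field names families by the spacing between the second
aspartate and the final catalytic residue: `DD34E` typifies Tc1, `DD34D`
mariner, and larger spacings such as `DD40E` mark nonclassical members.
Identifying an element *without close homologs* therefore rests on structure
rather than similarity. tc1scout implements that structural workflow as
composable, tested operations:

1. **Three-point evidence rule** for calling an element: (i) identical TIRs
   at both ends, (ii) excision sites consistent with a `TA` target-site
   duplication (TSD) at both boundaries, (iii) a transposase ORF carrying a
   plausible DDE/DDD triad between the TIRs.
2. **Frameshift repair**: degenerate copies often carry small insertions
   that split the transposase ORF; the reading frame is restored by minimal
   insertion removal, optionally guided by a homologous reference protein.
3. **Copy census**: genome-wide placement of a reference element with the
   strict *more than 90% coverage* rule for counting full-length copies,
   plus a solo-TIR scan.
4. **Boundary inference without TIRs**: when TIRs have decayed beyond
   recognition, boundaries are fixed by comparing homologous regions that
   carry the element against those that lack it (the presence/absence gap).
5. **Composition profiling** of unassigned protein regions (serine-rich
   class labels, Pearson-correlation ranking against a proteome).
6. **Neighbor-joining phylogeny** of aligned DDE domains with outgroup
   rooting and a two-clade membership readout.

## Excision-site convention

Published boundary notations such as `TACA|`, `|TGTA` and `TA|TA` do not
state whether the 4-mer lies inside or outside the element. tc1scout defines
the boundary 4-mer as *2 bp of flank + the 2 terminal element bases* (and
mirrored at the 3' end). `excision_ok` requires (a) the two 4-mers to be
reverse complements of each other and (b) the flank-side dinucleotide on
each side to equal the TSD. This single convention satisfies both printed
patterns -- `TACA`/`TGTA` for an element whose termini begin `CA...TG`, and
`TATA`/`TATA` for a TIR-less IS630-type element -- and is self-consistent:
for any element whose termini are reverse complements (always true with
exact TIRs), TSD duplication implies the 4-mer symmetry.

One consequence, surfaced by testing: if a TIR contains an internal `TA`,
a shifted sub-element (starting just after that `TA`) also satisfies the
full evidence rule. The discovery pipeline therefore prefers the *longest*
TIR pair among TSD-anchored candidates, which resolves the ambiguity in
favor of the outermost boundaries.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| TIR length bounds | 10--250 | bp | brackets known family TIRs (26, 141, 169 bp) |
| TIR identity | 1.0 discovery / 0.8 scan | fraction | "identical TIRs" is an exact claim; degenerate copies tolerate 20% divergence |
| TSD | `TA` | dinucleotide | the family's target site |
| full-length rule | coverage > 0.90 | fraction | strict reading of "more than 90%"; exactly 90.0% does not count |
| census identity | 0.8 | fraction | autonomous family members diverge by up to ~20% at the DNA level |
| census chaining gap | 0.2 x reference | bp | tolerates internal indels without double-counting a locus |
| triad spacing set | \{34, 37, 38, 39, 40\} | aa | classical classes, the known exceptions, and DD40E |
| D1--D2 gap | 50--250 | aa | brackets observed first-spacer lengths; configurable, no published bound |
| SNP gap buffer | 1 | bp | alignment columns adjacent to gaps are excluded from SNP counts (edge wander) |
| boundary tolerance | 2 | bp | max disagreement between absence-gap endpoints across homologs |
| positives definition | BLOSUM62 score > 0, identities included | -- | consistent with printed positives >= identities; the original matrix is unstated |
| rich-class thresholds | S >= 2x background; partners >= 1.5x | fraction | see below |

**Percent rounding.** Domain identity is rounded to 2 decimals and
positives to 1 decimal, matching the precision these statistics are
conventionally printed with (`41.83%`, `54.9%`).

**Rich-class thresholds.** No published thresholds exist for SR-/SAP-/PS-/
SP-rich labels; the argument is made from raw percentages (serine ~13.4%,
proline ~8.4%). A flat 2x-background rule would reject proline at 8.4%
against a ~5% background, contradicting the very example the label is based
on. tc1scout therefore requires the primary residue (serine) at 2x
background and partner residues at 1.5x, both configurable, with the more
abundant of S/P leading the label (SP- vs PS-rich).

## The synthetic-genome world

The generator is first-class, tested code: it states a small world with
exactly the structure the detectors assume, so that every downstream module
is testable offline with known truth.

A planted element is built from an `element_spec` (TIR/UTR/ORF lengths, a
`triad_spec`, the TSD) with these deliberate constructions:

* **TSD duplication**: each full insertion overwrites the target
  dinucleotide with `TA` and duplicates it around the element, so every
  planted copy passes the excision-site check by construction.
* **ORF guard**: the last three 5'UTR bases are an in-frame `TAA`, so the
  maximal ORF call starts exactly at the planted `ATG` (no accidental
  upstream in-frame extension).
* **TIR guard**: the first base inside each TIR boundary is chosen to break
  inverted-repeat symmetry, so the planted TIR length is also the longest
  exact one (otherwise ~25% of seeds would extend it by chance).
* **Unique triad**: a real catalytic domain is unique within its protein;
  after random codon assignment the generator neutralizes every decoy
  (D,D,D/E) combination (under the default scan parameters) and plants the
  family's conserved glycine context near the true triad. Without this, a
  random 1,155-aa protein contains hundreds of coincidental triads and the
  class readout would be noise, which is not the situation the evidence
  rule addresses.
* **Divergence**: copy-2 substitutions are uniform over the element but
  never hit the outermost 4 bp (keeps excision evidence intact, as for the
  intact copy pair the rule was derived from) and stay >= 12 bp away from
  indels so each indel's local amino-acid consequence remains decodable.
  A 3-bp deletion removes the planted internal methionine codon in frame.
* **Frameshifts**: insertion offsets default to the central 20--60% of the
  ORF (an insertion in the terminal 10% would leave a >90%-coverage ORF and
  there would be nothing to repair).

What the generator does **not** emulate: host-genome composition structure
(isochores, repeats other than the planted ones), nested insertions,
transposition dynamics, or sequencing error. A green round trip therefore
establishes correctness of the operations on clean planted structure, not
performance on real assemblies.

## Frameshift repair: contract and search

`repair_frameshifts()` finds the removal set of minimal total length
(ties: fewest segments, then leftmost, then lexicographic) such that the
region afterwards carries a single forward ORF covering at least 90% of it.

Implementation work surfaced a genuine ambiguity in the "minimal removal"
criterion: for a 41-bp insertion, removing just 2 bp can leave 39 in-frame
foreign bases (13 junk codons) and still satisfy the contract, and removals
ending at a slightly earlier stop can pass the coverage threshold. The
*biological* repair is therefore generally **not** the unguided minimum.
The original recovery of such elements was reference-guided -- the broken
ORF was reconciled against a known homologous transposase -- and tc1scout
makes that mode explicit: with `reference_protein` and `min_identity = 1`
the search returns the minimal removal whose restored protein equals the
reference exactly. Unguided repair remains available and honestly returns
the smaller minimum.

The search enumerates candidates in ascending total removal length, so the
first verified candidate is the provable minimum. Candidate segments are
anchored by reading-frame arithmetic between each start codon near the 5'
end and each stop codon near the 3' end, using per-frame stop-position
indexes; in exact-reference mode the windows are further pinned by
prefix/middle/suffix codon agreement with the reference. Every surviving
candidate is verified by a full ORF re-scan. The enumeration is exact for
removal sets of one or two segments whose restored stop codon is read from
contiguous original bases; a restored stop spanning a removal junction (not
a generative situation for insertions into a working ORF) is outside the
enumeration, and `max_segments` is limited to 2 -- the two published repair
cases need exactly 1 (one 41-bp insertion) and 2 (two single-A insertions).

## Numerical choices

* **Alignment engine** (census, copy comparison, boundary inference):
  Biostrings `pairwiseAlignment`, affine gaps, match 2 / mismatch -3 /
  gap open 5 / gap extend 2 (no published parameters; these are
  conventional for diverged DNA).
* **Gap wander**: global alignments may slide a gap within repeated
  context. SNP counting excludes columns within 1 bp of a gap; indel
  amino-acid consequences are decoded by local translation comparison
  around the gap rather than codon arithmetic on the reported position;
  boundary inference accepts +/-2 bp endpoint disagreement across homologs.
* **NJ**: Saitou--Nei with the Studier--Keppler criterion; Q-ties broken by
  the lowest index pair (deterministic); negative branch estimates clamped
  to zero with the deficit moved to the sibling edge so the joined pair's
  distance is preserved; p-distance by default with an optional Poisson
  correction. Distance-based NJ stands in for Bayesian tree inference,
  which is out of scope; topology agreement with published trees on real
  data is a user-level validation.
* **Composition PCC**: population Pearson correlation on the 20 paired
  fractions; ambiguous residues (B, Z, X, U, O) are excluded from both
  numerator and denominator; a zero-variance vector yields `NA` with a
  classed warning rather than a crash.

## Configuration and reproducibility

The CLI (`inst/cli/tc1scout`; subcommands `simulate`, `discover`, `census`,
`compose`, `phylo`) reads an optional JSON config; explicit flags win. JSON
was chosen over TOML because the toolchain this package targets ships a
JSON parser but no TOML parser. All generator entry points take an integer
`rng_seed` and restore the caller's RNG state; identical (inputs, config,
seed) produce byte-identical reports.

## Known limitations

* Discovery scans the forward strand for candidate ORFs; census is
  strand-symmetric, so minus-strand elements surface there (and
  `find_orfs` itself is strand-complete).
* The evidence rule cannot distinguish an element from a shifted
  sub-element when a TIR contains an internal `TA`; the longest-TIR
  preference is a heuristic, correct for exact planted structure.
* Repair is exact only within the documented 1--2 segment envelope.
* `infer_insertion_interval` assumes each without-group homolog lost the
  segment in a single contiguous block; recombined partial deletions are
  reported as ambiguous.
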