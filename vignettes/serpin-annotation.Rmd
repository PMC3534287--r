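---
title: "Annotating plant serpin reactive-centre loops: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating plant serpin reactive-centre loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpintools)
```

# The problem

Serpins inhibit serine (and some cysteine) proteases through a
suicide-substrate mechanism: the reactive-centre loop (RCL) presents a bait
sequence, the protease cleaves at the P1–P1′ bond, and loop insertion into
β-sheet A traps the enzyme in a covalent complex. Whether a given serpin can
do this at all is largely encoded in its RCL: the proximal hinge (P17–P9)
must be dominated by small residues for insertion, and essentially all known
inhibitory serpins carry a small residue (Ala, Cys, Gly or Ser) at P1′.
Non-inhibitory family members — hormone carriers, storage proteins,
chaperones — have drifted away from this pattern.

For plant genomes the practical tasks are: find the RCL in a predicted
protein, assign the canonical P positions, classify inhibitory capacity,
name the protein informatively, repair mis-annotated gene models, and place
each serpin among its paralogues. `serpintools` implements this pipeline and
ships the reference tables for the 14 full-length serpins of rice
(*Oryza sativa* cv. Nipponbare).

# The annotation model

## Hinge location

The anchor of the canonical numbering is the highly conserved Glu at P17.
Candidate Glu residues are scored in a C-terminal search window
(`window_frac = 0.4` of the sequence) against a consensus profile:

| position | allowed residues | weight |
|---|---|---|
| P17 | E (required anchor) | 2 |
| P16 | E, K, R | 1 |
| P15 | G | 1 |
| P14 | S, T | 1 |
| P13 | A, G, S, T, N, Q | 1 |
| P12–P9 | A, G, S, T, V | 1 each |

Maximum score 10. The profile is a documented stand-in: the classic RCL
consensus criteria this follows were never printed in the source analysis,
so the profile lives entirely in `annotation_config()` and alternative
profiles can be swapped in and tested. The ambiguity code X never scores.

Ties between equal-scoring candidates are broken toward the candidate whose
P1 lies closest to 35 residues from the C-terminus (the typical placement of
a serpin RCL), then toward the more C-terminal candidate — deterministic by
construction.

## Canonical positions and naming

Counting C-terminal from the anchor, `index(Pk) = p17 + (17 − k)`, P1′ at
`p17 + 17`. The canonical rule is applied uniformly even though a minority
of animal serpins have only 16 residues between the conserved Glu and the
experimentally determined P1; no 16-residue fallback mode is provided, and a
name would only change on in-vivo cleavage evidence. The P2-P1′ triplet
becomes the name (`OsSRP-LRS`); when two serpins of one species share a
triplet, *all* colliding members are numbered in ascending locus order.
Numbering only the later member would silently re-rank names whenever a new
paralogue appears.

## Classification thresholds

With the default config: **inhibitory** iff hinge score ≥ 7 and P1′ ∈
{A,C,G,S}; **non-inhibitory** iff hinge score ≤ 4, or P1′ non-small combined
with ≥ 2 non-small residues at P12–P9; otherwise **uncertain**. These
cutoffs reproduce the published call pattern on the rice fixture: the PLP
serpin (non-small P1′ plus degraded distal hinge) is called non-inhibitory
outright, the PTY/PGY serpins (non-small P1′, otherwise consensus hinge)
fall to uncertain, and the eleven putatively inhibitory serpins classify as
inhibitory. The flag `P1prime_not_small` is set whenever P1′ is outside the
small set, and the classifier never labels a flagged serpin inhibitory.

Note that with the doubled anchor weight the profile maximum is 10, not the
9 one might expect from counting its nine positions; the cutoffs (7/4)
produce the same call for every packaged case under either weighting, and
both the weights and the cutoffs can be overridden in `annotation_config()`.

## Motif scanning

The plant-specific s2B–s3B motif Y-x-x-G-x-D-x-R-x-F is scanned
non-overlapping from the N-terminus. "Conservative variants" — how relaxed
the published phrase was meant is unstated — are implemented as exactly one
mismatch among the D/R/F anchors (Y and G must match), and the relaxation
count is config-exposed (`motif_max_anchor_mismatch`).

# Gene-model curation

Edits are anchored by short printed substrings ("landmarks"), not absolute
coordinates, because database coordinates drift across annotation releases
while the landmark text is stable. Landmarks must resolve uniquely; an
absent or ambiguous landmark is an error naming the offending operation.
Every script can declare an expected final length, and a mismatch is a hard
error: curation is meant to be auditable, not best-effort. All six packaged
rice scripts declare their printed final lengths, which also makes
double-application fail (the landmarks are consumed by the first pass).

Two judgement calls in the packaged scripts:

- The PSG translated-intron segment is printed only as "30 residues"; its
  boundary residues are unknown. The script brackets it with synthetic
  anchors (`WIHD`/`DHIW`), clearly labelled as stand-ins, and the conforming
  synthetic input plants the same anchors.
- The pre-curation LRS model is described as 719 aa, but the printed blocks
  (137 kept + 72 excised + 252 kept + 7 replaced) total 468; the remainder
  belongs to an erroneous fifth exon never addressed by the edit text. The
  conforming input is therefore the 468-aa printed-block model, and the
  script reproduces the printed 396.

# Identity, distances and trees

Percent identity uses pairwise gap exclusion: columns where either sequence
is gapped are excluded from numerator and denominator. The source analysis
never states its identity definition (the values were produced "by the
program"); pairwise exclusion is the standard convention and is exposed in
config next to the alternatives. Banding for display applies the published
legend to the nearest integer (ranges are printed as integers); 100 maps to
its own band `identical` and values below 20 to `below_range`. Whether the
published matrix was computed on the full hand-edited alignment or the
gap-stripped site set is also unstated, so both modes exist
(`sites = "all" | "ungapped"`).

Distances are p-distances, `d = 1 − identity/100`, on the gap-stripped site
set (the published site-exclusion rule). Neighbour joining is implemented
directly — Q-criterion, ties broken toward the lowest index pair in the
current order, negative branch lengths clamped to zero with a reported
count — because the deterministic tie rule is part of the contract; `ape`
provides the tree container, Newick I/O and the independent oracle in tests.
For additive matrices NJ provably recovers the generating tree, and the
suite verifies exact recovery of topology and path lengths on 200 random
planted trees of 4–8 taxa.

Bootstrap supports resample gap-stripped sites with replacement and count,
for each internal edge of the reference tree, the replicates containing the
same bipartition — supports on a single tree's nodes, not a majority-rule
consensus, matching how such values are conventionally displayed. Taxon
order is canonicalised (sorted) before support computation: floating-point
Q-criterion near-ties would otherwise make supports depend on input row
order through summation order. The analysis being mirrored used parsimony in
its methods text but neighbour joining in the figure that presents the tree;
this package implements the figure's method and leaves parsimony out of
scope. Published bootstrap values depend on a hand-edited alignment and tool
internals and are treated as qualitative only.

# qPCR quantification

The crossing-point transformation is
`abundance = 100000 × 2^(20 − CP)` — CP 20.00 is arbitrarily anchored at
100,000 relative units (chosen because the Actin reference crosses near
CP 20), giving the halving law `abundance(cp − 1) = 2 × abundance(cp)`.
Replicates are aggregated as the arithmetic mean of CP *before*
transformation (CP is the measured quantity; config-exposed). A replicate
beyond the detection threshold (36 cycles) is excluded from the mean; when
all replicates exceed it the gene is "not detected" and carries no units or
ratio. Normalised ratios are gene units over reference units within the
same sample; an undetected reference makes the sample's ratios errors (NA
with a warning) while raw units are still reported, and both the ratio and
the side-by-side log10 display values are emitted since published usage
varies between the two.

Amplicon prediction matches the forward primer on the given strand and the
reverse-complement of the reverse primer strictly downstream; the product
length runs from the first base of the forward match through the last base
of the reverse binding site (full product size including both primers, the
convention of the shipped primer tables). Exactly one product is required;
zero or multiple products are distinct errors. Verifying the shipped
primers' printed sizes against real genomic sequence needs the locus
accessions and is deliberately a separate, optional tier not run offline.

# Synthetic data: what a green test establishes

The generators state a fixed world and the tests measure against it:

- `generate_serpin()` plants a hinge whose consensus-match fraction equals
  the requested quality, the P2-P1′ code at canonical positions, a
  controlled number of decoy Glu residues, and optionally the plant motif.
  Background residues are drawn uniformly from the 19 non-Glu residues so
  Glu placement is exactly controlled. Default length 400 aa (rice serpins
  run 340–440), P1 35 residues from the C-terminus. Degradation removes
  consensus distal-first (P9 inward), so the anchor is the last feature to
  go; quality 0 plants no anchor at all.
- `generate_family()` simulates sites independently down a planted tree
  under a uniform substitution model (substitution probability
  `1 − exp(−b)` per branch, uniform choice among the other 19 residues).
  No indels, no empirical exchange matrix: identity and NJ tests need only
  monotone decay and near-additivity, not biological realism.
- `generate_qpcr_table()` fixes the reference at CP 20 and sets gene CP to
  `20 − log2(ratio)` plus Gaussian replicate noise, as technical
  triplicates.

Consequently a green suite establishes that the algorithms are correct on
sequences with exact planted structure — it does not establish recovery on
real serpins with indel-riddled alignments, biased composition, or
non-canonical hinges, and the published identity values (87% for the
closest rice pair, 42.9% mean) are not desk-reproducible because they
depend on downloaded sequences and a hand-edited ClustalX alignment. The
fixture tables themselves are shipped verbatim, including three locus
assignment conflicts present in the source annotations
(`load_rice_fixture()$discrepancies`), which are deliberately not
reconciled.

# Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; every user-facing report is
  1-based.
- Banding rounds with `floor(x + 0.5)` (deterministic nearest-integer, no
  banker's rounding).
- NJ clamps negative branch lengths to zero and reports the count; an
  all-zero distance matrix yields an all-zero tree.
- `percent_identity` errors when two rows share zero non-gap columns;
  `strip_allgap_sites` errors when no column survives.
- Bootstrap supports are undefined below 4 taxa (error).
- Sequences shorter than 60 residues are rejected by the hinge search; a
  window without any eligible Glu is the distinct error "no hinge
  candidate".
- All generator randomness is seed-local: callers' RNG state is saved and
  restored.

# Known limitations

- No alignment construction: the identity/phylogeny modules consume
  externally produced alignments (the published parameters: gap opening 10,
  gap extension 0.05, Blosum30 series) since hand-editing cannot be
  automated.
- No parsimony or likelihood tree search; no rooting inference — the basal
  trichotomy in Newick output is a display of unrootedness.
- The inhibitory classifier is a sequence heuristic; it does not model
  exosites, structure, or target-protease specificity beyond P1/P1′.
- Amplification-efficiency modelling, standard curves and melt-curve
  analysis are out of scope; only the 2^(20−CP) transformation is used.
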