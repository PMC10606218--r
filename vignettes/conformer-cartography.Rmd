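---
title: "Conformer cartography and in-silico mutagenesis of alternating-access carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer cartography and in-silico mutagenesis of alternating-access carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformoscope)
```

## The scientific problem

Secondary carriers built on the LeuT fold transport their substrate by
alternating access: a "rocking bundle" of transmembrane helices rotates
against a comparatively immobile "hash" scaffold, so that the substrate
binding site is exposed either to the outside (outwardly open, OO) or to
the inside (inwardly open, IO) of the membrane, never to both. Slc11
(MntH/Nramp) carriers of divalent metals are a classic case: solved
structures capture the two end states, while modern structure predictors,
run over the natural sequence diversity of a clade, emit ensembles of
models that can populate the path in between. The analytical questions
this package addresses are:

* Given a pool of single-chain CA models and two anchor structures, which
  models are OO, which IO, which in between — and in what order do they
  fall along the transition?
* Which residue-residue contacts, and which communities of contacts,
  exist in exactly one state (candidate gates)?
* Does a combination of point mutations, modeled by an external
  predictor, switch the carrier's predicted conformation? Do mutation
  combinations interact (epistasis, suppression)?
* At the sequence level, which alignment columns distinguish clades
  (type-ii evolutionary rate shifts; group-specific sites), and do such
  sites colocalize in 3D?

Structure prediction itself is out of scope: the package consumes
predicted models (PDB format, CA traces, optional pLDDT in the B-factor
column) and emits mutant FASTA plus a run manifest for the predictor.
For development and testing, a seeded rocking-bundle generator stands in
for the predictor with known ground truth.

## Deviation profiles

All structural readouts rest on per-residue CA deviation under a *single
global* Kabsch superposition (`deviation_profile()`). Residue
correspondence between models is always obtained by global sequence
alignment (BLOSUM62, affine gaps 11/1), never by comparing author
numbering, because anchor structures can be truncated. One global fit is
essential: the conformational signal *is* the large local deviation of
mobile segments under a fit dominated by the static scaffold; windowed or
local fits would absorb exactly the motion we want to read. Residues
without a correspondence are reported missing (`NA`), never as zero.

The broad-scale deviation (BSD) of a mutant is the fraction of in-scope
(transmembrane) residues deviating by more than `tau` (default 2 A) from
the native model. `classify_switch()` turns BSD into a three-way verdict:

* `silent` — BSD below 0.05;
* `switched` — BSD at or above 0.25 *and* at least 4 of the 5 signature
  segment groups moved (mean deviation above `tau`). The signature is the
  set of helical segments a genuine state change must mobilize; requiring
  most of them prevents a large but localized rearrangement from being
  mistaken for a switch;
* `partial` — everything else.

The numeric thresholds are this package's operationalization of a
qualitative readout; they are arguments everywhere and recorded in every
report. Epistasis between two mutation sets is the non-additivity
`epsilon = BSD(A+B) - BSD(A) - BSD(B)`, classified cooperative /
additive / antagonistic with a band of 0.10; a suppressor's strength is
the drop in BSD it causes on a switched background.

## Elastic similarity, embedding, state calls

Pairwise structural similarity uses a superposition-free elastic
distance-matrix score over the aligned residue pairs:
`sum_{i<j} (theta - |dA - dB| / d*) exp(-(d*/envelope)^2)` with
`theta = 0.2`, `envelope = 20` A, and `d*` the mean of the two
intramolecular distances; the `i = j` terms contribute `theta` each.
Because all compared proteins here are homologs (about 40 percent
identity or better), correspondences from sequence alignment are
reliable and no structural alignment search is needed — the score is
used to compare conformers, not to detect remote homology. Scores are
normalized Z-like against the pool itself in bins of aligned length;
reproducing any web service's absolute score scale is a non-goal.

The similarity matrix, shifted non-negative, is embedded in 2-D by
correspondence analysis (SVD of the standardized residuals of the
row/column profiles); classical MDS on the complementary dissimilarity
serves as a cross-check in the tests, and axis signs are canonicalized
(largest-magnitude coordinate positive) for reproducibility.

State calls compare each model's similarity to the two anchors:
`margin = (s_OO - s_IO) / (s_OO + s_IO)` after the min-shift, with OO
declared above `+delta` and IO below `-delta`. The package default is
`delta = 0.05`, suited to heterogeneous pools where only near-ties
should count as intermediate. For the synthetic benchmark the margin is
analytically close to `1 - 2t` (the min-shift cancels the affine offset
of the score, and the elastic score decays essentially linearly in the
interpolation coordinate), so the band that mirrors the generator's
state definition (intermediate for `t` in (1/3, 2/3)) is `delta = 1/3`;
that value is used wherever the benchmark is evaluated. Transition
ordering projects the embedding onto the OO-to-IO chord, breaking ties
toward the OO anchor.

## Residue-interaction networks

`build_psn()` works at the CA level: contact if CA-CA distance is at or
below 5 A (configurable up to about 8) with sequence separation of at
least 3 residues; interaction strength
`I_ij = 100 / sqrt(N_i N_j)` with `N_x` the mean contact count of
residue type `x` in the analysed pool, floored at 1. This is a CA proxy
for heavy-atom contact definitions used by web services — models here
carry CA-level reliability only — and the normalization is
pool-internal and deterministic rather than a precomputed table; both
are deliberate deviations and stated as such. Edges below `i_min = 3`
are pruned. Consensus networks keep edges present in at least an
`occupancy` fraction (default 0.5) of an ensemble's graphs, averaging
strengths; occupancy 1 is the intersection. Communities are connected
components, with greedy-modularity splitting (deterministic; no
random-seeded method) of components above 30 nodes, and communities
below 3 members are dropped. State comparison classifies edges OO-only
/ IO-only / shared and matches communities across states by member
Jaccard.

## Clade-level sequence analytics

*Pattern matching.* PROSITE-style patterns (literals, `[classes]`,
`x(m,n)` gaps) are compiled to token lists and matched by dynamic
programming over (token, position) — exhaustive over gap ranges with no
backtracking blow-up, so the worst case is linear in pattern size times
sequence length. Tests prove equivalence against an independent
regex-engine translation. The clade-diagnostic pattern for the MCg1
carriers ships with the package (`mcg1_pattern()`); the remote
PHI-BLAST search it was designed for is out of scope.

*Rate shifts.* A type-ii shift is a column conserved (at least 0.9
within-group consensus among non-gap residues) as residue X in one clade
and as a different residue Y in another; type-i is conserved in exactly
one. Gap-majority columns are skipped.

*Group-specific sites.* Two branches, mirroring the
Sequence-Harmony / Multi-Relief pairing, both reimplemented from their
published descriptions (numeric parity with the web server is not
promised):

* harmony: generalized Jensen-Shannon divergence (base 2, pseudocount
  0.5 per residue, normalized by `log2(k)` groups) between per-group
  column profiles. The similarity-oriented score `1 - divergence` is
  z-standardized so group-distinct columns come out strongly negative,
  matching the `z-score < -10` selection convention.
* relief: 100 seeded subsamples of half the rows per group; each
  sequence's nearest same-group and nearest other-group neighbour (by
  whole-row identity) update every column's weight by
  `mismatch(miss) - mismatch(hit)`; the mean weight is z-standardized
  (`z-weight > 6` selects).

Standardization uses the trimmed core of the column distribution (trim
0.25 per tail). The trim must exceed the anticipated fraction of signal
columns — about 11 percent in the three-clade benchmark — plus the
noisy background tail, so that a minority of strongly scoring columns
cannot inflate the null spread; the quartile-based core is the standard
robust choice with that property. Columns with more than 50 percent
gaps are excluded from standardization and never selected. A column is
reported only when *both* thresholds select it.

*Colocalization.* For a site set on a structure, the statistic is the
mean CA distance to the nearest other site. The nearest-neighbour form
(rather than the all-pairs mean, which is reported as a secondary
statistic) rewards sets forming a few tight clusters — the expected
topology of evolutionarily coupled substitutions, which turn up as two
or three spatially connected groups rather than one blob. The null
permutes same-size site sets over the model's residues (without
replacement, excluding the observed set), and
`p = (1 + #{null <= obs}) / (n + 1)`; p-values are bit-reproducible
given the seed. Tests verify null uniformity by a Kolmogorov-Smirnov
check over 200 random site sets.

## The synthetic rocking bundle: what it emulates, what it does not

`generate_ensemble()` builds an 11-helix bundle of ideal helices (2.3 A
CA radius, 1.5 A rise, 100 degrees per residue — 3.8 A CA spacing), 20
residues each. Helices h1/h2/h6/h7 form the mobile bundle; the IO
anchor applies one rigid rotation of 25 degrees about the bundle axis
plus a 2 A axial translation to that subset. Two contact communities
are planted geometrically: static h5/h8 flank h1's OO position (and
only that position), and static h10/h11 flank h6's IO position, each
flank leaning 10 degrees toward its partner so contacts form connected
multi-residue patches, as crossed packed helices do, rather than
isolated residue pairs. The generator *asserts* before returning that
the planted contacts exist in exactly one anchor and that no other
inter-helix contacts exist in either anchor — the ground truth is
verified geometry, not intent. Intermediates are per-atom linear
interpolations (adequate at 25-degree rotations; torsion-space
interpolation is knowingly not attempted) with optional iid Gaussian
coordinate noise, and state truth follows `t < 1/3` (OO) / `t > 2/3`
(IO). The mutation-response table maps label sets to target coordinates
(combination entries override singles; unlisted labels are silent;
otherwise the most-displacing single dominates), which is how silent
singles, one-helix partial movers, full switchers, a cooperative pair
and a suppressor are planted. The grouped-MSA generator plants type-ii
and group-selective columns at an exact conservation count
(`round(n * 0.95)` consensus rows) over a shared Dirichlet background
(concentration 0.1 — strongly conserved columns, as in within-family
alignments of close homologs).

A green benchmark therefore establishes that the estimators recover
*geometric and combinatorial* ground truth under iid coordinate noise
and profile sampling noise. It does not establish performance on real
predictor output, whose errors are correlated along the chain, nor
anything about real transport activity of mutants; and linear
interpolation makes mid-path models slightly compressed relative to a
physical pathway.

## Numerical and degenerate-input choices

* Kabsch superposition uses SVD with a determinant correction, so the
  rotation is always proper; fewer than 3 points or mismatched sizes
  are errors. The test oracle is an independent hierarchical grid
  search over rotations (coarse Euler scan, then tangent-space
  refinement), agreeing to 1e-4 A on small point sets.
* Alignment identity is matches over aligned (both non-gap) columns,
  reported to 0.1 percent; the denominator convention of external
  comparison servers is not documented anywhere authoritative, so this
  one is declared, and cross-tool comparisons of absolute identity
  should expect up to a point or two of drift.
* Self-similarity sits on the matrix diagonal and is normalized with
  the same bin statistics; identical models in a pool are legal (the
  size-bin standard deviation falls back to 1 when degenerate).
* Empirical p-values are never 0 by construction; permutation draws
  that reproduce the observed set exactly are redrawn.
* PDB coordinates are written to 3 decimals; round-trips are exact to
  1e-3 A. Non-standard residues read as `X` with coordinates kept, so
  profiles stay index-complete; `X` scores 0 against everything during
  mapping.
* All generators and resampling routines take explicit integer seeds
  and restore the caller's RNG state; identical seeds give bit-identical
  output everywhere, including pipeline reports.

## Known limitations

* The elastic-score normalization is pool-internal; scores are not
  comparable across pools, only within one analysis.
* CA-level contacts miss side-chain interactions; community membership
  should be read at segment granularity, which is how it is used.
* The registries for the real carrier templates record the documented
  site numbering and combination aliases, but the four glycine
  positions of the six-fold h3 compound are figure-derived stand-ins
  (flanking the two documented h3 sites) and the shipped template
  sequences are synthetic placeholders carrying the documented
  wild-type letters; analyses of real accessions require supplying the
  real sequences.
* Printed cross-accession identities (83 / 90 / 41.4 percent) require
  the UniProt/NCBI sequences, which cannot be fetched in an offline
  build; the corresponding acceptance check documents this and runs
  whenever `inst/extdata/carrier_sequences.fasta` is provided.
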