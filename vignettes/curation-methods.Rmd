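---
title: "Curating enzyme superfamilies with sfcurate: models, thresholds and design choices"
author: "sfcurate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating enzyme superfamilies with sfcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcurate)
```

## The curation problem

Functionally diverse enzyme superfamilies are sets of homologous enzymes that
conserve only an aspect of their chemistry — often a partial reaction, a metal
site, or a catalytic strategy — while individual reaction families within them
have diverged to catalyse different overall reactions. Curating such a
superfamily means classifying its members along a three-level hierarchy
(superfamily → subgroup → family), where a family is isofunctional, and
transferring functional annotations only to the depth the evidence supports.
Transferring a family-level function on sequence similarity alone is the
classic over-annotation error; the guard against it is conservation of the
catalytic residues specific to each level.

`sfcurate` implements that workflow end to end: bounded seed-set selection,
profile construction from seed alignments, automatic calibration of bit-score
thresholds, residue-gated hierarchical annotation transfer, and sequence
similarity networks (SSNs) for curator-driven subgrouping and dissemination.

## Data model

Sequences live in `Biostrings::AAStringSet` objects over the 20 standard
residues plus `X`. An *enzyme functional domain* (EFD,
`EnzymeFunctionalDomain`) is the portion of a chain responsible for one
annotated function: an ordered set of non-overlapping 1-based inclusive
ranges, at least one of which is the *superfamily domain* (SFD) performing the
conserved chemistry. Multi-functional proteins carry several EFDs with
disjoint SFD ranges, each classifiable on its own; `efdSlice()` extracts the
concatenated EFD sequence so classification never operates on whole
multi-domain chains. Coordinates are 1-based inclusive throughout, including
alignment columns — the convention of curated protein databases.

The hierarchy is a tree of `HierarchyNode` objects held from the root;
parents are implicit (R's copy semantics make parent back-pointers fragile,
so containment is validated top-down instead). Subgroups may nest. Each node
carries its member accessions, a seed alignment (`StockholmAlignment`, with
functional-residue columns riding in a `#=GC FUNC_RES` mask so the files stay
valid for third-party tools), residue specifications, a profile and
calibrated cutoffs. `validateHierarchy()` reports — rather than raises —
violations of level ordering, member containment and cross-level residue-spec
satisfiability; cross-MSA columns are projected through a shared alignment
row, and checks without any shared row are listed as skipped rather than
silently passed.

## The similarity backend

All scores come from one built-in backend with a single gap convention (a gap
of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$; BLOSUM62, open 11,
extend 1 by default). Raw scores are converted with the Karlin–Altschul
identities

$$\mathrm{bit} = \frac{\lambda\,\mathrm{raw} - \ln K}{\ln 2},\qquad
  E = m\,n\,2^{-\mathrm{bit}},$$

with the standard gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$.
Bit scores are independent of the search-space size, which is why all
thresholds are expressed in bits; E-values depend on the query length $m$ and
database residue count $n$ and are used only for network edges.

Profiles are position-specific scoring models built from seed alignments:
columns with more than 50% gaps are dropped, and each retained column scores
residue $a$ as $\operatorname{round}\!\big(2\log_2\frac{(c_a+1)/(n_r+20)}{1/20}\big)$
— integer half-bit log-odds with one pseudocount per residue against a
uniform background. The uniform background matches the synthetic generator
and keeps the arithmetic auditable; it is deliberately simpler than the
mixture priors of full profile-HMM packages, and the package's external-tool
contract (`importHits()` for HMMER `--tblout` and BLAST `-outfmt 6`) exists
precisely so that a production HMM backend can replace the built-in scorer:
calibration consumes only ranked bit scores. Profile search is *glocal* —
global in the profile (skipped columns are penalized as deletions), local in
the target — matching how a whole-domain model is scored against subsequences
of multi-domain proteins; the search keeps a column trace for every hit so
residue checks can read the aligned query residue under any spec column.
Full forward/Viterbi HMMs, composition adjustment and seeding heuristics are
out of scope by design.

The DP kernels (Needleman–Wunsch, Smith–Waterman, glocal profile search) are
implemented in C++. The batch kernels propagate match and column counts
through the recursion in a packed 64-bit word ordered by (score, matches,
columns), which yields percent identity without traceback and one
deterministic tie-break.

## Seed-set reduction

Seed alignments are capped at 250 sequences: larger alignments are hard to
curate, slow to compute with, and biased by over-represented lineages.
`reduceSeedSet()` first drops fragments shorter than half the median length
(short chains distort alignment columns), then walks a descending identity
ladder (0.9, 0.8, …, 0.4 by default), greedily clustering the whole filtered
set at each rung and keeping representatives, stopping at the first rung
whose representative count fits the cap; if the ladder is exhausted the cap
longest representatives are kept. Greedy clustering processes sequences in
canonical order (length descending, id ascending), so the result is
independent of input order; each sequence joins the first representative it
matches at or above the rung identity, giving the coverage guarantee that
every filtered sequence is at least final-rung identical to some retained
seed. Identity is measured on the optimal global alignment (matches divided
by alignment columns). The exact ladder is a documented default, exposed in
`seedConfig()`, standing in for curator practice; conservative prefilters
(length ratio, a k-mer count bound sound for thresholds above
$(k-1)/k$, and a bit-parallel longest-common-subsequence bound) skip only
pairs provably below the rung, so they never change the clustering.

## Threshold calibration

For each node, the database is searched with the node's profile and the
ranked bit scores (best score per target; equal scores count as one rank;
non-positive bits are discarded as beneath consideration) yield two candidate
trusted cutoffs:

* the score before the first relative drop of at least 10%
  (`findDrop()`), and
* the score at which the entire seed set has been captured, i.e. the lowest
  seed score (`seedCaptureScore()`).

When both exist the **lower** is the trusted cutoff TC; the noise cutoff NC
is the next strictly lower ranked score (equal to TC when nothing follows —
in particular when the only obtainable score is the seed-capture score); and
the gathering threshold is the arithmetic midpoint $GA = (TC+NC)/2$.
"Midpoint" is interpreted on the bit-score scale, since bits are the quantity
every other rule manipulates. The GA is deliberately lax: specificity comes
from residue post-processing, not from the score gate. A curator can override
the GA (`calibrationConfig(manualGA=)`), mirroring the manual decision
required when no automatic candidate exists. One caveat the rules imply: a
newly inserted very high score can manufacture a new first drop and thereby
move the drop candidate, so insensitivity to additional top-of-list hits is
guaranteed only for insertions that create no fresh ≥10% fall; the
lower-of-both rule confines the effect to nodes where seed capture was not
the binding candidate.

## Annotation transfer

`assignAnnotation()` evaluates the superfamily profile first; a query below
the superfamily GA stays unannotated. Otherwise every child whose bit score
reaches its own GA is followed downward. Residue checks are applied at
*every* level that defines residue specs (the conservative reading where the
contract is open): a spec passes iff the aligned query residue at the spec's
seed-MSA column — located through the profile column map and the hit's column
trace — is in the allowed set; a deletion at the spec column fails. Family
assignment always requires passing residue checks, so no query can ever be
labelled at family level with profile evidence alone; a family passing on
score but failing residues yields an assignment at its parent with the
failing residue report attached. When sibling nodes pass at the same depth
the higher bit score wins (ties by name) and runners-up are listed in the
diagnostics. `batchAnnotate()` tabulates the transfers deterministically
(id-ascending) and refuses duplicate query ids.

## Sequence similarity networks

`buildNetwork()` aligns all pairs locally; for each unordered pair the
retained E-value is the **larger** (less significant) of the two directional
E-values — with a symmetric matrix the raw score is symmetric, so this is the
E-value computed with the longer sequence as query — giving conservative
edges. Nodes always carry sequence length; `paintAttributes()` merges curator
metadata; singletons are kept through `applyThreshold()` so the network keeps
showing coverage of the sequence space. `thresholdSweep()` reports edge
counts, component counts and memberships across a permissive-to-stringent
E-value ladder: edge deletion makes edge counts non-increasing and component
counts non-decreasing by construction, and somewhere along the sweep the
components track the functional subdivision of interest.
`makeRepresentative()` collapses clusters (reusing the greedy clustering) into
representative nodes whose attributes are summarized as a sorted unique value
list plus the modal value (ties lexicographic). `exportBundle()` writes the
dissemination archive — XGMML (numeric attributes at 17 significant digits,
so round trips are exact), README, and the node length histogram as image
plus table. The archive is written by a built-in STORE-method zip writer, so
no external archiver is needed.

## The synthetic superfamily generator

`generateSuperfamily()` emulates the object of study: a root ancestor
(uniform residue background, 280 residues) diverges into subgroup ancestors
(per-site substitution probability 0.45), family ancestors (0.25) and members
(0.08), with conserved residues planted at disjoint positions per level (4
superfamily, 3 per subgroup, 3 per family) and frozen within their lineage.
A 0.3 fraction of members carries an appended unrelated domain (60–120
residues), exercising the EFD machinery and the glocal search. Two
partially classified tiers mirror real superfamilies, which always contain
sequences placed only at subgroup or only at superfamily level: 12 unplaced
subgroup members per subgroup (divergence 0.35 from the subgroup ancestor,
subgroup and superfamily residues intact) and 12 unplaced superfamily members
(divergence 0.55 from the root). Besides realism these tiers matter
methodologically: the drop rule presupposes a ranked continuum with hits
below the seed set, and a database containing only perfect members and random
decoys degenerates to the TC = NC corner case. Unplaced sequences are node
members but not curated seeds, so they anchor the noise cutoffs naturally.

`generateQueries()` draws fresh held-out members per family (20 by default)
by the same process, plus 20% mutant copies with one family-level planted
residue knocked out — catalytic knockouts that the residue gate must hold
above family level. Ground truth (labels, planted positions, EFD ranges) is
recorded exactly, and everything is byte-reproducible from the seed.

The model is i.i.d. substitution without insertions; an optional deletion
mode (rate 0.01, never at planted positions) exercises gapped alignments and
the gap-majority column rule while keeping ancestor coordinates addressable.
What the generator does **not** emulate — rate heterogeneity across sites,
insertions, phylogenetic correlation beyond the three-level tree, biased
residue composition, convergent residue changes — bounds what passing tests
show: they validate the machinery (threshold rules, residue gating, network
behaviour) under a clean evolutionary signal, not the difficulty of any real
superfamily.

## Numerical choices and degenerate inputs

* Integer raw scores everywhere; bit scores and E-values in double
  precision. E-values near $10^{-170}$ for near-identical domain pairs stay
  comfortably inside double range.
* Ties: hit tables order by bit score descending then target id; greedy
  clustering by length descending then id; sibling assignments by bit then
  name; modal attribute values lexicographically.
* Degenerate inputs raise early, descriptive errors: empty sequences, ragged
  alignments (naming the offending row), single-row MSAs, duplicate ids,
  unsorted score lists, spec columns dropped from a profile, uncalibrated
  nodes, seed sets absent from a hit table (the curator-decision error).
* The problem sizes used by the shipped tests and the acceptance script —
  a 240-member default superfamily for calibration, annotation and network
  checks, and a ~1000-member superfamily for the seed-reduction bound — were
  chosen as the smallest sets that exercise every tier of the hierarchy with
  stable statistics.

## Known limitations

* The built-in profile scorer is not an HMM: no position-specific transition
  probabilities, no local-local envelope estimation. Against distant homologs
  its glocal scores drop faster than hmmsearch's would; the import contract
  is the intended escape hatch.
* Calibration against a database without sub-seed homologs collapses to
  TC = NC (reported in the diagnostics); thresholds from such databases are
  exact but not lax.
* The seed-inside-profile training bias (~1/n per column) slightly inflates
  seed scores relative to held-out sequences; with a lax GA this is
  immaterial, but it is visible whenever GA = TC.
* XGMML attribute round trips are exact for scalar attributes; list-valued
  summaries on representative nodes travel as comma-joined strings.
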