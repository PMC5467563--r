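# sfcurate

Biocuration toolkit for functionally diverse enzyme superfamilies.

A functionally diverse superfamily is a set of homologous enzymes that share
only an aspect of their chemistry — a partial reaction, a metal site, a
catalytic strategy — while its reaction families have diverged to catalyse
different overall reactions. Curating one means classifying members along a
superfamily → subgroup → family hierarchy (families are isofunctional) and
transferring functional annotations only to the depth the evidence supports:
transferring a family-level function on similarity alone is the classic
over-annotation error. `sfcurate` is for curators and method developers who
need that workflow as reproducible, scriptable pieces:

* **Seed selection** — reduce thousands of homologs to a ≤ 250-sequence seed
  set that still samples the whole set (fragment filter, descending identity
  ladder, greedy clustering; `reduceSeedSet()`).
* **Profiles and thresholds** — build position-specific scoring profiles from
  seed alignments and calibrate trusted / noise / gathering bit-score cutoffs
  from a ranked search (`buildProfile()`, `searchProfile()`,
  `computeCutoffs()`). With candidate cutoffs from the first ≥ 10% score drop
  and from whole-seed-set capture, the trusted cutoff TC is the lower of the
  two, the noise cutoff NC is the next ranked score, and the gathering
  threshold is the midpoint **GA = (TC + NC) / 2** — deliberately lax,
  because specificity comes from residue checks, not the score gate.
  Bit scores follow the Karlin–Altschul identities
  `bit = (λ·raw − ln K)/ln 2`, `E = m·n·2^(−bit)`.
* **Annotation transfer** — assign each query (or each enzyme functional
  domain, `efdSlice()`) to the deepest level whose profile passes its GA
  *and* whose conserved catalytic residues are intact; a knockout at a
  family-planted residue is held at subgroup level (`assignAnnotation()`,
  `batchAnnotate()`).
* **Sequence similarity networks** — all-vs-all alignment with conservative
  (worst-directional) E-value edges, threshold sweeps, representative
  networks with attribute summaries, and Cytoscape-compatible XGMML bundles
  (`buildNetwork()`, `thresholdSweep()`, `makeRepresentative()`,
  `exportBundle()`).
* **Synthetic ground truth** — a generator that evolves a superfamily from a
  common ancestor with planted conserved residues at every level, unplaced
  (partially classified) tiers, optional extra domains and labelled held-out
  queries, so the whole pipeline is testable offline
  (`generateSuperfamily()`, `generateQueries()`).

External search tools plug in through `importHits()` (HMMER `--tblout`,
BLAST `-outfmt 6`): calibration consumes only ranked bit scores, so the
built-in scorer and a production HMM backend are interchangeable there.

## Worked example

```r
library(sfcurate)

# a synthetic superfamily with known ground truth
sf <- generateSuperfamily(synthConfig(seed = 1))
sf$hierarchy
#> superfamily 'synthSF': 288 member(s), 4 residue spec(s)
#>   subgroup 'sg1': 92 member(s), 3 residue spec(s)
#>     family 'sg1_fam1': 40 member(s), 3 residue spec(s)
#>     family 'sg1_fam2': 40 member(s), 3 residue spec(s)
#>   subgroup 'sg2': 92 member(s), 3 residue spec(s)
#>     ...

# calibrate profiles and thresholds against the members plus shuffled decoys
db  <- c(sf$sequences, shuffleResidues(sf$sequences[seq(1, 240, 4)], seed = 99))
cal <- calibrateHierarchy(sf$hierarchy, db)
cal@children[[1]]@children[[1]]@cutoffs
#> Cutoffs: TC=671.00 NC=316.62 GA=493.81 (method: lower_of_both)
```

TC = 671 is the lowest bit score of the family's own seed members against
its profile; NC = 316.6 is the next ranked score (the best non-member, here
a sibling-family sequence); the gathering threshold 493.8 sits in the gap
between them, so genuine family members clear it with a wide margin.

```r
# annotate held-out queries (intact members and catalytic knockouts)
q   <- generateQueries(sf)
tab <- batchAnnotate(q$sequences, cal)
head(tab[, c("id", "subgroup", "family", "assigned_level", "evidence")], 3)
#>               id subgroup family assigned_level          evidence
#> 1 sg1_fam1_mut01      sg1   <NA>       subgroup hmm_plus_residues
#> 2 sg1_fam1_mut02      sg1   <NA>       subgroup hmm_plus_residues
#> 3 sg1_fam1_mut03      sg1   <NA>       subgroup hmm_plus_residues
table(tab$assigned_level)
#>   family     none subgroup
#>      119        1       24
```

All 24 catalytic knockouts pass the family *score* gate but fail the residue
check, so they are held at subgroup level — the over-annotation guard. Of
120 intact held-out queries, 119 recover their planted family; one falls
just below a gathering threshold and stays unannotated rather than being
guessed.

```r
# similarity network over the classified members, swept to stringency
classified <- sf$truth$id[!is.na(sf$truth$family)]
net <- buildNetwork(sf$sequences[classified], maxEvalue = 1)
net
#> SimilarityNetwork (full): 240 node(s), 25461 edge(s)
thresholdSweep(net, c(1e-6, 1e-20, 1e-30))
#>   cutoff n_edges n_components
#> 1  1e-06   11886            1
#> 2  1e-20    9480            3
#> 3  1e-30    9480            3
```

Tightening the edge threshold strictly loses edges, and at 1e-20 the network
resolves into exactly the three planted subgroups. `exportBundle(net,
"ssn.zip")` packages the network as XGMML with a README and the node length
histogram, the form in which curated networks are disseminated.

A thin command-line front end over the same functions is installed at
`system.file("scripts", "sfcurate.R", package = "sfcurate")` with
subcommands `synth`, `seeds`, `calibrate`, `annotate`, `ssn` and `sweep`.

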