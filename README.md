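# tcrclone

Clonotype graphs and sharing statistics for paired single-cell T cell
receptor (TCR) repertoires.

## The problem

Single-cell sequencing of antigen-reactive T cells yields, per cell, the
rearranged TCR α (TRA) and β (TRB) chains with their CDR3 junctions. Three
questions recur in autoimmunity studies built on such data:

1. **What is a clone?** Cells can carry one or two chains per locus, chains
   drop out, and the same junction can recur in different cells. tcrclone
   builds an undirected *chain-pairing graph* — one vertex per unique chain
   (locus + junction amino-acid sequence), one edge per within-cell
   codetection — and defines a clone as a connected component: a maximal set
   of chains paired with one another but not with chains outside the set.
   Vertex weight is the number of distinct cells carrying the chain; each
   component gets a deterministic `Clone_<k>` identifier and a topology
   label such as `1 TRA-2 TRB`.

2. **Which junctions are shared?** A junction seen in ≥ 2 cells is
   *expanded* (evidence of clonal proliferation); a junction found in more
   than one donor is *public*, otherwise *private*. Group comparisons are
   equalized by iterative random downsampling (by default 10,000 iterations
   of 183 junctions per group), with Gini–Simpson diversity, Shannon
   entropy, junction-length Wilcoxon rank-sum tests, Fisher's exact tests
   and Benjamini–Hochberg FDR.

3. **Is the sharing germline-driven?** Public junctions tend to be short and
   easy for V(D)J recombination to produce. tcrclone scores each junction's
   generation probability
   `pgen(s) = Σ_scenarios P(V) P(delV) P(ins len) Π P(nt) P(delJ) P(J)`
   under a small, fully declared recombination model (no D segment, no
   palindromes), summed exactly over every (V, deletions, insertion, J)
   scenario that concatenates to `s` — at nucleotide or amino-acid level.
   External pgen values (e.g. from inference-based models) can be imported
   instead. TRB junctions that share a TRA chain are compared by pairwise
   Levenshtein distance against resampled null sets of nonexpanded TRB
   junctions, with two-sample Kolmogorov–Smirnov tests.

A synthetic-repertoire generator with per-junction ground truth (injected
public junctions, convergent TRA chains with near-duplicate TRB partners,
invariant iNKT spike-ins, chain dropout) makes every analysis testable
without any external data.

## Worked example

```r
library(tcrclone)

design <- repertoireDesign(groups = data.frame(name = c("HC", "newT1D", "T1D"),
                                               n_donors = c(4, 6, 4),
                                               cells_per_donor = c(38, 62, 68)),
                           seed = 42)
sim <- generateRepertoire(design)
repertoire <- applyFilters(sim$table, filterConfig())   # drops iNKT/MAIT chains
repertoire
#> RepertoireTable: 1534 chain records, 795 cells, 14 donors (HC/newT1D/T1D)
#>   loci: TRA=752, TRB=782

sharing <- classifyJunctions(repertoire)
sharing
#> SharingSummary: 1233 unique junctions (51 public / 1182 private), 224 expanded
#>   expanded cells: 329 / 795

graph <- buildCloneGraph(repertoire)
graph
#> CloneGraph (aa): 1233 chains, 633 pairing edges, 600 clones
head(callClones(graph)[, c("clone_id", "topology_label", "n_cells")], 3)
#>    clone_id topology_label n_cells
#> 12  Clone_1    2 TRA-2 TRB       6
#> 9   Clone_2    3 TRA-1 TRB       4
#> 19  Clone_3    1 TRA-2 TRB       4

pairing <- pairingEnrichment(repertoire, sharing, fromLocus = "TRA")
pairing$table                      # multi/single TRB partners x publicness
#>         cls
#>          public private
#>   multi      30       1
#>   single      1     557
signif(pairing$p, 3)
#> [1] 4.25e-48

obs <- sharedTraTrbDistances(repertoire, sharing, scope = "public")
nulls <- nullDistanceSets(repertoire, sharing, setSize = 20, nSets = 1000, seed = 7)
ks <- ksMedianP(obs, nulls)
c(median_p = signif(ks$median_p, 3), direction = ks$direction)
#>   median_p  direction
#> "0.000351"    "lower"
```

Reading: 51 of 1233 junctions are public; public TRA junctions pair with
multiple distinct TRB junctions far more often than private ones (30/31 vs
1/558, Fisher p ≈ 4×10⁻⁴⁸ — the generator planted convergent TRA chains and
cross-donor public junctions); and the TRB junctions sharing a TRA chain are
more alike in sequence than random nonexpanded TRB sets (KS median p ≈
0.0004, shifted lower). On real AIRR rearrangement TSVs use
`readRearrangements(path)` in place of the generator.

A command-line wrapper (`inst/cli/tcrclone`) exposes `simulate`, `analyze`
(filters → clone graph → sharing → downsampling → lengths → pairing →
Levenshtein null → pgen, one TSV per analysis plus a run log) and `report`,
driven by a YAML config; exit codes are 0 / 2 (configuration error) /
3 (data error).

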