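---
title: "Models and methods behind tcrclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tcrclone analyzes paired-chain TCR repertoires from single-cell data: it
calls clones on a chain-pairing graph, classifies junction sharing within
and across donors, and asks whether shared junctions look germline-like.
This vignette explains the models and the choices behind them; nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The chain-pairing graph and the clone definition

Each unique chain — locus plus junction amino-acid sequence, by default —
is a vertex, weighted by the number of distinct cells in which the chain
was detected. Two chains are joined by an edge when at least one cell
contains both; the edge weight counts those cells. A **clone** is a
connected component: the maximal set of chains paired with one another but
not with chains outside the set. This definition deliberately merges cells
that share either chain, so convergent α chains recruiting several β chains
appear as one component with topology `1 TRA-2 TRB` and so on.

Choices worth knowing:

* **Chain key resolution.** Amino-acid junctions without V/J genes by
  default: at this resolution junction identity almost always implies gene
  identity, and sharing analyses operate on amino-acid junctions anyway.
  `strictGenes = TRUE` adds the gene calls; `resolution = "nt"` switches to
  nucleotide junctions (records without one are excluded and counted).
* **Edge support.** An edge requires one supporting cell
  (`minEdgeCells = 1`). Whether a codetection threshold above 1 is ever
  warranted depends on doublet rates; the parameter exists, the default
  keeps every observed pairing.
* **Clone identifiers.** Components are sorted by descending member-cell
  count, ties broken by the lexicographically smallest chain key, and named
  `Clone_1`, `Clone_2`, … The scheme is deterministic and stable under row
  order and cell relabeling; the numbers themselves carry no meaning and are
  not comparable across datasets.
* **Multi-chain cells.** Cells with more than two chains of a locus are
  kept; removing suspected doublets is the filter module's job
  (`filterConfig(max_chains_per_locus = 2)`), not the graph's.

## Sharing: expanded, public, private

Per unique (locus, junction): *expanded* ⇔ observed in ≥ 2 cells; *public*
⇔ observed in > 1 donor, else *private*. Both are definitional, so on
dropout-free data the classification recovers generator ground truth
exactly — which is precisely what the recovery tests assert. Publicness is
computed on the filtered table by default; a junction present in several
disease groups is attributed to each and flagged `cross_group`.

The filter chain runs in a fixed order, each step logged with its removal
count: (a) an invariant-chain blocklist — the iNKT α chain
TRAV10/CVVSDRGSTLGRLYF/TRAJ18, a bystander lineage that contaminates
CD154-enriched CD4 data, plus the canonical MAIT chain (TRAV1-2/TRAJ33) as
an extension default; (b) an optional memory-only cell restriction;
(c) minimum UMI/read support; (d) a per-cell chain-count cap per locus.

Reference overlap (e.g. against a VDJdb export) matches a query junction to
same-locus reference junctions at distance 0 or 1. The one-mismatch metric
is substitution-only (Hamming, equal lengths) by default — "single amino
acid mismatch" in a junction of the same length class — switchable to
Levenshtein ≤ 1, which additionally admits one indel.

## Downsampling-equalized comparisons

Sharing counts scale with sequencing depth, so groups are compared after
sampling an equal number of units (default: unique expanded junctions)
without replacement, many times, and taking per-group medians. Defaults are
183 junctions and 10,000 iterations — the scale at which such comparisons
stabilize in datasets of a few thousand cells — both configurable.
Per-iteration seeds are drawn once from the master seed, so results are
reproducible and independent of iteration order. Publicness inside a
subsample is taken from the full-data classification by default (the
population being downsampled is already classified); `reclassify = TRUE`
rederives it within each cell/donor subsample instead, which is the right
choice when the unit changes the donor structure.

Diversity uses the Gini–Simpson form 1 − Σpᵢ² (inverse Simpson available)
and Shannon entropy in bits. The junction-length and pgen comparisons use
the two-sided **unpaired Wilcoxon rank-sum** test: the public and private
strata are unpaired samples, so the rank-sum (Mann–Whitney) form is the
coherent choice even where figure legends in this literature sometimes say
"signed rank". When both samples are completely tied the normal
approximation has zero variance; identical rank distributions carry no
evidence of a shift, so p = 1 is returned. FDR control is
Benjamini–Hochberg, with the family defined as the tests reported together
in one output table.

## The Levenshtein null test

For every TRA junction (optionally restricted to public TRA) codetected
with ≥ 2 distinct TRB junctions, all pairwise Levenshtein distances among
its partners are pooled into one observed distribution — mirroring a single
pooled histogram rather than per-TRA testing, which would be hopelessly
underpowered at a handful of pairs per chain. Null sets draw the same
number of junctions from unique **nonexpanded** TRB junctions (pooled
across donors by default; per-group pools available) and the observed
distribution is compared to each null set with a two-sided two-sample KS
test; the median p over sets and the direction of the median shift are
reported. Distances are small integers, so the KS statistic is computed on
heavily tied data and the test is conservative; the median-p summary over
many null sets is the stable quantity, not any single set's p-value. The
edit-distance kernel itself is compiled (unit-cost DP) and is checked in
the test suite against both a memoized recursion written straight from the
definition and `utils::adist`.

## The recombination model and pgen

The generative model is deliberately simple: junction = V prefix (trimmed
from its 3′ end by a per-segment deletion distribution) + untemplated
insertion (length distribution, independent per-position nucleotide
distribution) + J suffix (trimmed from its 5′ end). No D segment, no
palindromic nucleotides, no sequence-dependent trimming. The payoff is
exactness: the probability of a nucleotide junction is a finite sum over
every (V, delV, insertion, delJ, J) scenario that concatenates to it, and
the test suite verifies that these probabilities sum to one over the
exhaustively enumerated sample space of small models, and that Monte-Carlo
sampling frequencies match them. Amino-acid pgen sums over all synonymous
codings; rather than enumerating them, each scenario's contribution
factorizes over codon positions (prefix/suffix positions are fixed,
insertion positions carry the nucleotide distribution), which stays exact
at any junction length.

Because the model is not inferred from data, absolute pgen values are not
comparable to inference-based tools — the contract is rank structure:
fewer untemplated insertions ⇔ higher pgen ⇔ more germline-like, with the
TRA model given shorter insertion support (0–9, mode 2) than TRB (0–12,
mode 3) to encode the smaller number of nontemplated nucleotides at the VJ
joint. `importPgen()` attaches externally computed values when absolute
scales matter. Sampling enforces in-frame, stop-free junctions by
rejection, because observed amino-acid junctions represent productive
rearrangements; the recorded per-draw scenario probability equals that
scenario's pgen contribution, which the tests exploit.

The built-in models declare 20 V and 20 J segments per locus, built as
families around eight base sequences with one interior codon swapped per
family member — closely related germline genes in miniature. The segment
count is a calibration choice: with a few thousand cells, an 8×8 model
produces cross-donor junction collisions at many times the rate seen in
real repertoires of this size, which would swamp the planted public
junctions; at 20×20 with deletion range 0–6 the generator yields, at the
default study scale (3 groups, 12/24/12 donors, ≈ 2,760 cells), about
4,200 unique junctions split nearly evenly between loci and a public
junction count in the few hundreds — the scale of the data the package is
designed for. These numbers are produced, not asserted: the acceptance
script computes them on every run.

## The synthetic generator and what passing tests mean

`generateRepertoire()` plants known structure: latent clones per donor with
geometric (default p = 0.85, so ≈ 28% of cells sit in multi-cell clones) or
zipf sizes; injected public junctions spread over ≥ 2 donors, drawn with
zero insertions when `zeroInsertionBias` is on (making them germline-like
by construction); convergent TRA chains whose TRB partners are single-
substitution mutants of a base (pairwise distance ≤ 2); an invariant iNKT
spike at a configurable cell rate; per-cell locus dropout; memory/naive
labels. Ground truth records each junction's label and intended sharing
*before* dropout — dropout only removes evidence, a monotonicity the tests
check directly.

The generator emulates multi-donor structure, expansion, convergence and
dropout. It does **not** emulate V/D/J germline diversity at real scale,
sequence-dependent trimming, allelic inclusion biology (extra chains arise
only through the planted structures), transcript-level noise, or
phenotype beyond the memory/naive label. Passing recovery tests therefore
demonstrates that the analysis chain detects these structures when present
and stays quiet when absent — not that any particular biological dataset
will show them.

One subtlety: in a dropout-free paired-chain world, *any* junction shared
across donors mechanically pairs with multiple partners, because each donor
recombines the partner chain independently — cross-donor collisions are
genuine convergent recombination. The no-enrichment control for the
reverse (per-TRB) pairing test is therefore run on high-entropy models
under which collisions essentially never occur, and only replicates whose
ground truth contains no cross-donor sharing enter the assertion.

## Numerical and interface choices

* Junctions follow the IMGT convention (conserved C…F/W anchors included);
  sequences are uppercased on read, gene calls kept verbatim.
* `junction_aa` is authoritative; a `junction_nt` that does not translate
  to it raises a warning, not an error — single-cell assemblies are noisy.
* Degenerate inputs fail loudly with typed conditions: configuration
  errors (bad settings; CLI exit 2) vs data errors (inputs that cannot
  support the analysis, e.g. an empty table, an over-large downsampling
  target naming the offending group, a null pool smaller than the set
  size; CLI exit 3).
* Ungenerable junctions report pgen 0 with an `ungenerable` flag rather
  than −Inf on the log scale, and are excluded from median comparisons
  with a message.
* All stochastic stages derive their seeds from one master seed by fixed
  offsets, so a pipeline run is reproducible end to end; the test suite
  asserts byte-identical outputs for repeated runs.
* Test problem sizes: oracle sweeps use 1,000 random graphs, 10,000
  random string pairs and 1,000 random contingency tables; signature
  recovery uses 100 replicates at ≈ 2,100 cells each, with smaller
  companion designs (≈ 330 cells) for the distance-null and control
  checks. These sizes put the property estimates' binomial error well
  inside the asserted margins while keeping the default suite to a few
  minutes.

## Known limitations

Absolute pgen values are model-dependent and intentionally not comparable
to inference-based estimates; only public-vs-private contrasts are
contracted. The KS test on tied integer distances is conservative. Clone
calling treats every codetection as real pairing — ambient contamination
or doublets must be handled upstream via the filter config. The donor
sharing matrix counts unique junctions, not cells, so one heavily expanded
public junction contributes 1 to each donor pair it spans.
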