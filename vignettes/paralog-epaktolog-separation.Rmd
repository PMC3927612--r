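---
title: "Separating paralogs from epaktologs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating paralogs from epaktologs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paranet)
```

# The inference problem

Orthology, paralogy and pseudoparalogy do not exhaust the ways two
multidomain proteins can be homologous. Independent acquisition of the
same mobile domain family by unrelated genes — domain shuffling —
creates *epaktologs*: proteins whose only shared history is the imported
domain. Because mobile domains are typically short and often tandem
duplicated, the chained alignment of a shared array can outscore the
full-length similarity of genuine paralogs, so neighbour lists from
all-against-all searches mix the two relationships. This package
implements network-structural and architecture-based procedures that
tell them apart, and quantifies what happens to domain-architecture
(DA) statistics when they are not told apart.

# Similarity networks and their decomposition

A TSS = *k* dataset keeps, per query, the *k* top-scoring non-self
matches with e-value below the homology cutoff (default $10^{-5}$,
strict `<`). Edges are directed, $u \to v$ iff $v$ is in $u$'s list.
Two reading frames of the same graph drive the separation:

* **strong components** — maximal mutually reachable vertex sets. A
  paralog pair tends to rank each other highly in both directions,
  whereas the epaktolog link is usually asymmetric: the protein with the
  large tandem array has closer relatives of its own, so the intruding
  edge is not reciprocated and the strong component stays clean.
* **weak components** — connectivity on the undirected shadow. A single
  one-way epaktolog edge suffices to fuse two families, which is why
  weak components absorb shuffled-domain proteins much earlier in *k*.

The wording of the underlying construction mixes directed and
undirected intuitions; we compute strong components on the directed
graph and weak components on its undirected shadow, which reproduces
all the qualitative behaviours the procedures are known for
(asymmetric best-hit chains join weak but not strong components).

Ranking uses the bit-score as the primary key, not the e-value: e-values
saturate at the numeric floor for strong matches while bit-scores remain
informative. Ties break by ascending e-value, then lexicographic subject
id, so every ranking is deterministic. The vertex set of the graph is
fixed per cutoff (every protein involved in any qualifying hit), so
profiles across *k* compare like with like; component counts are
reported for components with at least two members ("families"), the
full partition including singletons is still returned. `trace_query()`
flags absorption into the giant component when the query's component
reaches a configurable fraction of all vertices (default 20%; the
notion of "the LCC" is inherently qualitative, so the threshold is a
parameter, not a claim).

# Interspecies best-hit clustering

Queries that share their best qualifying match in a target proteome are
clustered; with a complete, non-redundant target, two queries cluster
precisely when their duplication postdates the split with the target
species. Scanning targets in order of divergence therefore brackets
duplication dates: `duplication_timing()` returns the interval between
the youngest split that clusters the query and the oldest split showing
a 1:1 match. Two open-ended cases follow the same logic: clustered
everywhere means the duplication postdates the youngest sampled split
(interval reaching to the present); 1:1 everywhere means it predates
the oldest sampled split. Non-monotone patterns — the signature of
incomplete target proteomes, which mimic gene loss and reassign queries
to paralog or epaktolog anchors — are flagged `UNRESOLVED` rather than
treated as errors. Redundant targets (several entries for one gene) are
not collapsed; their cluster-splitting effect is part of what the
profile is meant to expose.

# Domain architecture comparison

Architectures are built from annotation tables at four cutoffs
($10^{-2}$ … $10^{-5}$, strict `<`): hits passing the cutoff are
visited by ascending e-value (ties: longer hit, then smaller start) and
accepted unless they overlap an accepted hit by more than 30% of the
shorter hit's length. The 30% tolerance is a package choice — overlap
elimination is required but unquantified in standard practice; small
tolerances admit legitimately abutting domains while still suppressing
duplicate hits to the same region.

Architecture pairs are aligned by longest common subsequence over
family tokens. Among equal-length LCSs the leftmost (greedy smallest
indices) is taken for determinism; since that tie-break depends on
argument order, `classify_difference()` evaluates both orientations and
unites the category sets, making classification symmetric — an
invariant the test suite checks on random token vectors. Each unmatched
domain contributes one category (N-terminal / C-terminal / internal by
position relative to the matched anchors), except that an unmatched
domain inside a contiguous same-family run containing a matched domain
is an extra tandem copy and is classified `DUPLICATION` — this
precedence also applies to terminal tandem copies, where positional
labels would otherwise apply. Pairs with no shared domain are
`UNASSIGNED`; pairs with no unmatched domain are `IDENTICAL`. A pair
may hold several categories at once, and with four cutoffs it receives
four (possibly different) category sets; distributions pool these
assignments and normalise over non-identical ones. Homogeneity
statistics are judged at the strictest cutoff only, which is the
primary DA definition.

Re-thresholding note: the multi-cutoff protocol here re-filters one
supplied annotation table at the four cutoffs rather than re-scanning
sequences with a second search tool; only hits present in the input can
ever appear in an architecture.

# The simulator

The generator's defaults are the study conditions for every test in the
package; they were chosen once, on biological plausibility, and are not
tuned per experiment.

* **Sequence model.** One random 20-letter template per family;
  instances evolve by i.i.d. substitutions (default
  $5 \times 10^{-4}$ substitutions/site/My — a plausible order for
  conserved protein domains) with no indels, which keeps coordinates
  exact and leaves the tested phenomena intact. A substitution event
  replaces a residue with one of the other 19, so identities plateau at
  the random-match floor rather than decaying to zero.
* **Events.** Gene duplication, terminal gain, internal gain, loss,
  tandem duplication and shuffling insertion are per-gene Poisson
  processes on the branches of a fixed ultrametric ladder tree; only
  `shuffling_insertion` (which inserts a *mobile* family and records the
  acquisition) can make two duplication-unconnected lineages
  epaktologous. Sharing a family through common ancestry or ordinary
  gain never counts — the label tracks the defining mechanism, not mere
  content, and is derived from the event history alone.
* **Scoring.** The built-in comparer chains colinear same-family
  instance pairs and sums identity × length × 2; a shared tandem array
  of t copies contributes t chained terms, reproducing the score
  inflation that makes epaktologs overtake paralogs. Pseudo e-values
  are $10^{-\mathrm{score}/S_0}$ with $S_0 = 30$, clamped to
  $[10^{-180}, 10]$ — only the ordering and the position of the
  $10^{-5}$ cutoff matter downstream. Pairs sharing neither a family
  nor an ancestral gene produce no row, as two unrelated sequences
  below the homology threshold would not.
* **Annotations.** Instance e-values are
  $10^{-(\mathrm{identity\%} - 35) \times 0.4}$; instances under 35%
  identity to their family template are undetectable. The slope places
  the four cutoffs between 40% and 47.5% identity, so deeply diverged
  domains drop out of strict architectures first and the four-cutoff
  protocol has real work to do.
* **Event log.** Every random decision is resolved into an explicit
  event record before being applied; `replay_event_log()` re-applies
  the records with no RNG and must reproduce the proteome exactly.

## The shuffling presets

`shuffle_internal`/`shuffle_terminal` encode the canonical confusion scenario: ancestors
`A` (a-b) and `X` (x-z); an old duplication (700 My) splits `A1`/`A2`;
a mobile 60-aa domain `s` is inserted into `A1` at 450 My and into `X2`
at 50 My (internally in `shuffle_internal`, terminally in `shuffle_terminal`) and tandem
duplicated three times in each. The `X` lineage duplicates twice,
recently (80 and 60 My), giving `X1`/`X2`/`X3`. The second `X`
duplication is deliberate: the asymmetry that lets strong components
reject the epaktolog edge requires the array-bearing protein to have
closer relatives of its own — with a lone reciprocal partner the
epaktolog pair would be mutual best hits and no network statistic could
separate them. The timings place the three relevant scores in the
intended order with wide stochastic margins: paralog pair `A1`–`A2`
(two 150-aa domains at ~1400 My separation) below epaktolog pair
`A1`–`X2` (four chained 60-aa copies at ~500 My) below `X2`'s own
recent paralogs (two 150-aa domains at ~160 My).

`ladder3` provides three species (splits at 600 and 300 My) and three
two-domain genes duplicating at 450 My, 150 My and never, for the
interspecies clustering and duplication-dating analyses.

## What the generator does and does not emulate

It emulates the processes the inference chain must survive:
duplication-generated paralogy at controlled depths, independent
shuffling with tandem expansion, cutoff-graded domain detectability,
and asymmetric hit tables. It does not model indels or domain-boundary
erosion, nucleotide-level exon shuffling, rate heterogeneity across
sites or lineages, horizontal transfer (pseudoparalogy), or
database-scale family size distributions. Passing tests therefore show
that the procedures behave correctly *given* the mechanisms above; they
do not certify performance on any particular real proteome snapshot,
whose error modes (misprediction, incompleteness, redundancy) enter the
package only as the stylised incompleteness experiments in the test
suite.

# Experiments shipped with the package

`run_contamination_experiment()` mixes simulated true-paralog pairs
(families evolving by duplication plus modest gain/loss/tandem rates)
with simulated epaktolog pairs (unrelated families acquiring shared
mobile domains) at 0%, 20% and 50% and recomputes the DA statistics on
each mixture; the paralog and epaktolog pools are balanced so that the
largest level is reachable, and metrics are pooled over replicates so
the internal-category denominator stays positive.
`run_insertion_position_experiment()` classifies pairs differing by one
uniformly placed insertion into an N-domain architecture (N drawn from
3–6), where internal slots outnumber each terminal slot by construction.

Problem sizes used by the tests and the acceptance script — 200 random
digraphs of up to 12 vertices for the component oracle, 50 replicates
per shuffling preset, 20 replicates of the contamination experiment,
10,000 insertion pairs — were chosen to make the binomial uncertainty
on the reported rates small relative to the margins being asserted.

# Degenerate inputs and numerical conventions

Empty hit tables parse to empty objects with a warning; malformed rows
fail with their line numbers. All cutoffs are strict (`evalue <
cutoff`), matching the conventional "< $10^{-5}$" notation. Clusters of
size one are skipped (with a warning) by homogeneity statistics;
benchmarks with no within-component pairs report `NA` precision rather
than 0. Architecture building rejects `start > end`. Every ranking,
tie-break and traceback is deterministic, so identical inputs and seeds
give byte-identical outputs; pipeline manifests record parameters and
input checksums and contain no timestamps for exactly that reason.

# Known limitations

The pseudo e-values are calibrated only ordinally; absolute values are
not comparable to BLAST. Ground-truth epaktology requires the shared
mobile family to be present in both extant architectures, so a shuffled
domain later lost makes the pair `UNRELATED` even though a trace of the
insertion remains in the log. The ladder species tree cannot express
balanced topologies, which is sufficient for divergence-ordered
profiles but not for general phylogenetic simulation. Strong-component
precision is reported against `PARALOG` labels only; in multi-species
simulations orthologs inside a component count against precision, so
benchmarks are most interpretable on single-species scenarios.
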