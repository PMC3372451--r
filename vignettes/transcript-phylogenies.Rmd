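---
title: "Reconstructing transcript phylogenies on a gene tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing transcript phylogenies on a gene tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceforest)
```

## The model

Alternative splicing produces several transcripts (isoforms) from one gene
by including or excluding exons. `spliceforest` treats the evolution of
those transcripts as a two-level process on a known, rooted, strictly binary
gene tree:

* **Gene level.** Each orthologous exon column is, in each gene, *absent*,
  *alternative* (spliced into some transcripts) or *constitutive* (spliced
  into all). Exons are gained, lost, and switch status along the gene tree.
  Gene-level events carry **zero cost**: the model is about transcript
  evolution, and a change forced by the gene structure (a constitutive exon
  appearing, an exon disappearing) should not be charged to a transcript
  lineage.
* **Transcript level.** A transcript is a vector over the exon columns
  (0 = excluded, k >= 1 = included in configuration k; configurations above 1
  encode exons with internal states such as alternative 3'/5' splice sites).
  Along each gene-tree edge a transcript lineage can gain or lose exons (cost
  `c_E` per change), die (cost `c_D`), and new transcripts can be created at
  any gene (cost `c_B`).

A candidate history is a **forest of transcript trees**; each tree is a
subtree of the gene tree (a transcript lineage cannot leave its gene family,
and a duplication starts a *new* tree). The score of a solution is

S = c_B * N_tree + c_D * N_death + S_F,

where S_F sums the Sankoff small-parsimony scores of the individual trees.
The method returns *all* minimum-score forests.

Intron retention is encoded by the caller as an extra cassette-exon column;
paralogous exons must be given distinct columns (ortholog assignment is the
caller's responsibility and out of scope here). Gene duplication nodes are
ordinary binary nodes: all gene-level events are free, so nothing
distinguishes them in the scoring.

## The algorithm

1. **Ancestral exon states.** Leaf states follow from the observed
   transcripts (constitutive iff all transcripts include the column,
   alternative iff some do, absent otherwise). Internal states minimise the
   number of unit-cost transitions per column, subject to Dollo parsimony:
   a column may be gained (absent to present) at most once in the whole
   tree. We solve this exactly by trying every candidate gain clade and
   running a constrained Sankoff pass inside it; all co-optimal labelings
   are retrievable, and the deterministic default is the first in a fixed
   enumeration order. No root prior is imposed. Ties do occur (for example
   "born present at the root then lost" versus "gained on a terminal
   edge"); downstream results that depend on the choice can be re-run per
   labeling.
2. **Topologies.** A *topology* is a forest whose leaves are not yet
   assigned: a multiset of gene-subtree shapes, one slot per covered gene
   per tree. Slots at an internal gene with no children are excluded from
   enumeration (they add `c_B + 2 c_D` and explain nothing), although edit
   operations (`remove_edge`, `branch_swap`) can produce and represent
   them. A topology is valid when every gene hosts a slot and every
   gene-tree edge is spanned by at least one parent-child slot link --- on a
   tree the two conditions together are exactly "all genes connected".
   Topologies are enumerated by direct constrained construction, grouped by
   increasing tree count and ordered by a canonical key (the sorted multiset
   of shape strings), so runs are reproducible. Edge removal and branch
   swapping are provided as the elementary moves between topologies and are
   tested against the enumerator, but they are not used as the generator:
   neither move changes per-gene slot counts, so move-based generation
   cannot reach, for example, the two-slot-at-the-root forests that exist
   whenever leaves carry several transcripts.
3. **Leaf assignment.** Given a topology, a *state* of a gene is its ordered
   slot list with pointers into one state of each child; the *guide tree*
   groups slots by identical subtree shape, and pointers must stay within
   matching groups. The number of states is bounded by the closed-form
   count `count_states(n, k_LR, k_L, k_R)`; the guide tree usually cuts it
   drastically. Two reductions are exact and worth noting: leaf states are
   fixed to the identity ordering (all leaf slots share one group, so the
   parent's pointer choices already realise every assignment), and states
   that differ only by permuting same-shape slots are collapsed to one
   representative. A postorder dynamic program then scores states; per
   state it commits to the profiles of its best child-state pair, which
   makes the procedure a heuristic on gene trees of depth greater than two.
   On trees of depth <= 2 the implementation switches to an exhaustive
   sweep over full state combinations and is exact --- hence exact on any
   3-leaf tree and on single-transcript instances. Tie chains found by
   backtracking are re-scored exactly and only those matching the best
   recomputed score are reported, so every returned solution carries its
   true score.
4. **Search.** Topologies are explored by increasing tree count. A sound
   lower bound --- structural cost plus, per tree, the relaxed Sankoff score
   computed as if all transcripts were available to that tree alone --- is
   attached as a per-shape weight and applied already while forests are
   being generated: a partial multiset whose bound exceeds the incumbent is
   cut with everything below it. The incumbent starts from random sampling
   (random demand-driven forests plus random edge removals, scored under
   random assignments; seeded and reproducible). The search stops when
   `c_B * t` alone exceeds the incumbent; since every tree covers at least
   one observed transcript, the tree count is also bounded by the total
   transcript count, which keeps the search finite for `c_B = 0`.
5. **Ranking.** All minimum-score solutions are deduplicated (two state
   combinations can describe the same labeled forest), filtered to the
   minimum total number of events (transcript-level changes + births +
   deaths + gene-level events), and ordered by decreasing mean similarity
   index --- the share of leaf exons supported by at least two leaves of the
   same tree --- with ties broken by the forest serialisation.

### The extended model

Instead of a constant `c_B`, the extended model prices each birth as the
change distance from the newborn root's reconstructed vector to its closest
ancestor among the other transcript vectors of the solution at the same
gene or any ancestor gene (a tree with no candidate keeps `c_B`; by the
same convention the root-most trees always pay something, matching the
default that every tree is charged a birth). The cost is known only after
leaf assignment, so no useful lower bound exists and the extended search
visits every topology; it is therefore gated to small instances.

## Tunable parameters

| Parameter | Meaning | Default |
|---|---|---|
| `c_B` | cost of a transcript birth (per tree) | 1 |
| `c_D` | cost of a transcript death | 1 |
| `c_E` | cost per transcript-level exon change; `Inf` forbids changes | 1 |
| `samples` | random samples per tree count for the initial upper bound | 3 |
| `max_trees` | optional cap on the number of trees | total transcripts |

Costs are unitless; only their ratios matter. `c_E = Inf` asks whether the
observed transcripts can be explained by gene-level events alone; instances
where some gene's every transcript carries an alternative-gained exon then
have no finite-score solution, and the package reports `no_solution`
rather than an answer.

## The simulator

`simulate_instance()` emulates the generative process the reconstruction
assumes: `n_E` exon columns present at the root (status drawn uniformly
between alternative and constitutive) plus as many columns initially
absent; per edge, each present column dies and each absent column is born
with the configured probabilities (a reborn column violates Dollo and is
flagged in the ground truth, deliberately: the reconstructor must stay
Dollo-consistent even when the data are not); transcripts then die, gain
and lose currently-alternative exons, and new transcripts are born as a
copy of a random existing transcript with one random flip --- matching the
extended model's closest-ancestor semantics. Event probabilities default to
0.05 per edge per exon or transcript: sparse events with occasional noise,
the regime in which parsimony reconstruction is meaningful. The number of
ancestral transcripts defaults to uniform on 1..4 when not fixed. A lineage
never goes extinct at a node (one survivor is kept and the rescue flagged),
so every leaf has at least one observed transcript.

What the simulator does not emulate: nucleotide sequences (and hence
alignment or ortholog-assignment errors), rate heterogeneity across
lineages, and any dependence of transcript events on exon identity. Passing
the simulated benchmarks therefore says the *algorithm* recovers the model
it assumes at these scales; it does not validate the model against real
transcriptomes.

## Numerical and design choices

* All scores are small integers (or `Inf`) scaled by the costs; score
  comparisons still use a 1e-9 tolerance so that non-integer costs behave.
* `Inf` is used directly for forbidden configurations; care is taken never
  to form `0 * Inf`.
* Ancestral-vector traceback breaks configuration ties by the lowest
  configuration index, deterministically.
* The brute-force oracle is an independent code path (demand-driven forest
  construction, exhaustive leaf bijections, plain per-tree Sankoff) and is
  guarded: it refuses assignment spaces beyond 1e6.
* `benchmark_optimality()` compares the dynamic program against the oracle
  on a deterministic, capped sample of each instance's topologies (the full
  space, counted exactly by `count_topology_space()`, grows faster than
  exponentially and is enumerable only for the smallest instances); the
  refined-topology percentage divides the number of topologies the pruned
  search actually assigned by that exact space size. Benchmark trends are
  asserted directionally: exact optimality at three leaves, genuine
  degradation beyond, a non-positive (non-negative) rank correlation of
  optimality (score difference) with leaf count, and a strictly falling
  refined percentage. Per-cell means at this run count carry sampling noise
  of a few percentage points, so pointwise monotonicity between adjacent
  sizes is deliberately not asserted.
* Default problem sizes in the test suite --- up to 3 leaves and 3
  transcripts per gene against the full oracle, up to 8 leaves with one
  transcript per gene, benchmark cells of 13 runs at 3--6 leaves --- were
  chosen so that the exhaustive certification itself stays tractable, the
  same constraint the original benchmarks faced.

## Known limitations

* The leaf assignment is heuristic above depth 2; the benchmark quantifies
  the gap (optimality percentage and mean score difference) rather than
  bounding it.
* The number of co-optimal solutions can be large; backtracking is capped
  (`max_solutions`) and the cap is reported implicitly by the solution
  count.
* Topology enumeration is exponential in the transcript count; instances
  past a few genes with a few transcripts each rely entirely on the lower
  bound, and adversarial cost settings (`c_B = 0`) force wide searches.
* Reported event placements inherit the arbitrariness of co-optimal
  ancestral exon labelings; only the score is canonical.
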