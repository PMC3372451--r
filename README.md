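# spliceforest

Parsimony reconstruction of transcript phylogenies on a known gene tree.

## What problem this solves, and for whom

Alternative splicing lets one gene produce several transcripts (isoforms)
by including or excluding exons. Exon and intron evolution are well
studied; the evolution of the *transcripts themselves* is not, yet
questions like "is the short isoform in fish homologous to the short
isoform in mammals?" are phylogenetic questions. `spliceforest` is for
computational biologists who have, for one gene family: a rooted binary
gene tree, the observed transcripts of each extant gene encoded over
orthologous exon columns, and who want the most parsimonious evolutionary
history of those transcripts.

The model is two-level. The gene structure evolves first: each exon column
is absent, alternative or constitutive in each gene, changes at this level
are free, and an exon can be gained at most once (Dollo parsimony).
Transcripts evolve on top: they gain and lose exons (cost `c_E` per
change), die (cost `c_D`), and new transcripts arise (cost `c_B`). A
history is a forest of transcript trees, each tree a subtree of the gene
tree, scored by

```
S = c_B * N_tree + c_D * N_death + S_F
```

with `S_F` the sum of the trees' Sankoff small-parsimony scores under the
gene-level zero-cost rules. The package reconstructs ancestral exon
states, searches the topology space (forests with unassigned leaves) with
sound lower-bound pruning, solves the leaf assignment per topology with a
guide-tree-constrained dynamic program, and returns **all** minimum-cost
solutions, ranked by a similarity index. An extended model prices each
transcript birth by its distance to the closest ancestor instead of a
constant. A simulator, an independent brute-force oracle and a benchmark
harness are included.

## Worked example

```r
library(spliceforest)

# a cherry of two genes; Y's transcript carries exon e2, X's does not,
# but e2 is constitutive in Y and absent in X, so the gene level explains it
tree <- as_gene_tree(ape::read.tree(text = "(X,Y)R;"))
inst <- ts_instance(tree, list(
  X = matrix(c(1L, 0L), 1, 2, dimnames = list("tX", c("e1", "e2"))),
  Y = matrix(c(1L, 1L), 1, 2, dimnames = list("tY", c("e1", "e2")))))

reconstruct_ancestral_exon_states(tree, leaf_exon_states(inst))
#>   e1 e2
#> X  2  0
#> Y  2  2
#> R  2  0
#> attr(,"cost")
#> [1] 0 1

infer_transcript_phylogenies(inst, ts_costs(c_B = 1, c_D = 1, c_E = 1))
#> Minimum score S = 1 with 1 minimum-cost solution(s); 1 after the minimum-event filter.
#> Best-ranked solution: N_tree = 1 , N_death = 0 , S_F = 0
#>    R(X=tX,Y=tY)
```

Reading the output: the two observed transcripts join in a single tree
(`N_tree = 1`) spanning the root, with no transcript deaths and a
transcript-level parsimony score of zero --- the e2 difference is absorbed
by the constitutive gain of e2 on the edge to Y, which costs nothing ---
so the whole history costs one transcript birth, `S = c_B = 1`.

Simulated data with known ground truth:

```r
sim <- simulate_instance(make_caterpillar(4), sim_config(n_E = 6, n_T = 2), seed = 7)
res <- infer_transcript_phylogenies(sim$instance, ts_costs(), seed = 7)
res$score          # minimum S found
res$n_solutions    # number of co-optimal solutions
res$stats          # topologies generated / pruned / refined per tree count
```

## Command line

A thin launcher (installed under `exec/`) drives the same functions:

```sh
spliceforest simulate --leaves 5 --seed 11 --out-prefix sim
spliceforest infer --gene-tree sim.nwk --transcripts sim.tsv \
    --cb 1 --cd 1 --ce 1 --seed 1 --out results.json
spliceforest benchmark --leaf-sizes 3,4 --transcripts 1,2 --runs 5 \
    --seed 1 --out bench.csv
```

`--ce inf` forbids transcript-level changes entirely; if the instance then
admits no finite-score history the exit code distinguishes "no solution"
(4) from I/O (2) and configuration (3) errors.

Input formats: Newick for the gene tree; a TSV with columns
`transcript_id`, `gene_id`, then one integer per exon column (0 =
excluded, k >= 1 = included in configuration k). Results are written as
JSON, benchmarks as CSV.

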