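# structent

Structural-entropy community detection for weighted networks, and a
complete pipeline for turning a gene-expression matrix into a cell-sample
network, detecting tumour modules (K = 2) and submodules (K = 3) by
structural-entropy minimisation, and building the gene map that assigns
each gene to the sample module it most strongly expresses.

## The model

For a weighted undirected graph *G* with vertex degrees *d_v* and volume
*vol* (the sum of degrees), the **one-dimensional structural entropy**

&nbsp;&nbsp;&nbsp;&nbsp;H¹(G) = −Σ_v (d_v / vol) · log₂(d_v / vol)

is the average number of bits needed to locate the vertex reached by a
stationary random walk (for disconnected graphs, the volume-weighted
average over components; an edgeless graph has H¹ = 0). Given a
**partitioning tree** — a rooted ordered tree whose root holds all
vertices, whose leaves hold single vertices and whose every level
partitions the vertex set — the entropy of *G* by the tree is

&nbsp;&nbsp;&nbsp;&nbsp;H^T(G) = Σ_{α ≠ root} (g_α / vol) · log₂(V_{α⁻} / V_α),

where V_α is the volume of the vertex set at node α, g_α its cut (total
weight of edges leaving the set) and α⁻ the parent. The K-dimensional
structural entropy of *G* is the minimum of H^T over height-K trees; the
minimising tree's level-1 sets are the natural **modules** of the network
and its level-2 sets the **submodules**. `minimize_entropy()` finds a
low-entropy tree greedily with two operators: **merging** (two sibling
sets fuse; the members may later re-group one level deeper) and
**combining** (a new parent is inserted over two siblings, keeping both
as substructure), each applied only when it strictly decreases the
entropy, using locally computable deltas.

Sample networks are built from expression data by `build_network()`:
Pearson correlation between sample profiles, a noise-amplifying constant
modifier *M* added to every weight (default M = 1/(n−1) for n < 1000,
1/n otherwise), top-*k* neighbour retention, and an entropy curve H(k)
whose **stable points** (strict interior local minima) choose *k*.
`gene_map()` codes each gene to mean 0 and range [−1, 1], assigns it to
the sample group with maximal mean coded expression, and reorders the
matrix into the block pattern that displays one gene block per module.

## Worked example

```r
library(structent)

sim <- synthetic_expression(groups = 3, samples_per_group = 12,
                            genes = 600, signal_per_group = 100,
                            effect = 5, noise_sd = 1, seed = 1)
truth <- setNames(sim$truth$membership, colnames(sim$expr))
res <- run_pipeline(sim$expr, truth = truth, K = 2)
res
#> structent pipeline: k = 19, 3 modules, 3 map groups, H = 4.1007 bits
#> weighted similarity to truth: 1.0000
res$network$report$stable_points
#> [1] 14 16 19
lengths(res$modules)
#>  1  2  3
#> 12 12 12
```

The pipeline computed the pairwise Pearson weights, added the modifier
M = 1/35, scanned k = 2…35, found stable points of the entropy curve at
k = 14, 16 and 19, and kept k = 19 (least H). Entropy minimisation on the
resulting network needed 4.10 bits and returned exactly the three planted
groups of 12 samples (weighted Jaccard similarity 1.0 against the truth
labels); the gene map in `res$genemap` places all 300 planted signal
genes in their own group's block.

A command-line wrapper with subcommands `simulate`, `buildnet`,
`partition`, `genemap`, `similarity` and `pipeline` is installed at
`inst/cli/structent` (see `?structent_cli`).

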