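# trajCCI

Trajectory inference for single-cell RNA-seq that folds **intercellular
communication** into the cell graph. Most pseudotime methods order cells by
transcriptional similarity alone; `trajCCI` additionally scores
ligand–receptor co-expression between cell neighbourhoods and adds it to the
edge weights, on the premise that signalling partners tend to be adjacent on
the differentiation path. It is aimed at analysts working with desk-scale
scRNA-seq matrices (hundreds to a few thousand cells) who have — or can
simulate — a ligand–receptor pair table, and who may have external ordinal
labels (stages, sampling times) to validate orderings against.

## The method

1. **Communication (CCI) matrix.** Cells are grouped (given labels, or
   k-means with the Gap statistic). For each ligand–receptor pair
   *k* = (*L*, *R*) and group pair (*i*, *j*), a mass-action score with
   Hill saturation
   `C^k_ij = (L̄_i R̄_j) / (k_h + L̄_i R̄_j)` is projected to cell pairs:
   `P_pq = Σ_k C^k_ij` over pairs whose ligand is validly expressed
   (> 1, log scale) in sender *p* and whose receptor is validly expressed
   in receiver *q*. `P` is symmetrized and scaled to [0, 1].
2. **Fuzzy kNN graph.** On 50 principal components, per-cell conditional
   probabilities `p(i|j) = exp(-(d(x_i,x_j) - ρ_i)/σ_i)` with `σ_i`
   calibrated so neighbour weights sum to `log2(k)`; fuzzy-union
   symmetrization `p_ij = p(i|j) + p(j|i) - p(i|j)p(j|i)`; then
   **`p̂_ij = p_ij + K·S_ij`** where *K* is the communication weight
   (*K* = 0 bypasses communication).
3. **Abstraction and lineage.** Louvain partitioning; partition-graph
   connectivity = observed inter-edges over the count expected at random
   (clipped to 1); per-cell activation entropy (low = committed) summarized
   per partition over its 25% lowest-entropy core; edges oriented high → low
   entropy; lineage = maximum-weight spanning arborescence
   (Chu–Liu/Edmonds) rooted at the highest-entropy partition.
4. **Pseudotime.** Diffusion pseudotime from the highest-entropy cell of
   the root partition, with `Inf` for cells in disconnected components.
5. **Evaluation.** The pseudotime accuracy score (PAS): over cell pairs
   with distinct external labels, (concordant − discordant) / comparable,
   in [−1, 1]; `sweep_cci_weight()` scans *K* from 0 to 10 and reports the
   argmax.

## Worked example

```r
library(trajCCI)

# synthetic branching lineage with planted ligand-receptor structure
syn <- generate_lineage(600, 200, n_branches = 2, noise_sd = 0.2, seed = 1)
cfg <- trajcci_config(seed = 1)
res <- run_trajcci(syn$matrix, lr = syn$lr_table, config = cfg)
res
#> Trajectory inference result
#>   599 cells x 200 genes after preprocessing
#>   16 partitions; root partition(s): 0, 11; root cell: cell_0001
#>   lineage edges: 0->1 6->2 5->3 0->4 2->5 1->6 3->8 15->7 10->9 13->10 7->12 11->13 12->14 9->15

labels <- time_quartile_labels(syn$true_time)
pt <- res$pseudotime$pseudotime
pas(pt, labels[names(pt)])
#> PAS = 0.9963  (134300 concordant, 250 discordant, 0 tied of 134550 comparable pairs)
```

One low-complexity cell was filtered out (599 of 600 remain). The lineage
forest links 16 Louvain partitions from the high-entropy root partition 0
downwards; the root cell is the most plastic (highest-entropy) cell in it.
The PAS of 0.9963 says that 99.6% more label-distinct cell pairs are ordered
consistently with true-time quartiles than inconsistently; the per-cell
entropy correlates with true time at Spearman −0.97 on this fixture.

Everything is also available from a shell via the thin CLI:

```sh
Rscript inst/scripts/trajcci simulate --n-cells 600 --seed 1 --outdir sim/
Rscript inst/scripts/trajcci run --matrix sim/matrix.mtx --genes sim/genes.txt \
    --cells sim/cells.txt --lr sim/lr_pairs.csv --outdir out/
Rscript inst/scripts/trajcci sweep --matrix sim/matrix.mtx --genes sim/genes.txt \
    --cells sim/cells.txt --lr sim/lr_pairs.csv --metadata sim/truth.tsv --outdir out/
```

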