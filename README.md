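# difftraj

Pseudotime trajectory inference with multi-branch detection for
single-cell expression data, built on graph diffusion.

Developmental processes leave a continuum of cell states in a
single-cell experiment, but the assay destroys the cells, so time must
be reconstructed from the data: each cell gets a *pseudotime* in
[0, 1] ordering it along the inferred progression, and a *branch*
label separating diverging fates.  `difftraj` targets analysts who
already have a pre-processed (log-scale, feature-selected)
cells-by-genes matrix and want an ordering plus a lineage tree with
possibly several bifurcation events, not just one.

## Method in brief

For an expression matrix $X \in \mathbb{R}^{N\times D}$:

1. **kNN graph** with adaptive Gaussian affinities
   $K_{ij} = \exp(-\lVert x_i-x_j\rVert^2 / 2\sigma_i\sigma_j)$,
   $\sigma_i$ = distance to the $k$-th neighbour; symmetrized,
   normalized by $Z_iZ_j$, then row-normalized to a Markov matrix $M$.
2. **Random walk with restart**: continue along $M$ with probability
   $p$, teleport to the seed with $1-p$; the stationary operator
   $S = (1-p)(I-pM)^{-1}$ gives every cell a probability distribution
   over the manifold (the accumulated-transition construction of
   diffusion pseudotime is the $p\to1$ limit).
3. **Bhattacharyya kernel** between diffusion rows,
   $G = \sqrt{S}\sqrt{S}^{\mathsf T}$, and its log.  A spectral
   decomposition of $\log G$ (top $d$ components by absolute
   eigenvalue) gives a low-dimensional embedding for visualization.
4. **Pseudotime**: the kernel distance
   $D_{ij} = \sqrt{-2\log G_{ij}}$ — a true metric, computed from the
   full $\log G$ before any dimension reduction — is measured from a
   root cell (user-supplied, or the most distal cell of the earliest
   stage) and min-max normalized to [0, 1].
5. **Branches**: a reverse search scans cells by decreasing pseudotime
   and grows candidate groups over the kNN graph; when one cell's
   neighbourhood bridges two groups that each hold at least `n` cells,
   a bifurcation is confirmed and both become branches.  Branch 1 is
   always the trunk containing the root.

A seeded simulator (`simulate_branching()`) plants linear, bifurcating,
trifurcating or two-level lineage trees with known truth, and the
evaluation helpers implement Kendall-tau-vs-stage accuracy and the
repeated 90%-subsampling Spearman robustness protocol.

## Worked example

```r
library(difftraj)

sim <- simulate_branching(300, 50, "bifurcating", noise_sd = 0.2, seed = 1)
res <- run_pipeline(sim$X, k = 10, p = 0.9)
res
#> trajectory_run: N = 300  k = 10  p = 0.9
#> root(s): cell_253 ; branches: 3
res$summary
#>   branch size     t_min     t_max
#> 1      1  151 0.0000000 0.6598030
#> 2      2   79 0.5900435 1.0000000
#> 3      3   70 0.6151025 0.9751314

kendall_accuracy(res$pseudotime, sim$truth$true_pseudotime)
#> [1] 0.9246377

rb <- robustness_protocol(sim$X, fraction = 0.9, n_reps = 50, seed = 2)
c(mean = rb$mean, sd = rb$sd)
#>         mean           sd
#> 0.9989202283 0.0006245848
```

The three branches are the trunk (151 cells, pseudotime starting at 0,
containing the root) and the two arms created at the bifurcation near
pseudotime 0.6; the Kendall tau of 0.92 says the inferred ordering
almost matches the planted one, and the subsampling protocol shows the
ordering is stable (mean Spearman rho 0.999 over 50 draws of 90% of
the cells).  `res$embedding$Y` holds the 2-D coordinates for plotting,
and `run_pipeline(..., out_dir = "out")` writes `embedding.tsv`,
`pseudotime.tsv`, `branches.tsv`, `summary.tsv`, `config.json` and
`run.log`.

A thin command-line wrapper ships in `inst/scripts/difftraj`:

```sh
difftraj=$(Rscript -e 'cat(system.file("scripts","difftraj",package="difftraj"))')
Rscript "$difftraj" simulate --topology bifurcating --cells 300 --genes 50 --seed 1 --out sim
Rscript "$difftraj" run --input sim/matrix.tsv --labels sim/labels.tsv --out out
Rscript "$difftraj" evaluate --pseudotime out/pseudotime.tsv --truth sim/truth.tsv
```

Expression input can be TSV/CSV (cells in rows, header of gene ids,
first column of cell ids; `--transpose` if flipped) or Matrix Market
triplets with cell/gene companion files.

## Scope

The package consumes pre-processed matrices only (no QC, normalization
or count modelling), assumes tree-shaped (acyclic) trajectories, and
stores the dense `N × N` diffusion and kernel matrices, so memory and
time scale as O(N²).  See the vignette
(`vignettes/diffusion-pseudotime.Rmd`) for the model's assumptions,
parameter guidance and known limitations.
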