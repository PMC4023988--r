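# bicomm — dual-projection community detection in bipartite networks

`bicomm` detects the community structure of **both modes** of a bipartite
(two-mode) network — genes × samples, hosts × parasites, people ×
committees — and quantifies when the popular "combined" strategy fails.

Two pipelines share one detection backend (walktrap random-walk clustering,
walk length 4, modularity-maximizing dendrogram cut):

* **`detect_dual(graph)`** — the dual-projection strategy. Cluster the
  weighted one-mode projections `B Bᵀ` (shared-neighbor counts among mode-1
  nodes) and `Bᵀ B` (among mode-2 nodes) *separately*, then match the two
  community solutions across modes by maximizing Barber's bipartite
  modularity

  `Q_B = (1/m) Σᵢⱼ (B_ij − k_i d_j / m) δ(c_i, c_j)`,

  the bipartite analogue of Newman's Q (`m` edges, degrees `k_i`, `d_j`,
  δ fires when a cross-mode node pair shares a joint community label).
* **`detect_combined(graph)`** — the baseline. Cluster the block
  off-diagonal meta-matrix `[[0, B], [Bᵀ, 0]]` once and split the partition
  by mode.

When both modes carry the same number of communities the two strategies are
equally good; when the modes carry *different* numbers of communities the
combined strategy has to compromise between incompatible groupings and the
dual projection clearly outperforms it. The package ships the
planted-partition generators and the NMI simulation harness that establish
this, so the claim is reproducible end to end.

## Worked example

Generate a 60×120 planted benchmark with three mode-1 communities but only
two mode-2 communities (density 0.125, within-community tie probability
0.9), and run both pipelines:

```r
library(bicomm)

cfg <- scenario_config("unequal_3_2", "small", seed = 42)
gen <- generate_bipartite(cfg)
gen$graph
#> Bipartite graph: 60 x 120 nodes, 900 edges (density 0.125)

detect_dual(gen$graph)
#> Joint bipartite partition (dual): 3 mode-1 x 3 mode-2 communities, 3 joint; Q_B = 0.2361
detect_combined(gen$graph)
#> Joint bipartite partition (combined): 2 mode-1 x 3 mode-2 communities, 3 joint; Q_B = 0.2593

score_joint(gen$truth, detect_dual(gen$graph))      # node-weighted NMI vs truth
#> [1] 0.7732655
score_joint(gen$truth, detect_combined(gen$graph))
#> [1] 0.5185634
```

On this realization the dual projection recovers the planted three/two
structure much better (NMI 0.77 vs 0.52): the combined run found only two
mode-1 communities because the meta-matrix forces one compromise partition
across both modes. Averaging over replicates makes the gap systematic:

```r
sim <- run_simulation(cfg, reps = 50, base_seed = 1)
sim
#> Simulation: scenario unequal_3_2, 60 x 120, 50 replicates (base seed 1)
#>   combined mean NMI 0.599 +/- 0.105 sd  (n = 50)
#>   dual     mean NMI 0.840 +/- 0.092 sd  (n = 50)
```

`nmi()` is sqrt-normalized mutual information; `score_joint()` averages the
per-mode NMIs weighted by node counts. Scenarios: `equal_3_3`,
`unequal_3_2`, `unequal_2_10`, each with `"small"` (60×120) and `"large"`
(600×1200) presets. See the methods vignette
(`vignettes/dual-projection-methods.Rmd`) for the models, the matching
algorithm and the generator designs.

A command-line wrapper ships in `inst/cli/bicomm`:

```sh
bicomm generate --scenario unequal_3_2 --size small --seed 1 --output edges.tsv --truth truth.tsv
bicomm detect --input edges.tsv --method dual --output partition.tsv
bicomm simulate --scenario unequal_3_2 --size small --reps 100 --seed 1 --output results.csv
```

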