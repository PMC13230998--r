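# manifoldtopo

Topology-guided diagnostics for single-cell manifold inference under
heterogeneous observation depth, with a matching UMI-count simulator.

## The problem

Droplet-based scRNA-seq mixes deeply and shallowly observed cells: per-cell
total UMI counts commonly spread several-fold around a few thousand. Graph-based
manifold inference — normalization, highly-variable-gene (HVG) selection, PCA, a
kNN graph, Louvain clustering, and cluster-level connectivity by partition-based
graph abstraction (PAGA) — silently assumes uniformly informative observations.
Shallow cells violate that assumption collectively: they resemble each other
more than their own cell state, condense into spurious subclusters, and bridge
unrelated clusters in the abstraction graph. Viewing that graph as a
1-dimensional simplicial complex makes the damage quantifiable: spurious bridges
create independent loops, so the first Betti number
`beta1 = E − V + beta0` rises, whereas a faithful lineage abstraction is
tree-like (`beta1 ≈ 0`).

`manifoldtopo` is for computational biologists who want to (a) simulate
realistic heterogeneous-depth UMI data with ground-truth cell states, and (b)
measure when their graph-based analyses can be trusted.

## What it computes

**Simulator.** A cell state is a ranked gene-fraction vector over 36,601 gene
slots with ~10,000 expressed genes: raw molecule weights
`f_i = max(0, floor((i − 26301)/300)) + [i ≥ 36000]·exp((i − 36000)/75)`,
normalized to fractions `p`. Cells are multinomial draws of
`D ~ round(N(5000, 1500))` (clamped at 500) UMIs. Analytic expected
multiplicity spectra `E[N_k] = Σ_i P(X_i = k)` are available under Poisson
(`λ_i = D p_i`) and negative binomial (mean `D p_i`, dispersion θ) sampling.
Cell-state edits generate benchmark populations with ground truth: gene-identity
permutation (distinct types; population **X**), scaling 300 random genes by
2/0.5 or 1.67/0.6 (pathway activation; **Y**), and step-wise lineages with
repeated activation plus derepression of 10 silenced genes to 50 molecules
(**Z**: A → B → C → D/E).

**Diagnostics.** The standard workflow (log1p to 10k counts, 2,000
dispersion-selected HVGs, scaling clipped at 10, 30 PCs, kNN graph at 1% of
cells, Louvain at resolution 1), PAGA connectivity (reference-implementation
statistic, frozen by fixture tests), Betti numbers of the τ = 0.05-thresholded
abstraction, random-walk hit rates from low- to high-information cells (5 steps,
1,000 trials, with an exact matrix-power oracle), progressive-removal curves,
fixed-size subsample β1 distributions, and a hyperparameter sensitivity sweep.

## Worked example

```r
library(manifoldtopo)

# three "cell types" sharing one magnitude spectrum, heterogeneous depths
pop <- simulate_population_X(seed = 1, n_cells = c(Cell1 = 600, Cell2 = 300, Cell3 = 300))
pop
#> <cell_population X: 36601 genes x 1200 cells>
#>   states: Cell1=600, Cell2=300, Cell3=300
#>   depth: median 5041, range [500, 10798]

wf <- run_standard_workflow(pop, workflow_config(seed = 1))
wf
#> <manifold_workflow: 1200 cells, 30 PCs, k_nn = 12>
#>   clusters (6): 0=300, 1=300, 2=233, 3=159, 4=117, 5=91
```

Although X contains three states, Louvain splits `Cell1` (600 cells) into four
subclusters — the spurious substructure induced purely by depth heterogeneity.
The abstraction topology and the random-walk diagnostic quantify the picture:

```r
topo <- betti_numbers(compute_paga(wf), tau = 0.05)
topo
#> <topology_summary: V = 6, E = 3, beta0 = 3, beta1 = 0, tau = 0.05>

lab <- label_by_depth(pop, 5000)         # high-information: depth > 5000
ht  <- compute_hit_rate(wf, lab, k_walk = 5, trials = 1000, seed = 2)
spearman_hitrate_vs_depth(ht)
#> $rho      [1] 0.189519
#> $p_value  [1] 3.839139e-06
#> $n        [1] 586
```

Here β0 = 3 recovers the three true types (the subclusters of each type stay
connected), and the hit rate correlates positively with depth while spreading
widely at fixed depth — it measures proximity to the well-observed manifold,
not depth itself. The analytic spectrum behind the simulator:

```r
m <- build_fraction_model("combined")
expected_nk(m, "poisson", depth = 5000)
#> <expected_nk: poisson, D = 5000>
#>   k = 0..90; E[N_1] = 1590.594, E[N_2] = 248.424
#>   truncation: 5.98e-13 genes, 5.48e-11 UMIs beyond k_max
```

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
manifoldtopo simulate Z --seed 1 --out zdir            # 10x-style MTX + labels.tsv
manifoldtopo nk zdir --out nk.tsv                      # depth-binned mean N_k
manifoldtopo run zdir --seed 1 --out res               # clusters, PAGA edges, topology.json
manifoldtopo hitrate zdir --threshold 4000 --out hits  # hit rates + removal curve
manifoldtopo sweep zdir --threshold 4000 --out sweep   # beta1 distributions per setting
```

All subcommands accept `--seed`, `--config` (YAML), `--out`, and `--paga-tau`;
every output directory receives the resolved `run_config.yaml`.

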