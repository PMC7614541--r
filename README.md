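# neuroplex

Multiplex bilateral connectome analysis in R.

Synapse-resolution connectomes of insect brains resolve not just which
neurons connect, but *where*: each synapse joins an axon or a dendrite on
both sides, so the wiring diagram is really four directed graphs —
axo-dendritic (a-d), axo-axonic (a-a), dendro-dendritic (d-d) and
dendro-axonic (d-a) — over one shared neuron set, mirrored across two
hemispheres. `neuroplex` is for researchers analysing such data (or
prototyping methods for it): it implements the full chain from skeleton to
circuit statistics, and ships a synthetic bilateral-connectome generator
with planted ground truth so that every stage can be validated end to end
without any external dataset.

## What it implements

* **Compartment splitting** — synapse flow centrality: each tree edge of a
  neuronal arbor is scored by the number of presynapse→postsynapse tree
  paths crossing it; the maximal, synapse-free segment is the axon–dendrite
  linker and the split is placed at its soma-proximal end.
* **Multiplex construction & thresholding** — four-layer graphs from
  synapse tables; the bilateral reproducibility threshold retains an edge
  only when it exists in both hemispheres and its mean input fraction is
  ≥ 1% of the target's dendritic input.
* **Signal flow** — hierarchy scores minimizing
  `Σ w_ij (z_i − z_j − 1)²` (Laplacian pseudo-inverse), Spearman
  comparisons of per-layer sortings, feedforward/feedback edge fractions.
* **Signal cascades** — a modified independent-cascade model: every
  synapse transmits with probability p = 0.05 per hop, neurons activate at
  most once per run, stop nodes absorb; hop-resolved activation
  probabilities over (default) 1000 runs drive multimodality,
  lateralization, recurrence, cluster-level flow and efference-copy
  metrics.
* **Joint left–right clustering** — pass-to-ranks regularization,
  adjacency spectral embedding of the LL/RR/LR/RL subgraphs (d₁ = 24),
  Procrustes alignment, concatenation and re-embedding (d₂ = 10),
  homolog-pair averaging, then recursive 1-vs-2 component Gaussian-mixture
  splits under BIC (min group 32, max depth 8) giving a multiresolution
  cluster tree.
* **Homolog matching** — seeded FAQ graph matching (Frank–Wolfe on the
  relaxed quadratic assignment problem, compiled linear-assignment
  projection), multi-restart consensus `D = (1/S) Σ s_k D^k`, and
  neighbor-rank evaluation of candidate pairs.
* **Circuit metrics** — hubs (≥ 20 distinct partners, i.e. mean + 1.5 SD),
  sensory orders, local-neuron types 1/2, pathway enumeration,
  ipsi/bi/contralateral axon classes, bilateral partner cosine similarity,
  homolog pair/double/super loops, group connection probabilities, and
  DN→AN→DN zigzag motifs.
* **Reciprocity & overlap** — multigraph edge reciprocity
  `r = Σ A^src_ij A^tgt_ji / Σ A^src_ij` and the independent-layer null
  model `m(x) = n² Π_k p_k^{x_k} (1 − p_k)^{1 − x_k}` for connection-type
  overlap.

## Worked example

```r
library(neuroplex)

cfg <- generator_config(n_pairs = 100, n_unpaired = 10, n_hubs = 2,
                        n_recurrent_loops = 2, n_zigzags = 2, seed = 42)
g <- generate_connectome(cfg)
g$connectome
#> multiplex_connectome: 210 neurons
#>   ad    2802 edges,     7763 synapses
#>   aa    1051 edges,     2452 synapses
#>   dd     420 edges,     1006 synapses
#>   da     189 edges,      493 synapses
#>   excluded: self-loops = 0 , unclassified = 0
```

The four layers share 210 neurons (100 homolog pairs per hemisphere plus
10 unpaired); as configured, the a-d layer dominates and most edges are
weak. Threshold to strong bilateral connections and sort the hierarchy:

```r
thr <- symmetric_threshold(g$connectome, g$truth$pair_map)
thr
#> thresholded_graph (ad, >= 1% bilateral): 2726 of 2802 edges retained

sf <- signal_flow(g$connectome, type = "sum")
round(classify_edge_direction(g$connectome, sf, type = "ad")$synapse_fractions, 3)
#> feedforward    feedback         tie
#>        0.76        0.24        0.00
```

76% of a-d synapses point down the inferred input-to-output hierarchy,
reflecting the generator's feedforward bias of 0.8 minus what the planted
recurrent structure sends back. Propagate sensory signal with cascades and
cluster the pairs:

```r
inputs  <- with(g$connectome$meta, node_id[is_input])
outputs <- with(g$connectome$meta, node_id[is_output])
cas <- run_cascade(thr, cascade_spec(inputs, stop = outputs, p = 0.05,
                                     max_hops = 8, iterations = 1000, seed = 1))
sum(receives_signal(cas)[outputs])
#> [1] 16        # outputs visited in a strict majority of the 1000 runs

emb  <- joint_embedding(g$connectome, g$truth$pair_map, d1 = 16, d2 = 8)
tree <- recursive_gmm_cluster(emb)
tree
#> cluster_tree: 5 leaf clusters over 100 pairs (max depth 8 , min split size 32 )
```

Every left/right homolog pair receives one latent position, so both
members always land in the same cluster; `cut_tree(tree, depth)` exposes
coarser levels of the tree.

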