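---
title: "Methods: multiplex bilateral connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex bilateral connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroplex)
```

# Scope

`neuroplex` analyses synapse-resolution connectomes as *multiplex directed
networks*: one shared neuron set carrying four integer-weighted graphs, one
per connection type named by the presynaptic and postsynaptic compartment —
axo-dendritic (`ad`), axo-axonic (`aa`), dendro-dendritic (`dd`) and
dendro-axonic (`da`). The package covers the full analytical chain for a
bilaterally symmetric insect-style brain: compartment splitting, graph
construction, reproducibility thresholding, hierarchy sorting, stochastic
signal propagation, joint left–right clustering, homolog matching, and
circuit metrics. A synthetic generator with planted ground truth makes every
stage testable without external data.

# Axon/dendrite splitting: synapse flow centrality

In insect neurons, presynaptic and postsynaptic sites segregate into axon
and dendrite, separated by a synapse-free linker domain.
`synapse_flow_centrality()` scores each tree edge of a skeleton by the
number of (presynapse, postsynapse) node pairs whose unique tree path
crosses it; because paths in a tree are unique this equals, per edge, the
presynapse count on one side times the postsynapse count on the other,
summed over both orientations. The linker domain is the contiguous
maximal-centrality segment whose interior nodes carry no synapses, and the
split sits at its most proximal (soma-nearest) point; the recorded
`split_node` is the first axonal node distal to that point, so the dendrite
is always the compartment containing the soma.

Conventions where the procedure is underdetermined:

* If several disjoint segments attain the maximal centrality (multi-claw
  arbors), the segment closest to the soma is chosen, with node-id order as
  the final deterministic tie-break. This is a convention, not a biological
  claim.
* Neurons with no presynapses, no postsynapses, or no synapse-free linker
  are `unpolarized`; neurons with no synapses at all are `immature`.
  Neither receives a split.

The implementation computes subtree synapse counts in one linear sweep; the
test suite checks it against literal all-pairs path enumeration on random
trees up to 50 nodes.

# Graph construction and the bilateral threshold

`build_multiplex()` aggregates synapse records into the four layers over a
canonically sorted node set. Self-loops are excluded everywhere (the
reciprocity and overlap statistics assume loopless adjacencies) and
counted, as are records with missing compartment labels — nothing is
silently dropped.

Weak edges (1–2 synapses) are numerous but poorly reproducible between
hemispheres, so most analyses run on the *bilaterally thresholded* graph
(`symmetric_threshold()`): an edge is kept only if the homologous edge
exists on both sides and the mean of the two input fractions (edge weight
over the target's total in-weight in that layer) is at least 1%. A 0.5%
connection paired with a 2% connection averages 1.25% and passes — one
hemisphere can compensate for the other. Unpaired neurons cannot satisfy a
both-hemispheres rule; their edges are kept when their own fraction passes
the threshold. This exemption is our choice: it keeps the circuitry of
unpaired populations (e.g. Kenyon cells) analyzable rather than discarding
it wholesale.

# Multiplex edge statistics

`edge_reciprocity(A_src, A_tgt)` generalizes reciprocity to multigraphs: on
binarized, loopless adjacencies it is the conditional probability of a
reverse edge in the target layer given a forward edge in the source layer.
`expected_overlap_counts()` implements the independent-layer null model for
connection-type overlap: with per-layer densities $p_k = \sum_{ij} A^{(k)}_{ij} / n^2$,
the expected number of ordered pairs showing binary pattern $x$ over the
four types is $m(x) = n^2 \prod_{k=1}^4 p_k^{x_k} (1-p_k)^{1-x_k}$, which
sums to $n^2$ exactly. We keep the $n^2$ normalization of the formula even
though the layers are loopless (the diagonal contributes only to the
all-zero pattern); with $n$ in the thousands the $n^2$ versus $n(n-1)$
difference is far below the sampling noise of the counts.

# Signal flow: sorting the network from inputs to outputs

`signal_flow()` assigns each neuron a score $z_i$ minimizing
$\sum_{ij} w_{ij} (z_i - z_j - 1)^2$: every synapse prefers its presynaptic
neuron one level above its postsynaptic neuron, and the quadratic penalty
spreads violations smoothly. The minimizer solves $L z = b$ with $L$ the
Laplacian of $W + W^\top$ and $b$ the out-minus-in strength; we take the
minimum-norm solution through the pseudo-inverse and mean-center (the
objective is shift-invariant). On a directed chain this reproduces the
topological order with equal gaps. Edges with both directions present
contribute each direction independently. `classify_edge_direction()` calls
an edge feedforward when its source scores above its target, with a
$10^{-9}$ tolerance band reported as ties — exchangeable nodes receive
equal scores only up to numerical precision, and silently breaking such
ties by rounding error would be arbitrary. Group-level sorting uses mean
member scores.

# Signal cascades

`run_cascade()` implements a modified independent-cascade model. From a
start set active at hop 0, each synapse from an active non-stop neuron to a
never-activated neuron transmits independently with probability $p = 0.05$
per hop; a neuron with at least one successful upstream transmission
activates at the next hop, and active neurons then deactivate for the rest
of the run, so each neuron activates at most once per run and hop-resolved
activation frequencies are well defined. Stop neurons (typically the brain
output neurons) can be activated but never propagate. Defaults: 1000
iterations, up to 8 hops (5 when restricting to pathway depths with
confirmed functional connectivity).

Numerical choices:

* Per-edge transmission is drawn as one Bernoulli event of probability
  $1-(1-p)^w$ for weight $w$ — mathematically identical to $w$ independent
  per-synapse trials, and it lets each hop be one vectorized draw.
* Per-iteration seeds are derived from the master seed up front, so results
  are bit-reproducible and iterations are independent.
* "Receives the signal" means visited in a strict majority of iterations
  (`visit_probability > 0.5`); exactly half does not qualify. Visits are
  counted at any hop.

Derived metrics reuse the same machinery: `modality_integration()` labels
neurons unimodal/multimodal by which per-modality cascades reach them;
`lateralization()` compares left-seeded and right-seeded cascades;
`recurrence_fraction()` seeds a cascade at each neuron, takes its
downstream partners, and asks which of them send signal back within the
same hop budget (default 5), also counting the number of distinct return
path lengths; `cluster_flow_matrix()` tracks forward (toward outputs) and
backward signal between clusters ordered by mean signal flow; and
`efference_copy_reach()` splits the brain partners of output neurons into
recurrent (also upstream of the same output) versus parallel, using
deterministic $\le$ 2-hop reachability.

# Joint left–right embedding and clustering

To cluster neurons so that homologs land together, the connectome is split
into the LL, RR, LR and RL subgraphs with rows and columns aligned by
homolog pair. Each subgraph is regularized by pass-to-ranks (nonzero
weights replaced by average-tie ranks scaled into $(0,1]$ — order
preserving, tames the heavy-tailed weight distribution), then embedded by
the adjacency spectral embedding (truncated SVD with out- and in-positions
scaled by the square root of the singular values; the diagonal is augmented
with row-degree/$n$ to stabilize sparse spectra). The right hemisphere's
positions are aligned to the left's by orthogonal Procrustes over the pair
correspondence — spectral embeddings are identifiable only up to an
orthogonal transform. Each node's four position blocks (ipsilateral out/in,
contralateral out/in; $d_1 = 24$ each) are concatenated, reduced to
$d_2 = 10$ by a second SVD, and the left and right rows of each pair are
averaged, so clustering assigns homologs identically by construction.
Because known pairs provide the row correspondence, plain seeded Procrustes
suffices and no soft-correspondence refinement is used.

`recursive_gmm_cluster()` then splits recursively: at each node it fits 1-
and 2-component Gaussian mixtures and splits when BIC prefers two
components, the group has at least 32 members, and depth 8 is not
exceeded; BIC ties within $10^{-6}$ resolve to no split. The covariance
structure is itself selected by BIC within each component count. We chose
this over a fixed unconstrained covariance deliberately: with groups of
100–200 points in 10 dimensions a 2-component full-covariance model
carries 131 free parameters, and BIC then rejects splits that are plainly
present (or, when forced, fits a spurious one), while the BIC-selected
constrained models recover them cleanly. mclust's model-based hierarchical
initialization makes every fit deterministic; degenerate fits are retried
under a conjugate prior. The tree is multiresolution: `cut_tree()` exposes
coarser partitions, and a planted hierarchy should be evaluated at its own
granularity, since the recursion legitimately continues into real
substructure (laterality classes, feedforward depth gradients) below the
planted blocks.

`cluster_morphology_score()` consumes an externally computed pairwise
morphological similarity matrix (e.g. NBLAST output; the algorithm itself
is out of scope): scores are symmetrized by the geometric mean of the
$(i,j)$ and $(j,i)$ entries, rank-normalized into $[0,1]$, averaged within
clusters and then across hemispheres; chance level is 0.5 by construction
of the rank normalization.

# Homolog matching

`seeded_graph_match()` aligns the two hemispheres' adjacencies by
Frank–Wolfe ascent on the relaxed quadratic assignment objective (matched
edge agreement, equivalently minimizing the norm of the difference of
permuted adjacencies), with known pairs clamped as seeds. Each of the
(default 50) restarts starts from a random convex combination of the
barycenter and a random permutation; the step size comes from exact line
search on the quadratic; convergence is declared at step displacement
below $10^{-6}$ or 30 iterations; the final doubly stochastic iterate is
projected to a permutation by linear assignment (a compiled
shortest-augmenting-path solver). `match_consensus()` averages the runs'
doubly stochastic solutions weighted by their objective values, and
`neighbor_ranks()` scores known pairs by the rank (average ties) of the
true partner in the consensus row — rank 1 means the matcher's top
candidate is the true homolog. For unseeded evaluation runs the
configuration of 20 restarts and 30 iterations is used. Unequal
hemispheres are padded with isolated dummy nodes that are stripped from all
reports.

# Circuit metrics

All classifications are deterministic functions of the thresholded graph
and metadata:

* **Hubs**: in-/out-/in-out by distinct-partner degree with inclusive
  thresholds; the canonical threshold of 20 corresponds to the network
  mean plus 1.5 SD on a full-brain a-d graph and
  `degree_threshold_from_stats()` rederives it for any network.
* **Sensory orders**: breadth-first hop strata per input modality; a
  neuron's overall order is 1 + its minimum hop over modalities, direct
  input targets being 2nd order. Neurons whose only input is of unknown
  modality can be excluded from categorization.
* **Local neurons**: type 1 sends a strict output majority into its own
  sensory layer or the layer directly upstream (same modality); type 2
  has strict input *and* output majorities into one layer it does not
  belong to; remaining 2nd-order neurons are projection neurons by
  exclusion.
* **Pathways**: all simple directed paths from inputs to outputs within 6
  hops, with exact totals and uniform subsampling above a cap.
* **Laterality**: neurons are ipsilateral/bilateral/contralateral by the
  fraction of presynaptic sites targeting the opposite hemisphere; the
  0.2/0.8 cutoffs are configurable conventions (the empirical distribution
  is strongly trimodal, so results are insensitive to the exact values).
* **Bilateral partner similarity**: cosine of the ipsilateral and
  contralateral output vectors indexed by homolog-pair identity.
* **Homolog loops**: reciprocally connected homolog pairs; pair loops
  linked by inter-pair edges form double (2) and super ($\ge$ 3) loops.
* **Zigzag motifs**: descending → ascending → different descending neuron,
  optionally with one intermediate per leg (3–5 node variants); reciprocal
  DN–AN loops are searched separately and never counted as zigzags.

# The synthetic generator

`generate_connectome()` draws a bilateral multiplex connectome from a
stochastic block model with planted ground truth. What it emulates:
mirrored hemispheres of homolog pairs (plus optionally unpaired neurons),
four overlapping layers with geometric (mostly weight-1–2) integer weights
truncated at a maximum, a two-level hierarchical block structure, an
input-to-output feedforward gradient, per-neuron axon laterality with an
ipsilateral/bilateral/contralateral split defaulting to 61/24/15, mirror
noise (an edge present on one side only), and planted hubs, recurrent
loops and zigzag motifs registered in the returned ground truth. Defaults:
weak-edge fraction 0.66, within-block connection probability 0.25, sibling
blocks 0.10, background 0.02, feedforward bias 0.8, mirror noise 0.05.
All randomness flows from one master seed; a fixed seed reproduces the
connectome byte for byte.

What it does **not** emulate — and therefore what passing tests do and do
not show: cross-layer dependence (real a-d and d-a edges are strongly
reciprocal; the generator's layers are sampled independently, so multiplex
reciprocity statistics on synthetic data sit near the independence
baseline), degree heavy-tails beyond the planted hubs, spatial or
morphological structure, neuron-intrinsic properties, and any tuning to a
real connectome's parameters. Tests on this generator validate the
*implementations* — calibration against closed forms, exact agreement with
brute-force oracles, recovery of planted structure — not claims about real
brains.

# Problem sizes

The validation suite runs cascade calibrations at $10^4$ iterations on toy
graphs, oracle comparisons on graphs of up to 50 nodes, clustering recovery
on 400-pair (800-neuron) bilateral SBMs over 10 seeds, and matching
recovery on 150-pair hemispheres with 10% seeds — sizes at which the
planted structure is unambiguous while the full suite completes in a few
minutes on one core. The same machinery scales to brains of a few thousand
neurons: the heaviest steps are the SVDs ($O(n^3)$ dense) and the per-run
linear assignment in matching.

# Known limitations

* The cascade model is unsigned: it treats excitatory and inhibitory
  synapses alike as opportunities to perturb downstream activity.
* The signal-flow solver densifies the adjacency; for networks far beyond
  $10^4$ nodes an iterative solver would be preferable.
* Graph matching is connectivity-only; no morphological evidence enters
  the objective, and the manual review loop used in practice around such
  matchers is out of scope.
* The fine-grained type count produced by the cluster tree is data- and
  granularity-dependent and should not be read as an estimate of a true
  number of types.
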