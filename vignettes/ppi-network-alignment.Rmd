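---
title: "Aligning PPI networks with feature vectors and simulated annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning PPI networks with feature vectors and simulated annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppialign)
library(dplyr)
```

# The problem

Given protein–protein interaction (PPI) networks of two or more species, a
*global network alignment* partitions (a subset of) the proteins into
mutually disjoint **matchsets** — groups of proteins from at least two
networks hypothesized to be functionally conserved. A good alignment covers
many proteins (sensitivity) while keeping each matchset functionally
coherent (specificity); the two pull against each other.

`ppialign` scores every cross-network protein pair by blending sequence
similarity from BLAST with a topological similarity built on graph feature
vectors, and then searches for the set of candidate match edges whose
induced matchsets maximise the total score, using simulated annealing.
Because matchsets are connected components of the selected edges, the same
machinery performs pairwise and multiple alignment, and matchsets may hold
several proteins per network (multiple-to-multiple maps).

# The scoring model

## Sequence similarity

All-against-all BLASTP hits (consumed in the standard 12-column tabular
format; running BLAST itself is upstream of this package) are filtered by an
e-value cutoff and reduced to a candidate set $\Omega$ of cross-network
pairs. Each pair gets a raw score $\varepsilon$ — by default the bit score;
alternatively $-\log_{10}$ of the e-value — and a min–max normalised
similarity

$$s_h(u,v) = \frac{\varepsilon(u,v) - \varepsilon_{\min}}{\varepsilon_{\max} - \varepsilon_{\min}},$$

so the most similar pair in $\Omega$ scores 1 and the least similar 0.
Pairs outside $\Omega$ have $s_h = 0$. Two conventions are worth noting:

* the log-e-value mode uses $-\log_{10}$ (not a raw logarithm), so that a
  larger $\varepsilon$ always means *more* similar in both modes and the
  formula's stated range convention holds; e-values of 0 are clamped to
  $10^{-180}$ first;
* normalisation is global over $\Omega$ (one $\Delta\varepsilon$ across all
  network pairs), which keeps the map order-preserving and matches the
  single normalisation factor in the formula.

## Topological similarity

Every node $v$ of a network carries a 5-tuple feature vector
$(\gamma, \sigma, \tau, \eta, \theta)$:

* $\gamma$ — the node's **reputation**: its entry in the leading (Perron)
  eigenvector of the adjacency matrix, rescaled so the maximum entry is 1;
* $\sigma = |N_v|$ — the degree;
* $\tau = \sum_{x \in N_v} \gamma_x$ — the reputation mass of the
  neighbours;
* $\eta = |N_v^2|$ — the number of nodes at distance exactly 2;
* $\theta = \tfrac12 \sum_{x \in N_v^2} \gamma_x \, p_{xv}$, where $p_{xv}$
  is the number of length-2 shortest paths from $x$ to $v$ (equivalently the
  number of common neighbours).

Each coordinate is then normalised by its maximum over the nodes of *its
own* network, and the similarity of two nodes from different networks is the
Gaussian kernel $s_t(u,v) = \exp(-x^2/2)$ on the Euclidean distance $x$
between their normalised vectors: 1 for identical local structure, bounded
below by $e^{-5/2} \approx 0.082$.

On the bundled five-node example pair of isomorphic networks the pipeline
reproduces the hand-calculated tuples:

```{r fig-example}
g1 <- example_networks()$G1
node_features(g1) |> mutate(across(where(is.numeric), round, 2))
```

## The target function

With blending weight $\alpha \in [0,1]$ (default 0.5), a matchset $m$ scores

$$s_m = \sum_{\{i,j\} \subseteq m} \alpha\, s_h(i,j) + (1-\alpha)\, s_t(i,j)$$

over all unordered distinct pairs, and an alignment scores
$f(\mathcal A) = \sum_{m \in \mathcal A} s_m$. The sum runs over *every*
pair inside a matchset, including same-network pairs created transitively —
$s_h$ defaults to 0 there and $s_t$ is always defined — so $f$ depends only
on the partition into components, not on which particular edges were
selected.

# The optimizer

Starting from the empty alignment, the annealer repeatedly perturbs the set
of selected candidate edges and accepts a perturbation with the Metropolis
rule $P(\Delta f) = e^{\Delta f / (T_i \cdot s)}$ (worsening moves only;
improvements are always accepted), under geometric cooling
$T_i = T_0 c^i$.

Several details of this scheme are design choices of this package, made
where the method description leaves them open:

* **Move set.** Add a random unselected edge (probability 0.45), remove a
  random selected edge (0.45), or swap one for one atomically (0.10);
  infeasible draws fall back to the feasible type. The mixture makes every
  subset reachable from every other (ergodicity) while the swap move lets
  the search escape merged components quickly.
* **Schedule.** $T_0 = 1$, $c = 0.9$, 1,000 moves per level, 100 levels,
  early stop after 10 levels without improvement of the best score — a
  practical reading of "anneal until the score converges".
* **The constant $s$.** The Metropolis denominator's scaling constant is
  set to the mean combined candidate score, making acceptance rates
  insensitive to the score scale; it can be overridden.
* **Matchset-size cap.** Because every pair score is positive, the
  unconstrained optimum of $f$ merges all touching candidates into large
  components. The optional `max_matchset_size` cap rejects moves that would
  exceed it. The default leaves size unbounded (multiple-to-multiple maps
  are part of the method); for ortholog recovery between $k$ networks a cap
  of $k$ is the natural operating point, and the recovery experiments below
  use `max_matchset_size = 2` with two networks.
* **Incremental scoring.** Since $f$ depends only on the component
  partition, the score change of a move is the sum of cross-component pair
  scores gained by a merge or lost by a split; edges within an already
  connected component change nothing. The inner loop runs in compiled code
  but draws all randomness from R's RNG, so a fixed seed reproduces the
  trajectory bit-for-bit.

An exhaustive subset enumeration (`brute_force_optimum()`, up to 20
candidate edges) provides an independent optimum for validation; the test
suite checks that annealing with a slow schedule attains it on dozens of
random 12-edge instances.

# Evaluation

**Coverage** is the percentage of all input proteins appearing in some
matchset. **Consistency** is measured on Gene Ontology annotations (GAF
2.x): pooling the term occurrences of a matchset (with multiplicity across
proteins, all three aspects by default) with proportions $p_i$ over $d$
distinct terms,

$$E(m) = -\sum_i p_i \ln p_i, \qquad NE(m) = \frac{E(m)}{\ln d},$$

and ME / MNE are the arithmetic means over matchsets where the quantity is
defined ($E$ needs at least one annotated protein; $NE$ needs $d \ge 2$;
skipped matchsets are counted in the report). Lower values mean more
functionally coherent matchsets. Natural logarithms are used throughout —
$NE$ is base-independent, $E$ is reported in nats. Note the entropy carries
the conventional minus sign so that $E \ge 0$ and "lower is better" holds.
Terms are compared as flat identifiers; annotations are not propagated
through the ontology graph, which tends to make entropies conservative for
shallow versus deep term usage.

# The synthetic-data generator

Real benchmarks require IntAct network exports, BLASTP runs and GOA
snapshots; the generator replaces them with instances whose ground truth is
known exactly:

* a **seed network** — Erdős–Rényi with configurable mean degree (default
  100 nodes, mean degree 6), or a duplication–divergence process for
  heavier-tailed, more PPI-like degree distributions;
* $k$ **noisy copies** with relabelled nodes, each edge deleted with
  probability `p_del` (default 0.05) and `p_add * |E|` random non-edges
  inserted (default 0.05), with a truth map from every derived node to its
  ancestor;
* a **homology table** in BLAST tabular layout: true-ortholog pairs draw
  bit scores from $N(200, 20^2)$, background pairs (at 0.2 per true pair)
  from $N(60, 15^2)$, both truncated at 30 bits — separable but
  overlapping, as declared distributions, not estimates from real BLAST
  output;
* **annotations** with controllable purity $\pi$: each ortholog group draws
  a family GO term, and each member is annotated with it with probability
  $\pi$ (default 0.8), otherwise with a uniform vocabulary term, so
  expected ME decreases monotonically in $\pi$.

What passing tests on such data show — and do not show: the generator
validates the machinery (score bookkeeping, optimizer convergence,
ground-truth recovery under noise, entropy behaviour under purity), but its
networks lack the size, degree heterogeneity, ascertainment bias and
annotation sparsity of real interactomes, so recovery rates on it do not
forecast coverage or consistency on real data.

# Numerical choices and degenerate inputs

* **Power iteration.** The leading eigenvector is computed per connected
  component by power iteration on the shifted matrix $A + I$ (identical
  eigenvectors; the shift makes the Perron eigenvalue strictly dominant even
  on bipartite components, where plain iteration oscillates), from the
  all-ones vector, to an $\infty$-norm tolerance of $10^{-10}$ and at most
  10,000 iterations, then max-rescaled per component.
* **Disconnected networks.** The whole-matrix leading eigenvector would
  zero out all but one component; computing per component keeps every
  protein's reputation informative. Singleton or edgeless components get
  $\gamma = 1$.
* **Degenerate spreads.** If all raw sequence scores coincide
  ($\Delta\varepsilon = 0$, including a one-pair $\Omega$), every pair gets
  $s_h = 1$. A coordinate whose per-network maximum is 0 normalises to 0.
* **Ties and determinism.** Candidate edges are ordered lexicographically
  by protein ids; generators, the annealer and the file writers are
  deterministic under a fixed seed.
* **Score verification.** Alignment scores carried incrementally are
  checked against full recomputation to $10^{-9}$ in the test suite.

# Problem sizes used in the validation suite

The bundled tests run the worked five-node example exactly; optimizer
validation uses 50 random instances of 12 candidate edges against the
exhaustive optimum with a slow schedule ($T_0=1$, $c=0.95$, 200 moves per
level, 60 levels); ground-truth recovery uses a 100-node seed with two 5%
noisy copies, averaged over 5 seeds. These sizes exercise every code path
while keeping the default check quick; all scale up linearly in candidate
count through the compiled kernel.

# Known limitations

* The objective rewards node similarity only; edge conservation (conserved
  interactions inside matchsets) is not part of $f$ and is not reported.
* Without a matchset-size cap the optimum tends toward large merged
  matchsets; choose `max_matchset_size` deliberately when one-to-one-like
  maps are wanted.
* Cross-file protein identity is exact string match; no identifier mapping
  between databases is attempted.
* GO terms are flat ids; no semantic similarity or ontology traversal.
* The annealing schedule constants are package defaults, not values
  recovered from any published tool; results depend on them only through
  convergence speed, and the early-stop rule makes the defaults forgiving.
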