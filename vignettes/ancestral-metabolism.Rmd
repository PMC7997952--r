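---
title: "Reconstructing an ancestral metabolic core: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing an ancestral metabolic core: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ancestornet implements the inference machinery needed to characterize the
last common ancestor of a bacterial domain from comparative genomic data:
which gene families trace to the ancestor, what metabolic network those
families encode, how close that network comes to producing the universally
essential metabolites, and which modern lineages sit closest to the root of
the gene trees. This vignette explains the models behind each stage, the
parameters that matter, and the choices we made where the design was
genuinely open.

```{r setup}
library(ancestornet)
library(dplyr)
```

## From sequences to conserved families

The unit of analysis is the protein family. Families are built from a
pairwise global-identity graph: an edge between two sequences survives when
its global identity is at least 25% and its e-value at most 1e-10
(`build_similarity_graph()`, both thresholds inclusive and configurable),
weighted by identity. Families are the clusters of this graph under Markov
clustering (`mcl_cluster()`): the edge weights are turned into a
column-stochastic random-walk matrix, and expansion (matrix squaring)
alternates with inflation (entrywise power, then renormalization) until the
matrix stops changing; clusters are the connected components of the
converged attractor matrix.

Two MCL details are not dictated by the algorithm and are our choices:

* **Inflation defaults to 2.0**, the long-standing MCL default, and is the
  single knob that controls cluster granularity.
* **Self-loops** are added before normalization with weight equal to each
  node's maximum incident edge weight (1 for isolated nodes). Loops damp the
  period-2 oscillations of bipartite-ish walks; tying the loop weight to the
  local edge scale keeps the walk's self-affinity comparable to its
  strongest neighbour affinity across heterogeneous identity ranges.

Genomes enter the analysis only if they look anaerobic — no hit against an
oxygen/nitric-oxide reductase reference set with identity above 25%,
e-value below 1e-10 and at least 300 aligned residues
(`select_anaerobes()`; these three thresholds are strict inequalities,
whereas the family-graph thresholds above are inclusive — both read
literally from their sources) — and if they carry more than 1000 proteins,
which excludes energy parasites with massively reduced genomes. Genomes are
then binned into major taxonomic groups (`assign_groups()`): the two
hugely over-represented phyla are split into classes, phyla with fewer
than 5 species are pooled into a residual "Other Bacteria" bin, and the
rest keep their phylum label.

A family is *universal* when it has at least one member in every group
(`universal_families()`). Mean coverage is the unweighted mean over groups
of the within-group genome fraction; we average fractions over groups
rather than pooling genomes so that a small group counts as much as a large
one — pooling would let the dominant classes mask absence elsewhere.
Functional annotation (`annotate_families()`) is majority vote over the
members' best hits (lowest e-value, ties by coverage, then identity, then
subject id — the last tie-break is ours, added for determinism), with
frequency ties reported as multi-category annotations rather than broken
arbitrarily.

## The bipartite metabolic network

Reactions are parsed from KEGG-style equations (`parse_reactions()`).
Equations with symbolic coefficients (`n`, `m`), malformed tokens, or the
same compound on both sides with equal coefficient (transport-like, no net
chemistry) are rejected with a reason rather than silently repaired;
polymer-style equations can be admitted with `allow_transport = TRUE`.
Reversibility comes from a lookup table, and any reaction absent from the
table is irreversible — the conservative default for reactions never seen
in a pathway map. A reversible reaction is stored once with a flag, not
duplicated, which keeps identifiers stable; every consumer of the network
treats both directions.

`build_reaction_network()` assembles the directed bipartite
metabolite–reaction graph. Degree and connectivity questions ("is this
reaction disconnected from the rest of the core?") are answered on the
undirected simplified skeleton, because connectivity claims about such
networks are claims about association, not flux direction.

## Network expansion and the minimal completing set

The *scope* of a seed set (`compute_scope()`) is the least fixed point of
firing every reaction whose substrates are all already producible
(either side for reversible reactions). The result is order-independent,
monotone in both seeds and reactions, and idempotent — properties the test
suite asserts against a brute-force fixed-point oracle.

Whether a target metabolite counts as producible has two readings, and the
package implements both (`producible_targets()`):

* `produced_by_any` (default): some reaction in the network makes it.
* `scope_from_seeds`: it lies in the scope of a seed set.

We default to `produced_by_any` because a conserved-core network
reconstructed from universal families is typically *not* self-generating
from nutrients — it is a fragment of a larger metabolism, and demanding
full reachability from external seeds would conflate missing transporters
with missing chemistry. For scope mode, the default seed set
(`default_seeds()`) is the network's external inputs: compounds consumed
but never produced.

`reduce_network()` finds a small set of non-core reactions completing the
targets: candidates are visited in increasing order of taxonomic
distribution score (`score_reactions()`; widely distributed reactions are
more credible in an ancestor, so poorly distributed ones are offered up
for removal first), each is removed if all targets stay producible, and
full passes repeat until nothing changes. Ties in the score are broken by
reaction id for determinism; the source procedure is silent on ties.
The retained set is *1-minimal* — no single retained candidate can be
dropped — and this is verified post hoc on every result. It is not a
globally minimum set cover (that problem is NP-hard); the greedy,
score-ordered contract is the method, and the exhaustive optimum is used
only as a test oracle on small planted universes. The stopping rule
"no further reaction can be removed" is implemented as repeated full
passes; with the default producibility notion one pass suffices, but the
re-checking matters under scope-based producibility where earlier removals
change reachability. The meaning of "violating the core network" during
removal is not fully pinned down by the procedure's description; we read
it as "core reactions are never candidates" (always true here), with an
optional stricter reading — removals must not fragment the components
containing core reactions — behind `strict_core = TRUE`.

## Rooting gene trees by minimal ancestor deviation

For a candidate root position on a branch, every leaf pair has an induced
ancestor; under a strict clock the ancestor is equidistant from both
leaves, so `|2 d(anc, i)/d(i, j) - 1|` measures the relative departure
from clocklike behaviour. The MAD score of a candidate root is the
root-mean-square of this deviation over all leaf pairs, and `mad_root()`
minimizes it: for pairs spanning the candidate branch the optimal position
has a closed-form minimizer (a clamped quadratic minimum); pairs on one
side contribute position-independent terms through their fixed ancestor.

Numerical and edge-case choices:

* Leaf pairs at zero path distance are skipped (denominator guard) and the
  pair count reduced accordingly; zero-length terminal branches are legal.
* A tree whose branches are all zero is rejected as degenerate.
* Multifurcations are accepted as hard polytomies; candidate roots live
  only on existing branches.
* The root is *ambiguous* when a second branch ties the minimum within a
  relative tolerance (`tie_tol = 1e-6`); the ambiguity index is the ratio
  of best to second-best score. Ambiguous trees are dropped from
  downstream analyses (`filter_ambiguous()`) — a tree that cannot commit
  to a root cannot vote on root-adjacent questions.

Root-to-tip divergence (`root_to_tip()`) is measured two ways: summed
branch lengths (phenetic distance) and node depth. Node depth counts
branching events on the root-to-leaf path including the root's initial
split, so a direct child of the root has depth 1; the alternative
convention (excluding the split) differs by a constant that does not
survive per-tree normalization exactly, so the convention is documented
rather than configurable. Distances are normalized by the per-tree maximum
into [0, 1], which makes trees with different rates comparable; each
group's per-tree score is its *least diverged* genome, the member closest
to the root.

Sister diversity (`sister_diversity()`) asks, for each group, how
phylogenetically diverse the neighbourhood of its pure (single-group)
clades is: old lineages accumulate diverse sisters, and lateral transfer
relocates lineages without erasing that signal. For each maximal pure
clade the distinct *other* groups in its sister clade are counted and the
group takes the maximum. Counting only other groups is deliberate: a
maximal pure clade's sister always contains at least one foreign group
(otherwise the parent clade would itself be pure), so the score is
guaranteed to lie in [1, G-1] for G groups — matching the stated range of
the statistic when 25 groups yield scores in [1, 24].

## Ancestral root states under F81

`f81_root_posterior()` estimates the root state of a discrete trait under
the F81 model: exchange toward equilibrium frequencies at a uniform rate,
with transition probability `P(i→j, t) = π_j + (δ_ij − π_j) e^(−βt)` and
`β = 1/(1 − Σπ²)`. Conditional likelihoods propagate by the standard
post-order pruning recursion; unknown tips contribute vectors of ones; the
root posterior is the normalized product of `π` with the root conditional
likelihood. Frequencies default to the empirical tip-state frequencies
pooled across the tree — the only information the tree itself offers —
with uniform or user-supplied alternatives. If the frequency vector is
degenerate (all mass on one state) the posterior is that point mass and
the rate is undefined; the function short-circuits rather than divides by
zero.

The prediction rule approximates marginal-posterior state selection: the
argmax is the prediction (ties kept as ties), and states within a factor 2
of the maximum are co-reported. The exact state-set selection rule used by
dedicated ancestral-reconstruction software optimizes a Brier-type
criterion; since downstream aggregation (`aggregate_root_states()`, modal
state across trees) consumes only the prediction, the simpler rule is
sufficient here and is stated as an approximation.

## Statistics

`wilcoxon_one_sided()` is the paired one-sided signed-rank test of
`H1: D_a < D_b`. Zero differences are dropped (the original convention for
this test), absolute differences are ranked with midranks, and the null
distribution of the positive-rank sum is enumerated exactly over all 2^n
sign assignments when n ≤ 12 — 4096 cases, instant, and exact even under
ties — otherwise a normal approximation with tie correction and continuity
correction is used. The two branches agree within 0.01 at the switch
point, which the suite checks. `pairwise_divergence_tests()` runs both
directions for every group pair over their shared trees (the matrix is
asymmetric by design), applies a Bonferroni multiplier equal to the number
of unordered pairs tested, and marks pairs with no shared trees as missing
rather than dropping groups. The residual "Other Bacteria" bin is excluded
by default: it is a taxonomic catch-all, not a lineage, and with it a
25-group analysis yields the 24×24 matrix and C(24,2) = 276 tested pairs
this analysis is known by. `ks_two_sample()` computes the exact two-sample
KS statistic (ECDF supremum over the pooled sample) with the asymptotic
Kolmogorov p-value at effective size `n_x n_y/(n_x + n_y)`.

## What the synthetic world emulates — and what it does not

All inputs can be generated with planted ground truth:

* `synthetic_world()` builds an ultrametric species history of unit depth:
  a designated basal group attaches directly at the root, the remaining
  groups radiate on a random coalescent backbone hanging from a stem
  (depths 0.3 within groups, 0.45 backbone, 0.25 stem). The stem is what
  makes "earliest-diverging" a well-posed planted truth: without it the
  deepest backbone split would compete with the root itself. Defaults —
  8 groups of 3 genomes — are a desk-scale caricature of a
  many-phyla dataset.
* `simulate_gene_trees()` derives gene trees by per-genome loss
  (`loss_prob = 0.1`), lateral transfers as topology-only prune-regraft
  moves at Poisson rate `lgt_rate = 0.05` per branch (the transferred leaf
  adopts the recipient's divergence time — enough to decouple gene trees
  from the species history, which is the property the analyses exploit),
  and multiplicative lognormal branch noise (`rate_noise_sd = 0.3`,
  i.e. roughly ±35% rate variation). These rates are our choices of a
  plausible moderate regime; nothing downstream is calibrated to them.
* `simulate_similarity_graph()`, `simulate_presence_matrix()` and
  `simulate_reaction_universe()` plant, respectively, a partition, a
  universal family set, and a unique minimal completing reaction set. The
  reaction universe defaults mirror the scale of a conserved-core
  analysis — 57 targets, 48 producible by a 121-reaction core chain, a
  9-reaction completing set — with a desk-scale candidate pool of 40.

The generators are pure functions of their parameters and seed, and every
artifact round-trips through the package's TSV/Newick writers and readers.

What passing the planted-recovery tests shows is that the machinery is
correct and has power in a regime where the truth is known. It does not
show that real data are this kind: real similarity graphs have overlapping
domains and promiscuous paralogs, real gene trees have reconstruction
error correlated across families, real LGT is biased toward neighbours
and highways rather than uniform donor–recipient pairs, and real
reaction universes contain alternative routes that make the minimal
completing set non-unique. Sequence-level simulation and realistic
substitution models are deliberately out of scope.

One asymmetry deserves a note. Under an ultrametric history with
multiplicative branch noise, branch-length root-to-tip distances carry no
basal signal in expectation — a clock makes all tips equidistant, noise or
not. The node-depth metric does carry it (the basal clade sits next to the
root, so its path to the root crosses fewer splits). Planted-basal
recovery is therefore assessed on node depth; on real, non-clocklike data
both metrics are informative, which is exactly why both are implemented.

## Validation scale and known limitations

The test suite validates each analytical core against an independent
oracle: MAD against a 1000-position-per-branch grid search on 100 random
8-taxon trees (and exactness on clocklike trees); scope against
brute-force fixed points on 200 random 20-reaction networks; the greedy
reduction against exhaustive subset search on 100 planted universes of up
to 15 candidates; the signed-rank test against full sign-assignment
enumeration and a 10,000-replicate null calibration; KS against the
brute-force ECDF supremum; F81 pruning against exhaustive state summation
on up-to-4-tip trees; and basal-group recovery over 100 transfer-free
worlds of 200 gene trees each. These sizes were chosen so the full suite
runs comfortably on a laptop while leaving the oracles exhaustive where
exhaustiveness is the point.

Known limitations: MAD rooting is quadratic in leaves per branch and
intended for the many-small-trees regime, not thousand-taxon trees; the
reduction is 1-minimal, not globally minimal; F81 assumes a single uniform
rate (no rate heterogeneity across sites or states); and the pairwise test
matrix treats trees as exchangeable paired observations, ignoring
phylogenetic correlation between gene families — the standard caveat for
across-tree vote-counting analyses.
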