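---
title: "Weighted mutual information for link prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted mutual information for link prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmilink)
```

## The problem and the data model

An undirected weighted network G(V, E, W) is observed; some links are
missing (unrecorded interactions, future connections). A link predictor
assigns every unlinked pair (x, y) a score s_xy and bets on the top of the
ranking. `wmilink` implements purely *local* predictors: s_xy depends only
on the common neighbours O_xy = Γ(x) ∩ Γ(y), their link weights, and
per-node summaries. Locality is the central assumption — nothing beyond
two hops is consulted, which is what makes these indices essentially free
to compute but also blind to long-range structure.

The graph model (`wgraph`) is deliberately strict: simple, undirected,
every weight finite and strictly positive. Zero weights are rejected at
the boundary rather than treated as absent links, because the weak-tie
exponent α raises weights to arbitrary real powers and 0^α is undefined
or infinite for α ≤ 0. Node identifiers are opaque strings; Pajek files
are mapped from 1-indexed integers to labels on read and back on write.

## The score families

Three classical indices and their weighted extensions share one template:
a per-neighbour kernel divided by a per-neighbour normaliser.

* WCN_α sums W_xz^α + W_zy^α over z ∈ O_xy.
* WAA_α divides each term by log(1 + S_z).
* WRA_α divides by S_z, with S_z = Σ_{z′∈Γ(z)} W_zz′^α.

At α = 0 every kernel term equals 2, so the weighted scores are exactly
twice the unweighted CN = |O_xy|, AA = Σ 1/log(1 + d_z), RA = Σ 1/d_z;
the package defines its unweighted indices as that α = 0 limit divided by
two, which matches the textbook CN and leaves every ranking unchanged.
The test suite asserts rank equality, not value equality, for this
degeneracy.

The mutual-information score treats "pair (x, y) is linked" as an event
L¹ and asks how much each common neighbour z reduces its surprisal:

I(L¹; z) = I(L¹) − I(L¹ | z) = −log(M^T/M) + log C_z,

with M = |V|(|V|−1)/2, M^T the number of training links, and C_z the
clustering coefficient of z in its pair form: among the d_z(d_z−1)/2
unordered pairs of z's neighbours, the fraction N_△z/(N_△z + N_∧z) that
are themselves linked. Contributions of distinct common neighbours are
summed, i.e. treated as independent — the second modelling assumption,
shared with naive-Bayes-style predictors. The WMI family multiplies each
I(L¹; z) by the corresponding weight kernel f(W_xz, W_zy) of WCN/WAA/WRA,
so structure decides *how informative* z is and weights decide *how
strongly* z couples to the candidate pair.

Counts are a property of z alone: they are computed once per training
graph, over all pairs of z's neighbours, and are not adjusted for the
pair currently being scored (the scored pair is itself one of the
disconnected pairs in N_∧z). This keeps the context reusable across all
candidates and matches the definition of C_z as a node attribute.

## Tunable parameters

* **α (weak-tie exponent)**, any finite real, default 1. α < 1 boosts
  weak ties, α > 1 strong ties, α = 0 ignores weights. The sign of the
  optimal α is a property of the *network*, not the index: it reflects
  whether weights encode affinity or dissimilarity.
* **L (predicted-set size)**, default 100, and **probe fraction**,
  default 0.1: the standard protocol. Precision is bounded by
  |probe|/L, and `evaluate_index()` warns when the bound binds.
* **smoothing** for C_z: `"laplace"` (default) uses
  (N_△z + 1)/(N_△z + N_∧z + 2); `"raw"` the bare ratio.
* **log_base**, default 2 (scores in bits). All scores within one
  configuration share the factor 1/ln(base), so rankings — and therefore
  precision — are provably base-invariant; the acceptance tests verify
  this under bases 2, e and 10. Presentation only.
* **plain_strength**: see the ambiguity note below.

## Numerical choices and degenerate inputs

**C_z = 0 under raw smoothing.** A common neighbour none of whose
neighbour pairs are linked has log C_z = −∞, which would veto the whole
pair. The default Laplace smoothing removes the singularity. Under
`smoothing = "raw"` the −∞ is mapped to a finite sentinel of −10⁹ (score
units): affected pairs rank below every finite-scored pair, exactly as an
infinite penalty would order them, while keeping the sparse-matrix
scoring path free of 0·∞ = NaN artefacts. The sentinel is visible in
per-neighbour decompositions; treat such scores as "vetoed", not as
numbers.

**Tie-breaking.** Integer-valued indices such as CN produce large groups
of exactly tied candidates. `rank_candidates()` permutes each tie group
uniformly at random under the run's seeded RNG; a lexicographic rule
would systematically favour some node labels and bias precision. With
paired seeds, rankings that are equal up to within-tie order produce
*identical* precision — this is what makes the α = 0 column of a weighted
sweep agree exactly with the unweighted index.

**S_z in the parameterised WMI-WAA/WRA denominators.** The definition
attached to the parameterised WCN/WAA/WRA family raises the strength to
α as well; the parameterised WMI variants are typeset with a plain S_z.
Both readings coincide at α = 1. The package defaults to the α-powered
strength everywhere, for internal consistency of the family, and offers
`plain_strength = TRUE` to reproduce the literal plain-strength reading.
The two options are tested to agree at α = 1.

**Candidate universe.** All non-edges of the *training* graph over the
full node set: probe links are candidates (they are what we hope to
recover), and nodes isolated by the split stay in V, so M is a constant
of the node set.

**Validation protocol.** `select_alpha_validated()` picks α̂ on a
validation slice using the 80% training graph, then by default re-fuses
training + validation links into a 90% graph before scoring the test
slice (`refit = FALSE` keeps the bare 80% graph). Re-fusing mirrors the
two-way protocol's 90% training information and is the default because
the final measurement should use everything that is legitimately known.

**Determinism.** Every stochastic operation is a pure function of an
integer seed; subsidiary seeds for splits and tie permutations are drawn
from the master seed and recorded in the result object, and the RNG state
of the caller is always restored. Sweeps evaluate every grid point on
identical splits with identical tie permutations (paired design), which
removes split noise from comparisons between α values; independent-runs
averaging is recovered by giving each run its own seed stream. Exact ties
in a sweep's argmax are resolved toward the smallest |α|, then the
smallest α.

## The synthetic generator

`generate_weighted_network()` emulates the one mechanism the weak-tie
story depends on: a *planted correlation between link weight and endpoint
structural similarity*. An unweighted backbone (small-world ring lattice
with rewiring 0.1 by default; preferential-attachment and Erdős–Rényi
alternatives) supplies clustering; each link then gets weight
exp(β·cn(i,j) + ε), with cn(i,j) the backbone common-neighbour count of
its endpoints, ε ~ N(0, noise_sd), and β = +0.5, −0.5 or 0 for the
positive, negative and iid modes. The exponential link keeps weights
positive for any noise draw; β = 0.5 makes the planted signal clearly
dominate noise_sd = 0.3 on a backbone whose cn values span roughly 0–6,
while leaving realistic overlap between weight levels. The correlation is
planted on the full backbone before any train/probe split, because it is
meant to be a property of the ground-truth network.

Positive mode imitates affinity weights (synapse counts, co-occurrence
frequencies): strong ties are informative and the optimal α should be
positive. Negative mode imitates dissimilarity weights (distances,
detour-like traffic): the optimal α should fall below 1, typically below
0. The acceptance suite checks exactly these sign patterns over 10
generator seeds, plus a paired comparison showing that in positive mode
using the weights (α = 1) does not hurt relative to CN.

What the generator does *not* emulate: heavy-tailed weight
distributions, degree–weight correlations, community structure, and the
idiosyncrasies of any real network. Passing the synthetic checks
therefore demonstrates that the machinery recovers a planted weak-tie
regime, not that any particular real network is in one.

## Problem sizes used in the shipped checks

The stochastic checks run on networks of n = 300 nodes at mean degree 8
(1200 links, 44 850 candidate pairs), with 5 paired splits per grid point
on a 21-point α grid from −2 to 3 in steps of 0.25, L = 100, and 10
generator seeds; the validation-protocol comparison uses the same grid on
six index families. These sizes give stable sign patterns and an RMSD
comparison with comfortable margin while keeping a full run in tens of
seconds. The API accepts the much finer grid −5…5 in steps of 0.01 when a
precise α* is wanted; a coarse-then-fine refinement is the practical
compromise.

## Known limitations

* Local indices ignore everything beyond two hops; on low-clustering
  networks all CN-based scores (including MI) discriminate poorly, and
  the weight fusion is then doing most of the work.
* The independence assumption across common neighbours double-counts
  information when neighbours are themselves densely interlinked.
* The MI context is rebuilt per split rather than updated incrementally;
  at desk scale (10³–10⁴ nodes) this is negligible, but the package makes
  no claim about 10⁶-node graphs.
* Only precision@L is implemented, by design; AUC-style evaluation and
  weight prediction for the recovered links are out of scope.
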