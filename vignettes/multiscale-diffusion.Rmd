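---
title: "Diffusion profiles on a multiscale interactome: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion profiles on a multiscale interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package represents drug treatment on a heterogeneous network
G = (V, E) with four node kinds: drugs, diseases, proteins, and a
hierarchy of biological functions. Drugs attach to the proteins they
target, diseases to the proteins they disrupt, proteins interact
physically with each other and annotate to functions, and functions
form a directed child-to-parent hierarchy from specific to general
terms. The kind set is open — additional kinds (anatomical entities,
cell types) can be declared at assembly time with their permitted edge
pairs — but no loader for such ontologies ships.

The central object is the **diffusion profile** r of a focal drug or
disease: the stationary visitation-frequency vector of a biased random
walk with restart started at the focal node. Before walking, the graph
is converted to a directed view in which the focal node is a source (no
in-edges) and every other drug and disease is a sink (no out-edges), so
walks never use drugs or diseases as intermediates — a drug does not
propagate its effect through another drug. Proteins and functions keep
all incident edges in both directions.

At a node i, the walker first chooses among the *types* t of adjacent
nodes with probability proportional to scalar weights w_t, then
uniformly among the n_t neighbors of the chosen type:

    p(i -> j of type t) = ( w_t / sum_{t' adjacent to i} w_{t'} ) / n_t.

Function neighbors of a function node are split into *higher-level*
(parent) and *lower-level* (child) types with their own weights, so the
walker can learn to prefer ascending or descending the hierarchy. With
continuation probability alpha the walker steps through this transition
matrix M; with probability 1 - alpha it restarts at the focal node.
Mass reaching a sink is returned through the restart vector:

    r(k+1) = (1 - alpha) s + alpha ( r(k) M + s * sum_{j in sinks} r_j(k) ).

Every iterate sums to one. The fixed point is found by power iteration
from the uniform vector, stopping when the L1 change drops below eps.

## Parameters and defaults

* **Type weights** (dimensionless, only ratios matter):
  `w_drug = 3.21`, `w_disease = 3.54`, `w_protein = 4.40`,
  `w_biological_function = 6.58`, `w_higher_level_function = 2.10`,
  `w_lower_level_function = 4.49`. These are the optimized multiscale
  values; `make_weight_grid()` reproduces the sweep ranges
  (w_drug, w_disease, w_protein in [3, 9]; the two hierarchy weights in
  [1.5, 4.5]; `w_biological_function = w_higher + w_lower` by
  convention).
* **alpha = 0.860**: probability of continuing the walk. Smaller alpha
  concentrates the profile near the focal node; alpha -> 0 collapses it
  onto the restart vector.
* **eps = 1e-6**: L1 convergence tolerance of the power iteration.
* **max_iter = 10000**: an explicit cap guarding non-convergence; the
  iteration itself always converges geometrically for alpha < 1, so the
  cap only fires on misuse.

## Numerical choices

* Initialization is uniform (1/|V|) and convergence is measured in L1,
  matching the power-iteration formulation; metadata on the returned
  profile records the iteration count and final residual.
* Double precision throughout, with a sparse row-stochastic transition
  matrix (`Matrix::dgCMatrix`); the iteration multiplies by the stored
  transpose so each step is O(edges).
* Nodes unreachable from the focal node have exactly zero visitation at
  the fixed point, but the uniform initialization leaves a geometrically
  decaying residue on them at any finite iteration. The power path
  therefore zeroes the unreachable set after convergence and
  renormalizes. The dense linear-solve oracle
  (`exact_profile_oracle()`), which replaces sink rows by the restart
  vector and solves r = (1 - alpha) s (I - alpha M')^-1, produces the
  exact zeros by construction and is the reference the iteration is
  tested against.
* Nodes whose out-degree drops to zero only because of the directed-view
  construction (a protein whose sole neighbor is the focal drug) are
  treated as members of the sink set, since the sink-redistribution term
  is defined over all nodes without out-edges.
* Profiles are memoized per (graph, weights, alpha, focal) within a
  session (`options(msinteractome.cache = FALSE)` disables this); the
  cache key uses an opaque per-graph token, so any graph-modifying
  operation invalidates it by producing a new token.
* Ranking ties are broken by lexicographic drug id, and the degenerate
  correlation case (a zero-variance profile) is assigned the maximal
  correlation distance 2, i.e. score -2, with a message.

## Treatment prediction and evaluation

Seven comparison metrics are implemented (L2, L1, Canberra, cosine,
correlation distance, and the two proximity readouts r_d[drug] and
r_d[drug] * r_c[disease]); distances are negated so larger is always
more treatment-like. Raw visitation frequencies are compared; rank
transformation is used only in the expression-concordance analysis.

Cross-validation splits *drugs* into five folds. For each fold, every
disease ranks exactly that fold's drugs, with approved pairs as
positives and all other fold drugs as negatives (no negative sampling).
The alternative — letting held-out diseases rank the full drug
inventory — is defensible but mixes training drugs into held-out
candidate sets, so we restrict to the fold. Per-disease AUROC uses the
rank formulation with ties averaged; Recall@50 keeps its fixed cutoff
regardless of candidate-set size (with fewer than 50 candidates every
positive is trivially recovered, a degenerate case worth remembering on
small fixtures). Reported aggregates are the median AUROC, mean average
precision and mean Recall@50 across diseases, averaged over folds.

The sweep grid samples each weight axis at 3 evenly spaced points and
alpha at 2, giving 3^5 x 2 = 486 configurations over the standard
ranges; the published budget fixes the total but not the per-axis
resolution, so this layout is the package's own choice, and other
budgets truncate or subsample the cross-product under a fixed seed.
Model selection maximizes the median *training* AUROC averaged across
folds, crossed with the seven metrics.

## Baselines

* **Network proximity** uses the closest-distance statistic (mean over
  targets of the minimum shortest-path length to a disease protein) on
  the protein-protein layer only, z-scored against 1000 degree-matched
  permutations of both sets. Degree matching draws each replacement
  from log2-spaced degree bins merged upward until every bin holds at
  least 100 nodes; on desk-scale fixtures the floor must be lowered
  (the functions expose `min_bin_size`). Targets unreachable from every
  disease protein are dropped from the mean with a warning rather than
  poisoning it with infinities; a zero-spread null is flagged degenerate
  instead of producing an infinite z.
* **Functional overlap** compares term collections built from the
  annotation corpus: closure sets (a term counts if a protein is
  annotated to it or any descendant), multisets of per-protein closure
  counts, and enriched sets (one-sided hypergeometric over-representation
  against the annotated background, Benjamini-Hochberg FDR < 0.05 — the
  published analysis delegates this step to an external tool without
  stating settings, so these are the package's own). Jaccard and raw
  intersection variants exist for each, with z-scored versions built on
  the same degree-matched permutations. The published count of 17
  functional baselines is not itemized term-by-term; the package exposes
  all combinations (6 raw overlap, 4 z-scored overlap forms,
  Resnik and simIC under three aggregations each, and simGIC) and
  documents rather than asserts the enumeration.
* **Semantic similarity** uses natural-log information content
  IC(u) = -log p(u), where p(u) is the fraction of *annotated* proteins
  associated with u or its descendants. Using annotated proteins as the
  denominator makes p = 1 at a root ancestral to all used terms, the
  convention under which Resnik similarity vanishes at the root; a
  whole-proteome denominator would only shift all ICs by a constant.
  The log base rescales Resnik values and cancels inside the simIC and
  simGIC ratios. Terms with no common ancestor have similarity 0.

## Explanation and pharmacogenomics

Treatment-explanation subgraphs take the k = 10 most visited nodes of
each profile (ties broken by node id), always include the two focal
nodes, induce the subgraph and drop isolated nodes; the share of
visitation mass covered by the retained nodes is reported, not
asserted. Treatment importance of a gene is the product of its
protein's visitation frequencies in the two profiles, with a mid-rank
percentile (fraction of strictly smaller values plus half the ties,
scaled to [0, 1]) over all protein nodes of the same pair; published
importance values near 0.9 are on this percentile scale, since raw
visitation products are orders of magnitude below 1. In the
altered-versus-unaltered drug comparison ties count as failures (strict
inequality), and because the printed summary is ambiguous about whether
it aggregates over genes or over triplets, both aggregations are
returned. Expression signatures are compared by the mean Jaccard
overlap of the top-25 up- and down-regulated gene sets, restricted to
signatures with identical cell line, dose and exposure time, and the
concordance with (rank-transformed, negated-Canberra) profile
similarity is summarized by a Spearman correlation.

## The synthetic generator

`synthetic_spec()` describes a miniature interactome whose default
(seed 0) is the fixture used throughout the tests: 4 protein modules of
25 proteins (5 of them satellites), wired as a stochastic block model
(p_in = 0.15, p_out = 0.01) with power-law degree propensities inside
blocks so degree-matched sampling is exercised nontrivially; a 7-node
function tree per module under a common root; 8 diseases attached to 8
core proteins of their module; and 20 drugs, half *molecular* (targets
drawn from their disease's proteins) and half *functional* (targets are
satellite proteins annotated to the module's function subtree but
attached, sparsely, to a different protein block). Approved pairs are
exactly the same-module (drug, disease) combinations; treatment-altering
genes are planted on drug targets; signatures are noisy transforms of
rank-transformed drug profiles.

This plants the central qualitative claim at desk scale: with function
nodes present, a functional drug's profile overlaps its disease's
profile through the shared subtree; removing function nodes leaves the
two profiles nearly disjoint in the protein layer, so molecular-scale
ranking of functional-route treatments collapses toward chance while
multiscale ranking does not. The default sizes complete the full
pipeline — profiles for all drugs and diseases, cross-validation for
both network scales, the permutation baselines and the
pharmacogenomic analyses — in well under a minute, which is why they
were chosen.

What the generator does **not** emulate: the real network's degree
sequence and size (hundreds of nodes versus tens of thousands), the
topology and annotation depth of the real Gene Ontology, incomplete and
biased curation of targets and disease genes, and treatments whose
mechanism is neither a shared protein nor a shared function subtree.
Passing tests on the fixture therefore demonstrate correctness of the
machinery and recoverability of a cleanly planted signal, not
real-data performance; published full-network figures (held-out AUROC
0.705 versus 0.620, and related numbers) require the released network
files and are checked only when those files are present.

## Known limitations

* The loader keeps identifiers verbatim and performs no ontology-id
  normalization; inputs are assumed pre-harmonized, and pruning of
  functions unreachable from any drug target or disease protein is an
  explicit, optional step (`prune_functions()`) because released
  hierarchy files may or may not already reflect it.
* Hierarchy relation types (is-a, part-of, regulates, ...) are collapsed
  to a single child-to-parent orientation.
* The dense oracle is guarded to 2000 nodes; there is no full-network
  closed-form solver.
* Genes are identified with their protein nodes; no isoform handling.
* Expression-signature ingestion is a plain (gene, z) table with a
  metadata sidecar; upstream quality control of public signature
  resources is out of scope.
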