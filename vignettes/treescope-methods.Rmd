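---
title: "treescope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treescope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treescope)
```

# Scope

`treescope` is a toolkit for *annotated hierarchical trees*: reading and
writing newick/NHX, manipulating and rooting trees, interpreting gene trees
phylogenetically (orthology/paralogy via species overlap and via
reconciliation against a species tree, with gene-loss inference and relative
duplication dating), validating cluster trees with silhouette and Dunn
indexes, and rendering trees as ASCII art or rule-driven SVG.

This vignette documents the model assumptions, the algorithms, the default
parameters and the numerical conventions, so that results are reproducible
without reading the source.

# The tree model

A tree is a mutable recursive structure of `tree_node` objects (R
environments). Each node has `name`, `dist` (branch length to its parent),
`support`, an ordered `children` list, an optional `parent` reference, and an
open-ended `features` map for annotations. Defaults for missing numeric
fields are `dist = 1.0`, `support = 1.0` (`tree_defaults()`); rationale: a
neutral multiplicative unit that keeps topology-only files usable with
distance functions.

All traversals (`traverse()` with `preorder`, `postorder`, `levelorder`) are
iterative with explicit stacks/queues, so depth is bounded by memory, not by
R's recursion limit; trees with hundreds of thousands of nodes (e.g. the
NCBI taxonomy scale, ~450,000 nodes) parse, serialize and traverse in pure R
in well under ten minutes on one CPU.

# Newick and NHX input/output

Four writing dialects are registered (`newick_dialects()`):

* `FULL` (id 0): leaf names, branch lengths, internal labels.
* `LEAF_NAMES_LENGTHS` (id 1): leaf names and branch lengths only.
* `TOPOLOGY_ONLY` (id 2): leaf names only.
* `FLEXIBLE` (id 3): parse-only, non-strict; malformed numeric fields fall
  back to defaults instead of raising.

Two conventions deserve a note:

* **Internal label slot.** Plain newick has a single label slot per internal
  node but two competing uses (name vs. bootstrap support). `treescope`
  writes the node *name when non-empty, else the support*; on parsing, a
  bare number in an internal label is interpreted as support. Consequence:
  leaf support values are not serialized — they are not a round-trippable
  quantity in any of the plain-newick dialects.
* **NHX annotations.** Features are exported on request
  (`write_newick(..., include_features =)`) as `[&&NHX:key=value:...]`
  blocks. Keys may not contain `: = [ ]`, values may not contain `: [ ]`;
  duplicate keys on input resolve to the last occurrence (with a warning).

Numbers are written with `%.15g`, which preserves doubles to well below the
package-wide round-trip tolerance of 1e-9.

Names containing reserved characters (`( ) , : ; [ ]` or whitespace) raise
on write unless `auto_quote = TRUE` (single-quoted labels, `''` escapes
embedded quotes); silent quoting is avoided because it changes what
downstream consumers see.

# Rooting

`set_outgroup(root, outgroup, split)` reroots by reversing the parent chain
above the outgroup and inserting a new binary root on the outgroup's edge,
transferring support values along reversed edges and collapsing the old root
if it becomes unary. `split` controls where on the edge the root lands
(default: the midpoint of that edge). Multifurcating (unrooted-style) roots
are supported.

`midpoint_outgroup(root)` locates the tree diameter (the longest
leaf-to-leaf path, computed from the full pairwise leaf distance matrix,
with the lexicographically first pair used to break ties) and walks to the
edge containing the diameter's midpoint. The exact within-edge offset is
stored on the returned node as the feature `"outgroup_split"`, which
`set_outgroup()` consumes — so midpoint rooting balances the two diameter
endpoints to floating-point accuracy rather than to the nearest edge
midpoint.

Rerooting is a relabeling of the same unrooted tree: all pairwise leaf
path-length distances are invariant (verified to 1e-9 in the test suite).

# Orthology and paralogy inference

Leaves acquire a `"species"` feature via `assign_species(tree, rule)`; the
default rule takes the first three characters of the leaf name (a common
gene-naming convention), and any function of the name can be supplied.

## Species overlap

`species_overlap_events(tree, threshold = 0)` needs no species tree. For
each internal node the overlap score is `|I| / |U|`, where `I` and `U` are
the intersection and union of the children's species sets (global
intersection over global union for multifurcations). The node is a
*duplication* when the score is strictly greater than `threshold`, else a
*speciation*. The default `threshold = 0` means "any shared species implies
duplication", the standard species-overlap rule; raising it makes the caller
trade sensitivity for precision. Scores and event types are stored as node
features (`"overlap_score"`, `"event"`).

## Reconciliation

`reconcile(gene_tree, species_tree)` implements strict LCA-map
reconciliation for binary trees. Each gene node `v` maps to `M(v)`, the
species-tree LCA of its species set. `v` is a duplication iff `M(v) = M(c)`
for at least one child `c`. Losses are counted per child edge from the
species-tree depths: `depth(M(c)) − depth(M(v)) − 1` skipped lineages for a
speciation, one more (no `−1`) for a duplication, because under a
duplication both child lineages start at `M(v)` itself. Each inferred loss
is materialized in the returned copy of the gene tree as a ghost leaf named
`LOSS_<species>` with features `evoltype = "L"` and `"species"`; the
pre-defined phylogenetic layout draws these branches dashed grey.
`remove_loss_leaves()` restores the plain gene tree.

On the normative example — gene tree `(HSA_a,(HSA_b,MMU_b));` against
species tree `(HSA,MMU);` — this yields exactly 1 duplication and 1 loss
(the missing MMU copy of the `HSA_a` lineage).

The two inference methods are validated against each other: on loss-free
gene trees produced by `simulate_gene_tree()` (which duplicates random
subtrees by sibling-grafting, so ground truth is known and no losses exist),
ground truth, species overlap at threshold 0, and reconciliation identify
identical duplication node sets.

## Dating and monophyly

`date_duplication(node, ladder)` assigns a relative age rank: the smallest
index (0-based) in a reference species ladder (`species_ladder()`, the
nested leaf sets along a seed species' root path) that covers the species
under the node. Only the order of ranks is meaningful.
`check_monophyly()` classifies a set of attribute values as monophyletic,
paraphyletic (intruders form a single clade) or polyphyletic.
`ortholog_pairs()` converts a list of events into the pair list: leaf pairs
whose LCA is a speciation are orthologs, duplications give paralogs; each
unordered pair is emitted exactly once (from the event at its LCA).

# Cluster-tree validation

Profile matrices (items × conditions, `NA` = missing) attach to dendrogram
leaves via `link_profiles()`. Distances (`profile_distance()`) are
`euclidean`, `pearson` (1 − r) or `spearman` (1 − ρ), computed over
pairwise-complete columns; two profiles sharing no column is an error.

`silhouette_index(node)` treats the subtree as one cluster: for member `i`,
`a(i)` is the mean distance to the other members, `b(i)` the mean distance
to **all** linked leaves outside the subtree, and
`s(i) = (b − a)/max(a, b)` (0 for singletons). The node silhouette is the
mean `s(i)`. Using the whole root-complement as the outside set (rather
than a "nearest other cluster") is a deliberate choice: a dendrogram node
has no canonical neighboring cluster, and the complement makes the index a
pure function of the partition the node induces.

`dunn_index(clusters)` is the minimum single-linkage inter-cluster distance
divided by the maximum cluster diameter; an all-zero-diameter partition is
degenerate and raises rather than returning an arbitrary value.

Both indexes are verified to 1e-12 against independent brute-force oracles
built on `stats::dist`/`stats::cor` over synthetic fixtures from
`generate_profiles()` (Gaussian clusters spaced `separation` apart along the
first column, `noise_sd` noise, ground-truth dendrogram attached). With
`noise_sd = 0` every ground-truth cluster has silhouette exactly 1.

# Rendering

`render_svg(root, layout)` is rule-driven: the layout function maps each
node to a `node_style()` (shape, size, colors, dashed/solid, visibility)
plus a list of faces (`text_face`, `sequence_face`, `bar_face`,
`heatmap_face`, `image_face`) positioned at the branch or in an aligned
column right of the deepest leaf. Coordinates: leaves top-to-bottom in
traversal order (`row_height` px apart), x proportional to root-path length
(`ultrametric = TRUE` right-aligns leaves for dendrograms). All numbers are
formatted with two decimals, so output is byte-deterministic; rendering
never mutates the tree.

Pre-defined layouts encode the standard semantics: `phylo_layout` draws
duplications as blue circles (`#0000ff`), speciations as red circles
(`#ff0000`), losses as dashed grey branches (`#808080`), and aligned
sequence strips for leaves with linked alignments (`link_alignment()`,
FASTA via Biostrings); `cluster_layout` draws leaf profiles as heatmap rows
and node silhouettes as bubbles — green positive, red negative, area ∝
|silhouette|, hidden at 0.

# Worked example

```{r}
g <- parse_newick("((HSA_1,MMU_1),(HSA_2,(MMU_2,DME_1)));")
assign_species(g)
s <- parse_newick("((HSA,MMU),DME);")
r <- reconcile(g, s)
r
vapply(r$events, function(e) e$etype, character(1))
head(ortholog_pairs(r$events))
cat(ascii_art(remove_loss_leaves(clone_node(r$reconciled_tree))))
```

```{r}
set.seed(1)
gp <- generate_profiles(3, 5, 8, separation = 8, noise_sd = 1, seed = 11)
validate_clusters(gp$tree)[, c("n_leaves", "silhouette", "intra_distance")]
dunn_index(gp$clusters)
```

# Open design decisions

* The dialect registry ids (0–3) are package conventions; other tools
  number their newick flavors differently.
* The internal-label slot rule (name wins over support) and the resulting
  non-serialization of leaf supports.
* Loss counting uses the per-edge depth-difference convention described
  above; alternative conventions (e.g. counting the duplication's root edge
  differently) exist in the literature.
* The silhouette outside set is the root-complement, not a nearest-cluster
  set; `dunn_index` is the single-linkage variant.
* `simulate_gene_tree()` and `generate_profiles()` are synthetic-data
  generators for validation; they make no claim of biological realism
  (Yule-like topologies, Gaussian profiles).

Problem sizes exercised in the shipped tests: trees up to 450,000 nodes,
100,000-leaf caterpillars, 200-tree round-trip batteries, 100-tree oracle
batteries, and 50 random clustering fixtures of up to 100 items × 10
columns.
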