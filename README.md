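# treescope

Programmable analysis of **annotated hierarchical trees** in R: newick/NHX
input/output, tree manipulation and rooting, phylogeny-aware
orthology/paralogy inference (species overlap and gene-tree/species-tree
reconciliation with gene-loss inference and relative duplication dating),
cluster-tree validation (silhouette and Dunn indexes), and rule-driven
rendering to ASCII art or standalone SVG.

The central type is a mutable `tree_node` (name, branch length `dist`,
`support`, ordered children, parent, and an open `features` annotation map).
All traversals are iterative, so trees at the scale of whole taxonomies
(450,000+ nodes) parse, serialize and traverse in pure R.

## The scientific problem

Trees are the lingua franca of comparative genomics and clustering, but the
biology lives in the *annotations* and in operations that interpret them:

* **Orthology/paralogy.** Two genes are orthologs if their last common
  ancestor in the gene tree is a *speciation*, paralogs if it is a
  *duplication*. `treescope` labels internal nodes by two standard methods:

  * *Species overlap*: node `v` with children subtrees carrying species sets
    `S1, S2, …` is a duplication iff `|∩ Si| / |∪ Si| > t` (default
    threshold `t = 0`: any shared species). No species tree required.
  * *Strict reconciliation*: with the LCA map `M` sending each gene node to
    the species-tree LCA of its species, `v` is a duplication iff
    `M(v) = M(c)` for some child `c`. Losses per child edge are counted from
    species-tree depths — `depth(M(c)) − depth(M(v)) − 1` for a speciation,
    one more for a duplication — and materialized as ghost leaves
    (`evoltype = "L"`, drawn dashed grey).

* **Relative duplication dating** by topology scanning: the age rank of a
  duplication is the smallest index in a reference species ladder (nested
  leaf sets along a seed species' root path) covering its species set.

* **Cluster validation.** With expression profiles linked to dendrogram
  leaves, a node's silhouette is `mean((b_i − a_i) / max(a_i, b_i))` where
  `a_i` is a member's mean distance to the rest of the cluster and `b_i` its
  mean distance to all leaves outside the subtree; the Dunn index of a
  partition is the minimum single-linkage inter-cluster distance over the
  maximum cluster diameter. Metrics: euclidean, 1−Pearson, 1−Spearman,
  with pairwise-complete handling of missing values.

* **Midpoint rooting** places the root exactly at the midpoint of the tree
  diameter (the split position is carried as a node feature, so the two
  diameter endpoints are equidistant from the root to floating-point
  accuracy, not merely to the nearest edge).

## Worked example

```r
library(treescope)

g <- parse_newick("((HSA_1,MMU_1),(HSA_2,(MMU_2,DME_1)));")
assign_species(g)                 # default rule: first 3 characters
s <- parse_newick("((HSA,MMU),DME);")

r <- reconcile(g, s)
r
#> <reconciliation: 2 duplications, 4 losses, 4 events>
vapply(r$events, function(e) e$etype, character(1))
#> [1] "speciation"  "speciation"  "duplication" "duplication"

head(ortholog_pairs(r$events), 4)
#>   leaf1 leaf2     type
#> 1 HSA_1 MMU_1 ortholog
#> 2 DME_1 MMU_2 ortholog
#> 3 HSA_2 MMU_2  paralog
#> 4 DME_1 HSA_2  paralog
```

The species-overlap method, which has no loss model, is more parsimonious on
the same tree — a real methodological difference, not a bug:

```r
ev <- species_overlap_events(g)
vapply(ev, function(e) sprintf("%s (%.2f)", e$etype, e$overlap_score), "")
#> [1] "speciation (0.00)"  "speciation (0.00)"  "speciation (0.00)"
#> [4] "duplication (0.67)"
```

Cluster validation on a synthetic fixture (3 Gaussian clusters of 5 items,
8 conditions, centers 8 apart, unit noise):

```r
gp <- generate_profiles(3, 5, 8, separation = 8, noise_sd = 1, seed = 11)
head(validate_clusters(gp$tree)[, c("n_leaves", "silhouette")], 3)
#>   n_leaves silhouette
#> 1       10      0.338
#> 2        5      0.677
#> 3        4      0.645
dunn_index(gp$clusters)
#> [1] 1.008776
```

Rendering and text display:

```r
cat(ascii_art(g))
#>    /- /-HSA_1
#> --|   \-MMU_1
#>    \- /-HSA_2
#>       \- /-MMU_2
#>          \-DME_1
svg <- render_svg(r$reconciled_tree, layout = phylo_layout)
# blue circles = duplications, red = speciations, dashed grey = losses
```

A command-line interface ships in `inst/exec/treescope`
(`convert`, `stats`, `root`, `prune`, `random`, `view`, `events`,
`orthologs`, `validate`); run it without arguments for usage.

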