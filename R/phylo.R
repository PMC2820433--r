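#' Assign species codes to leaves
#'
#' Phylogenetic analyses treat leaves as OTUs belonging to a species. The
#' species code of each leaf is derived from its name: by default the first
#' three characters (a common convention for sequence identifiers like
#' `HSA001`), or by any user-supplied `name -> code` function. The code is
#' stored as the leaf feature `"species"`; internal nodes report the union of
#' their descendants' species via [get_species()].
#'
#' @param tree A tree whose leaves all have non-empty names.
#' @param rule A function mapping a leaf name to a species code. Default:
#'   `substr(name, 1, 3)`.
#' @return The tree, invisibly.
#' @examples
#' t <- parse_newick("((HSA001,MMU001),DME001);")
#' assign_species(t)
#' get_species(t)
#' @export
assign_species <- function(tree, rule = NULL) {
  if (is.null(rule)) rule <- function(name) substr(name, 1L, 3L)
  for (lf in leaves(tree)) {
    if (!nzchar(lf$name)) stop("leaf without a name; cannot assign species")
    code <- rule(lf$name)
    if (!is.character(code) || length(code) != 1L || !nzchar(code))
      stop("species rule returned an empty code for leaf '", lf$name, "'")
    set_feature(lf, "species", code)
  }
  invisible(tree)
}

#' Species set under a node
#'
#' @param node A `tree_node` whose leaves carry the `"species"` feature.
#' @return Character vector of unique species codes (sorted).
#' @export
get_species <- function(node) {
  sp <- vapply(leaves(node), function(lf) {
    s <- lf$features[["species"]]
    if (is.null(s)) stop("leaf '", lf$name, "' has no species assigned; ",
                         "run assign_species() first")
    s
  }, character(1L))
  sort(unique(sp))
}

#' Link a multiple sequence alignment to tree leaves
#'
#' Reads a FASTA alignment and stores each sequence as the `"sequence"`
#' feature of the leaf whose name equals the record id. All aligned sequences
#' must have equal length.
#'
#' @param tree A `tree_node`.
#' @param alignment Path to a FASTA file, or the FASTA text itself (a string
#'   containing `">"` records or a character vector of lines).
#' @param strict Error on leaves missing from the alignment (default)?
#'   When `FALSE`, unmatched leaves are reported in a warning instead.
#' @return The tree, invisibly.
#' @export
link_alignment <- function(tree, alignment, strict = TRUE) {
  if (is.character(alignment) &&
      (length(alignment) > 1L || grepl(">", alignment, fixed = TRUE))) {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(alignment, tf)
    alignment <- tf
  }
  seqs <- Biostrings::readBStringSet(alignment)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) > 1L)
    stop("aligned sequences have unequal lengths: ",
         paste(range(widths), collapse = " vs "))
  lv <- leaves(tree)
  lvn <- vapply(lv, function(x) x$name, character(1L))
  missing <- setdiff(lvn, ids)
  if (length(missing)) {
    msg <- paste("leaves without an alignment record:",
                 paste(missing, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  m <- match(lvn, ids)
  for (i in seq_along(lv)) {
    if (!is.na(m[i])) set_feature(lv[[i]], "sequence", as.character(seqs[[m[i]]]))
  }
  invisible(tree)
}

new_evol_event <- function(node, etype, in_group, out_group,
                           overlap_score = NA_real_) {
  structure(list(node = node, etype = etype,
                 in_group = in_group, out_group = out_group,
                 overlap_score = overlap_score),
            class = "evol_event")
}

#' @export
print.evol_event <- function(x, ...) {
  cat(sprintf("<evol_event %s%s  in: %s | out: %s>\n", x$etype,
              if (!is.na(x$overlap_score))
                sprintf(" (overlap %.3f)", x$overlap_score) else "",
              paste(x$in_group, collapse = ","),
              paste(x$out_group, collapse = ",")))
  invisible(x)
}

# leaf-name groups split by a node: first child's leaves vs the rest,
# loss leaves excluded
event_groups <- function(node) {
  grp <- lapply(node$children, function(ch) {
    lf <- leaves(ch)
    keep <- vapply(lf, function(x) !identical(x$features[["evoltype"]], "L"),
                   logical(1L))
    vapply(lf[keep], function(x) x$name, character(1L))
  })
  list(in_group = grp[[1L]], out_group = unlist(grp[-1L], use.names = FALSE))
}

#' Infer speciation/duplication events by species overlap
#'
#' The species-overlap algorithm needs no species tree: an internal node is a
#' duplication when its child subtrees share species. For every internal node
#' with at least two children, the overlap score is
#' `|intersection| / |union|` of the children's species sets (the global
#' intersection over the global union when there are more than two children);
#' the node is labelled a duplication when the score is strictly greater than
#' `threshold` (default 0: any shared species), a speciation otherwise. Each
#' node's `"event"` and `"overlap_score"` features are set.
#'
#' @param tree A tree with species assigned (see [assign_species()]).
#' @param threshold Duplication threshold in `[0, 1)`.
#' @return A list of `evol_event` objects in postorder. The event's
#'   `in_group`/`out_group` are the leaf names of the first child versus the
#'   remaining children.
#' @examples
#' t <- parse_newick("((HSA_1,MMU_1),HSA_2);")
#' assign_species(t)
#' ev <- species_overlap_events(t)
#' vapply(ev, function(e) e$etype, "")
#' @export
species_overlap_events <- function(tree, threshold = 0.0) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  spsets <- new.env(parent = emptyenv())
  events <- list()
  for (nd in traverse(tree, "postorder")) {
    key <- as.character(nd$id)
    if (is_leaf(nd)) {
      s <- nd$features[["species"]]
      if (is.null(s)) stop("leaf '", nd$name, "' has no species assigned; ",
                           "run assign_species() first")
      # a loss leaf inserted by reconcile() contributes no species
      if (identical(nd$features[["evoltype"]], "L"))
        assign(key, character(0), envir = spsets)
      else assign(key, s, envir = spsets)
      next
    }
    sets <- lapply(nd$children, function(ch) {
      ck <- as.character(ch$id)
      s <- get(ck, envir = spsets)
      rm(list = ck, envir = spsets)
      s
    })
    uni <- sort(unique(unlist(sets, use.names = FALSE)))
    assign(key, uni, envir = spsets)
    if (length(nd$children) < 2L) next
    inter <- Reduce(intersect, sets)
    score <- if (length(uni)) length(inter) / length(uni) else 0
    etype <- if (score > threshold) "duplication" else "speciation"
    set_feature(nd, "event", etype)
    set_feature(nd, "overlap_score", score)
    grp <- event_groups(nd)
    events[[length(events) + 1L]] <-
      new_evol_event(nd, etype, grp$in_group, grp$out_group, score)
  }
  events
}

# checks that every internal node has exactly two children
assert_binary <- function(tree, what) {
  for (nd in traverse(tree, "preorder")) {
    k <- length(nd$children)
    if (k != 0L && k != 2L)
      stop(what, " must be strictly binary for reconciliation; node '",
           nd$name, "' has ", k, " children. Resolve polytomies first.")
  }
  invisible(TRUE)
}

#' Gene-tree / species-tree reconciliation
#'
#' The classical strict reconciliation: each gene-tree node is mapped to the
#' species-tree LCA of its species set (the LCA map `M`). An internal gene
#' node `v` is a duplication when `M(v)` equals `M` of at least one of its
#' children, a speciation otherwise. Gene losses are inferred per child edge:
#' every species-tree edge skipped between `M(v)` (exclusive for speciations,
#' inclusive for duplications) and `M(child)` means one lineage lost; each
#' loss is materialized in the returned reconciled tree as a ghost leaf
#' carrying features `evoltype = "L"` and `species` (the lost lineage).
#' Both trees must be strictly binary and every gene-tree species must occur
#' in the species tree.
#'
#' @param gene_tree A binary gene tree with species assigned to its leaves.
#' @param species_tree A binary tree whose leaf names are unique species
#'   codes.
#' @return A list of class `reconciliation` with elements:
#'   `reconciled_tree` (a copy of the gene tree with loss leaves inserted and
#'   `"event"` features set), `events` (list of `evol_event`, postorder),
#'   `n_duplications`, `n_losses`, and `mapping` (list of
#'   `list(node, species_node)` pairs for the original gene nodes).
#' @examples
#' g <- parse_newick("(HSA_a,(HSA_b,MMU_b));")
#' assign_species(g, function(n) sub("_.*", "", n))
#' s <- parse_newick("(HSA,MMU);")
#' r <- reconcile(g, s)
#' c(r$n_duplications, r$n_losses)
#' @export
reconcile <- function(gene_tree, species_tree) {
  assert_binary(gene_tree, "gene tree")
  assert_binary(species_tree, "species tree")
  sp_leaves <- leaves(species_tree)
  sp_names <- vapply(sp_leaves, function(x) x$name, character(1L))
  if (anyDuplicated(sp_names))
    stop("species tree leaf names must be unique")
  gene <- clone_node(gene_tree)
  gl <- leaves(gene)
  gsp <- vapply(gl, function(lf) {
    s <- lf$features[["species"]]
    if (is.null(s)) stop("gene leaf '", lf$name, "' has no species assigned")
    s
  }, character(1L))
  unknown <- setdiff(unique(gsp), sp_names)
  if (length(unknown))
    stop("species not in the species tree: ", paste(unknown, collapse = ", "))
  # species-node depths for loss counting
  depth <- new.env(parent = emptyenv())
  assign(as.character(species_tree$id), 0L, envir = depth)
  for (nd in traverse(species_tree, "preorder")) {
    if (!is.null(nd$parent))
      assign(as.character(nd$id),
             get(as.character(nd$parent$id), envir = depth) + 1L,
             envir = depth)
  }
  sp_depth <- function(s) get(as.character(s$id), envir = depth)
  sp_lca <- function(a, b) {
    while (!identical(a, b)) {
      if (sp_depth(a) >= sp_depth(b)) a <- a$parent else b <- b$parent
    }
    a
  }
  # LCA map, postorder
  M <- new.env(parent = emptyenv())
  setM <- function(nd, s) assign(as.character(nd$id), s, envir = M)
  getM <- function(nd) get(as.character(nd$id), envir = M)
  po <- traverse(gene, "postorder")
  events <- list()
  mapping <- list()
  losses <- list()  # per edge: list(child=, lost_species_nodes=)
  n_dup <- 0L
  for (nd in po) {
    if (is_leaf(nd)) {
      setM(nd, sp_leaves[[match(nd$features[["species"]], sp_names)]])
    } else {
      m1 <- getM(nd$children[[1L]])
      m2 <- getM(nd$children[[2L]])
      mv <- sp_lca(m1, m2)
      setM(nd, mv)
      is_dup <- identical(mv, m1) || identical(mv, m2)
      etype <- if (is_dup) "duplication" else "speciation"
      if (is_dup) n_dup <- n_dup + 1L
      set_feature(nd, "event", etype)
      grp <- event_groups(nd)
      events[[length(events) + 1L]] <-
        new_evol_event(nd, etype, grp$in_group, grp$out_group)
      # losses along each child edge
      for (ch in nd$children) {
        mc <- getM(ch)
        # species path mv -> mc, walking up from mc
        path <- list(mc)
        x <- mc
        while (!identical(x, mv)) {
          x <- x$parent
          path <- c(path, list(x))
        }
        # path = mc=s_d, ..., s_0=mv (reversed); lost lineage at s_i is the
        # child of s_i off the path, for i = 1..d-1 (speciation) or 0..d-1
        # (duplication)
        hi <- length(path) - (if (is_dup) 0L else 1L)
        if (hi < 2L) next
        for (i in 2:hi) {
          s_i <- path[[i]]
          on_path <- path[[i - 1L]]
          off <- Filter(function(c) !identical(c, on_path), s_i$children)
          losses[[length(losses) + 1L]] <- list(child = ch, lost = off[[1L]])
        }
      }
    }
    mapping[[length(mapping) + 1L]] <- list(node = nd, species_node = getM(nd))
  }
  # materialize losses: insert a chain node + ghost leaf on each child edge
  for (ls in losses) {
    ch <- ls$child
    sp <- ls$lost
    label <- if (nzchar(sp$name)) sp$name
             else paste(leaf_names(sp), collapse = "/")
    parent <- ch$parent
    i <- child_index(ch)
    mid <- tree_node("", dist = 0)
    ghost <- tree_node(paste0("LOSS_", label), dist = ch$dist)
    set_feature(ghost, "evoltype", "L")
    set_feature(ghost, "species", label)
    mid$parent <- parent
    parent$children[[i]] <- mid
    ch$parent <- mid
    ghost$parent <- mid
    mid$children <- list(ch, ghost)
    mid$dist <- 0
  }
  structure(list(reconciled_tree = gene, events = events,
                 n_duplications = n_dup, n_losses = length(losses),
                 mapping = mapping),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d duplications, %d losses, %d events>\n",
              x$n_duplications, x$n_losses, length(x$events)))
  invisible(x)
}

#' Remove inferred loss leaves from a reconciled tree
#'
#' Deletes every ghost leaf inserted by [reconcile()] (feature
#' `evoltype = "L"`) and collapses the chain nodes left behind, restoring a
#' tree isomorphic to the original gene tree.
#'
#' @param tree A reconciled tree (modified in place).
#' @return The tree root.
#' @export
remove_loss_leaves <- function(tree) {
  repeat {
    ghosts <- Filter(function(lf) identical(lf$features[["evoltype"]], "L"),
                     leaves(tree))
    if (!length(ghosts)) break
    for (g in ghosts) {
      p <- g$parent
      detach(g)
      if (!is.null(p) && length(p$children) == 1L) {
        if (is.null(p$parent)) {
          ch <- p$children[[1L]]
          p$children <- list()
          ch$dist <- ch$dist + p$dist
          ch$parent <- NULL
          tree <- ch
        } else delete_node(p, preserve_dist = TRUE)
      }
    }
  }
  tree
}

#' Build a duplication-dating ladder from a species tree
#'
#' Walks from a seed species leaf to the species-tree root and records the
#' species set of each node on the way: a nested sequence of sets (level 0 =
#' the seed alone) used by [date_duplication()] for relative dating by
#' topology scanning.
#'
#' @param species_tree A species tree.
#' @param seed_species A leaf name of the species tree.
#' @return A list of character vectors, innermost first.
#' @export
species_ladder <- function(species_tree, seed_species) {
  hit <- Filter(function(lf) lf$name == seed_species, leaves(species_tree))
  if (!length(hit))
    stop("seed species '", seed_species, "' not in the species tree")
  lapply(root_path(hit[[1L]]), leaf_names)
}

#' Relative dating of a duplication node
#'
#' Topology scanning against a reference ladder: the age rank of a
#' duplication is the smallest ladder index (0-based) whose species set
#' contains every species under the node. Larger ranks are older; only the
#' relative order is meaningful.
#'
#' @param node A gene-tree node labelled as a duplication.
#' @param reference_ladder A nested list of species sets, e.g. from
#'   [species_ladder()].
#' @return An integer rank (0-based).
#' @export
date_duplication <- function(node, reference_ladder) {
  if (!identical(node$features[["event"]], "duplication"))
    stop("node is not labelled as a duplication; run an event-inference ",
         "method first")
  lf <- leaves(node)
  keep <- vapply(lf, function(x) !identical(x$features[["evoltype"]], "L"),
                 logical(1L))
  sp <- unique(vapply(lf[keep], function(x) x$features[["species"]],
                      character(1L)))
  for (i in seq_along(reference_ladder)) {
    if (all(sp %in% reference_ladder[[i]])) return(i - 1L)
  }
  stop("species under the node (", paste(sp, collapse = ", "),
       ") are not covered by the last ladder level")
}

#' Check the monophyly of an attribute value set
#'
#' Tests whether the leaves carrying the target attribute values form a
#' clean clade. Let `C` be the common ancestor of all matching leaves and `L`
#' the leaves under `C`: the targets are *monophyletic* when every leaf in
#' `L` matches; *paraphyletic* when the non-matching leaves (the intruders)
#' themselves form a single clade under `C`; *polyphyletic* otherwise.
#'
#' @param tree A `tree_node`.
#' @param target_values Values defining the group of interest.
#' @param attribute Attribute/feature name to test (e.g. `"species"` or
#'   `"name"`).
#' @return A list with `verdict` (one of `"monophyletic"`, `"paraphyletic"`,
#'   `"polyphyletic"`) and `intruders` (list of intruder leaves).
#' @export
check_monophyly <- function(tree, target_values, attribute = "species") {
  lv <- leaves(tree)
  vals <- lapply(lv, node_attr, attribute)
  if (any(vapply(vals, is.null, logical(1L))))
    stop("some leaves lack attribute '", attribute, "'")
  vals <- vapply(vals, as.character, character(1L))
  sel <- vals %in% as.character(target_values)
  if (!any(sel))
    stop("no leaf matches the target values for '", attribute, "'")
  ca <- common_ancestor(lv[sel])
  under <- leaves(ca)
  uvals <- vapply(under, function(x) as.character(node_attr(x, attribute)),
                  character(1L))
  intr <- under[!(uvals %in% as.character(target_values))]
  verdict <- if (!length(intr)) "monophyletic"
  else {
    ica <- common_ancestor(intr)
    iu <- leaves(ica)
    if (length(iu) == length(intr)) "paraphyletic" else "polyphyletic"
  }
  list(verdict = verdict, intruders = intr)
}

#' Extract ortholog and paralog pairs from inferred events
#'
#' Two genes are orthologs when their last common ancestor is a speciation
#' event and paralogs when it is a duplication. For every event node, all
#' leaf pairs drawn from two different child subtrees (their LCA is exactly
#' that node) are labelled by the node's event type; each unordered leaf pair
#' is labelled exactly once. Loss leaves are ignored.
#'
#' @param events A list of `evol_event` from [species_overlap_events()] or
#'   [reconcile()] on one tree.
#' @return A data.frame with columns `leaf1`, `leaf2` (with
#'   `leaf1 < leaf2`) and `type` (`"ortholog"` or `"paralog"`).
#' @export
ortholog_pairs <- function(events) {
  rows <- list()
  for (ev in events) {
    groups <- lapply(ev$node$children, function(ch) {
      lf <- leaves(ch)
      keep <- vapply(lf, function(x) !identical(x$features[["evoltype"]], "L"),
                     logical(1L))
      vapply(lf[keep], function(x) x$name, character(1L))
    })
    type <- if (ev$etype == "duplication") "paralog" else "ortholog"
    k <- length(groups)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (!length(groups[[i]]) || !length(groups[[j]])) next
      cross <- expand.grid(a = groups[[i]], b = groups[[j]],
                           stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(leaf1 = pmin(cross$a, cross$b),
                   leaf2 = pmax(cross$a, cross$b),
                   type = type, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(leaf1 = character(0), leaf2 = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Simulate a loss-free gene tree from a species tree
#'
#' Starts from a copy of the species tree (one gene per species) and applies
#' `n_duplications` duplication steps: each step picks a random node and
#' grafts a copy of its subtree as its sibling, so no losses are introduced.
#' The internal nodes created this way (and their copies, when a duplicated
#' subtree already contained one) are the ground-truth duplications, marked
#' with feature `dup_truth = TRUE`. Leaves are renamed
#' `<species>_<counter>` and carry the `"species"` feature.
#'
#' @param species_tree A species tree with unique leaf names.
#' @param n_duplications Number of duplication steps (>= 0).
#' @param seed Optional integer seed.
#' @return The root of the simulated gene tree.
#' @export
simulate_gene_tree <- function(species_tree, n_duplications, seed = NULL) {
  if (n_duplications < 0) stop("n_duplications must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  gene <- clone_node(species_tree)
  for (lf in leaves(gene)) set_feature(lf, "species", lf$name)
  for (k in seq_len(n_duplications)) {
    all <- traverse(gene, "preorder")
    v <- all[[sample.int(length(all), 1L)]]
    cp <- clone_node(v)
    dup <- tree_node("", dist = v$dist)
    set_feature(dup, "dup_truth", TRUE)
    if (is.null(v$parent)) {
      gene <- dup
    } else {
      p <- v$parent
      i <- child_index(v)
      dup$parent <- p
      p$children[[i]] <- dup
      v$parent <- NULL
    }
    v$dist <- tree_defaults()$dist
    cp$dist <- tree_defaults()$dist
    v$parent <- dup
    cp$parent <- dup
    dup$children <- list(v, cp)
  }
  counts <- integer(0)
  for (lf in leaves(gene)) {
    sp <- lf$features[["species"]]
    n <- if (is.na(match(sp, names(counts)))) 1L else counts[[sp]] + 1L
    counts[[sp]] <- n
    lf$name <- paste0(sp, "_", n)
  }
  gene
}
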