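#' Attach a child node (or a whole tree) under a parent
#'
#' Appends `child` to `parent`'s children. Because `child` may itself carry a
#' whole subtree, this operation also implements tree concatenation: attach
#' another tree's root under any node of this one.
#'
#' @param parent A `tree_node`.
#' @param child A root `tree_node` (no parent).
#' @param dist Branch length for the new edge; `NULL` keeps `child$dist`.
#' @return `child`, now connected.
#' @export
attach_child <- function(parent, child, dist = NULL) {
  if (!is.null(child$parent))
    stop("child already has a parent; detach() it first")
  # cycle guard: parent must not live inside child's subtree
  p <- parent
  while (!is.null(p)) {
    if (identical(p, child))
      stop("cannot attach a node under its own descendant (cycle)")
    p <- p$parent
  }
  if (!is.null(dist)) {
    if (!is.numeric(dist) || length(dist) != 1L || is.na(dist) || dist < 0)
      stop("dist must be a single non-negative number")
    child$dist <- as.numeric(dist)
  }
  child$parent <- parent
  parent$children[[length(parent$children) + 1L]] <- child
  child
}

# index of `node` among its parent's children (by reference identity)
child_index <- function(node) {
  sibs <- node$parent$children
  for (i in seq_along(sibs)) if (identical(sibs[[i]], node)) return(i)
  stop("internal error: node not found among its parent's children")
}

#' Detach a subtree from its tree
#'
#' Removes `node` from its parent's child list. The node keeps its whole
#' subtree and becomes a standalone root; the original tree remains valid.
#' Together with [attach_child()] this implements cut & paste of partitions.
#'
#' @param node A non-root `tree_node`.
#' @return `node`, now a root.
#' @export
detach <- function(node) {
  if (is.null(node$parent)) stop("cannot detach the root")
  i <- child_index(node)
  node$parent$children[[i]] <- NULL
  node$parent <- NULL
  node
}

#' Delete a single node, splicing its children into its parent
#'
#' The node disappears; its children take its place (at its position) among
#' the parent's children. With `preserve_dist`, each spliced child's branch
#' length grows by the deleted node's branch length so that all root-to-leaf
#' path lengths are unchanged.
#'
#' @param node A non-root `tree_node`.
#' @param preserve_dist Add the deleted node's `dist` to its children's?
#' @return The parent node, invisibly.
#' @export
delete_node <- function(node, preserve_dist = TRUE) {
  if (is.null(node$parent)) stop("cannot delete the root")
  parent <- node$parent
  i <- child_index(node)
  ch <- node$children
  if (preserve_dist) for (c in ch) c$dist <- c$dist + node$dist
  for (c in ch) c$parent <- parent
  kids <- parent$children
  parent$children <- c(kids[seq_len(i - 1L)], ch,
                       if (i < length(kids)) kids[(i + 1L):length(kids)])
  node$parent <- NULL
  node$children <- list()
  invisible(parent)
}

#' Prune a tree down to a set of leaves
#'
#' Keeps exactly the named leaves, removing all others and collapsing the
#' unary internal nodes that pruning creates. With `preserve_dist` (the
#' default) collapsed branch lengths are accumulated, so every pairwise
#' path-length distance among the kept leaves equals its value in the
#' original tree.
#'
#' @param root A `tree_node` (the subtree to prune, modified in place).
#' @param keep Character vector of leaf names to keep (non-empty subset of
#'   the tree's leaf names).
#' @param preserve_dist Accumulate branch lengths when collapsing?
#' @return The root of the pruned tree (may differ from `root` when the old
#'   root itself collapses).
#' @export
prune <- function(root, keep, preserve_dist = TRUE) {
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("keep must name at least one leaf")
  lv <- leaves(root)
  lvn <- vapply(lv, function(x) x$name, character(1L))
  missing <- setdiff(keep, lvn)
  if (length(missing))
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  po <- traverse(root, "postorder")
  kept <- logical(max(vapply(po, function(x) x$id, integer(1L))))
  # mark kept subtrees bottom-up
  for (nd in po) {
    k <- if (is_leaf(nd)) nd$name %in% keep
         else any(vapply(nd$children, function(c) kept[c$id], logical(1L)))
    kept[nd$id] <- k
  }
  if (!kept[root$id]) stop("keep must name at least one leaf of this subtree")
  # drop unkept branches
  for (nd in po) {
    if (!kept[nd$id] && !is.null(nd$parent) && kept[nd$parent$id]) detach(nd)
  }
  # collapse unary internals (postorder list still valid for surviving nodes)
  for (nd in po) {
    if (!kept[nd$id]) next
    if (length(nd$children) == 1L && !is.null(nd$parent)) {
      ch <- nd$children[[1L]]
      if (preserve_dist) ch$dist <- ch$dist + nd$dist
      parent <- nd$parent
      i <- child_index(nd)
      ch$parent <- parent
      parent$children[[i]] <- ch
      nd$parent <- NULL
      nd$children <- list()
    }
  }
  # a unary root is collapsed by promoting its child
  while (length(root$children) == 1L && is.null(root$parent)) {
    ch <- root$children[[1L]]
    root$children <- list()
    ch$parent <- NULL
    root <- ch
  }
  root
}
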