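# package-local state: monotone node id counter
.treescope <- new.env(parent = emptyenv())
.treescope$next_id <- 1L

#' Default branch length and support values
#'
#' Nodes created without an explicit branch length or support, and newick
#' fields absent from the input under a non-strict dialect, take these
#' values. Tests and user code should reference them through this function
#' rather than hard-coding the constants.
#'
#' @return A list with elements `dist` and `support`, both numeric scalars.
#' @export
tree_defaults <- function() list(dist = 1.0, support = 1.0)

#' Create a tree node
#'
#' The basic building block of every tree handled by this package: a mutable
#' node with a name, a branch length to its parent (`dist`), a support value,
#' an ordered list of children, an optional parent reference and an arbitrary
#' feature map. Nodes have reference semantics (they are R environments), so
#' topology-editing functions modify trees in place, and a node handed around
#' is never silently copied. Every internal node is a fully featured subtree:
#' any function taking a tree accepts any node and operates on its subtree.
#'
#' @param name Node label, a character scalar (may be empty).
#' @param dist Branch length to the parent, a non-negative number.
#'   Defaults to `tree_defaults()$dist`.
#' @param support Node support value. Defaults to `tree_defaults()$support`.
#' @param features Named list of arbitrary annotations.
#' @return An object of class `tree_node`.
#' @examples
#' r <- tree_node("root")
#' a <- attach_child(r, tree_node("A"), dist = 1)
#' b <- attach_child(r, tree_node("B"), dist = 2)
#' length(r)  # number of leaves
#' @export
tree_node <- function(name = "", dist = NULL, support = NULL,
                      features = list()) {
  if (!is.character(name) || length(name) != 1L)
    stop("node name must be a character scalar")
  defs <- tree_defaults()
  if (is.null(dist)) dist <- defs$dist
  if (is.null(support)) support <- defs$support
  if (!is.numeric(dist) || length(dist) != 1L || is.na(dist) || dist < 0)
    stop("dist must be a single non-negative number")
  if (!is.numeric(support) || length(support) != 1L)
    stop("support must be a single number")
  if (length(features) && is.null(names(features)))
    stop("features must be a named list")
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$dist <- as.numeric(dist)
  e$support <- as.numeric(support)
  e$children <- list()
  e$parent <- NULL
  e$features <- features
  e$id <- .treescope$next_id
  .treescope$next_id <- .treescope$next_id + 1L
  class(e) <- "tree_node"
  e
}

#' @export
is_tree_node <- function(x) inherits(x, "tree_node")

#' Test whether a node is a leaf (has no children)
#' @param node A `tree_node`.
#' @export
is_leaf <- function(node) length(node$children) == 0L

#' Test whether a node is a root (has no parent)
#' @param node A `tree_node`.
#' @export
is_root <- function(node) is.null(node$parent)

#' Walk up to the root of the tree containing a node
#' @param node A `tree_node`.
#' @return The root `tree_node`.
#' @export
get_root <- function(node) {
  while (!is.null(node$parent)) node <- node$parent
  node
}

#' Get or set a node feature
#'
#' Features are free-form annotations stored per node, kept separate from the
#' structural fields (`name`, `dist`, `support`, `children`, `parent`).
#'
#' @param node A `tree_node`.
#' @param key Feature name, a character scalar.
#' @param value Any R value; `NULL` removes the feature.
#' @return `get_feature` returns the stored value or `NULL`.
#' @export
get_feature <- function(node, key) node$features[[key]]

#' @rdname get_feature
#' @export
set_feature <- function(node, key, value) {
  if (key %in% c("name", "dist", "support", "children", "parent", "id"))
    stop("feature name '", key, "' would shadow a structural field")
  node$features[[key]] <- value
  invisible(node)
}

# read a structural attribute or a feature by name; NULL when absent
node_attr <- function(node, key) {
  switch(key,
    name = node$name,
    dist = node$dist,
    support = node$support,
    node$features[[key]]
  )
}

#' Deep-copy a subtree
#'
#' Because nodes have reference semantics, assignment aliases rather than
#' copies. `clone_node` produces an independent copy of a node and its whole
#' subtree (names, branch lengths, supports and feature maps included); the
#' copy is a root.
#'
#' @param node A `tree_node`.
#' @return A new `tree_node`, root of the copied subtree.
#' @export
clone_node <- function(node) {
  # iterative preorder so that arbitrarily deep trees copy safely
  map_parent <- list()  # stack of cloned parents parallel to the node stack
  stack <- vector("list", 64L)
  pstack <- vector("list", 64L)
  stack[[1L]] <- node
  pstack[1L] <- list(NULL)
  top <- 1L
  root_copy <- NULL
  while (top > 0L) {
    nd <- stack[[top]]
    par <- pstack[[top]]
    top <- top - 1L
    cp <- tree_node(nd$name, nd$dist, nd$support, nd$features)
    if (is.null(par)) {
      root_copy <- cp
    } else {
      cp$parent <- par
      par$children[[length(par$children) + 1L]] <- cp
    }
    ch <- nd$children
    k <- length(ch)
    if (k) {
      need <- top + k
      if (need > length(stack)) {
        length(stack) <- 2L * need
        length(pstack) <- 2L * need
      }
      for (j in k:1L) {
        top <- top + 1L
        stack[[top]] <- ch[[j]]
        pstack[[top]] <- cp
      }
    }
  }
  root_copy
}

#' @export
length.tree_node <- function(x) length(leaves(x))

#' @export
print.tree_node <- function(x, ...) {
  cat(ascii_art(x, ...), "\n")
  invisible(x)
}

#' @export
format.tree_node <- function(x, ...) write_newick(x, ...)

#' @export
as.character.tree_node <- function(x, ...) write_newick(x, ...)

#' Test whether a tree contains a node with a given name
#' @param tree A `tree_node`.
#' @param name Character scalar node name.
#' @export
has_node <- function(tree, name) {
  length(search_nodes(tree, name = name)) > 0L
}
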