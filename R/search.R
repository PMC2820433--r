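#' Search nodes by attribute and feature values
#'
#' Returns every node in the subtree whose structural attributes (`name`,
#' `dist`, `support`) and features match all the given values, in preorder
#' traversal order. Values are compared with `==` for atomic scalars and
#' `identical()` otherwise; a node lacking a requested feature never matches.
#'
#' @param root A `tree_node`.
#' @param ... Named conditions, e.g. `name = "A"`, `species = "HSA"`.
#' @return A list of matching nodes (possibly empty).
#' @examples
#' t <- parse_newick("((A[&&NHX:species=Hsa],B),C);")
#' length(search_nodes(t, species = "Hsa"))
#' @export
search_nodes <- function(root, ...) {
  conds <- list(...)
  if (length(conds) == 0L) return(traverse(root, "preorder"))
  if (is.null(names(conds)) || any(!nzchar(names(conds))))
    stop("all search conditions must be named")
  matches <- function(nd) {
    for (key in names(conds)) {
      want <- conds[[key]]
      have <- node_attr(nd, key)
      if (is.null(have)) return(FALSE)
      ok <- if (is.atomic(want) && length(want) == 1L &&
                is.atomic(have) && length(have) == 1L) {
        isTRUE(have == want)
      } else {
        identical(have, want)
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }
  all <- traverse(root, "preorder")
  all[vapply(all, matches, logical(1L))]
}

# path from a node up to its root, self first; list of nodes
root_path <- function(node) {
  out <- vector("list", 16L)
  n <- 0L
  while (!is.null(node)) {
    n <- n + 1L
    if (n > length(out)) length(out) <- 2L * n
    out[[n]] <- node
    node <- node$parent
  }
  out[seq_len(n)]
}

#' First common ancestor of a set of nodes
#'
#' The deepest node whose subtree contains every input node. A single node is
#' its own common ancestor (an ancestor of a node may be the answer when it
#' is itself among the inputs).
#'
#' @param nodes A list of `tree_node` objects from one tree (length >= 1).
#' @return A `tree_node`.
#' @export
common_ancestor <- function(nodes) {
  if (is_tree_node(nodes)) nodes <- list(nodes)
  if (length(nodes) < 1L) stop("need at least one node")
  p1 <- root_path(nodes[[1L]])
  ids1 <- vapply(p1, function(x) x$id, integer(1L))
  common <- rep(TRUE, length(ids1))
  for (nd in nodes[-1L]) {
    ids <- vapply(root_path(nd), function(x) x$id, integer(1L))
    common <- common & (ids1 %in% ids)
  }
  if (!any(common)) stop("nodes do not belong to the same tree")
  p1[[which(common)[1L]]]
}
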