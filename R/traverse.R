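#' Traverse a subtree
#'
#' Visits every node of the subtree hanging from `node` (including `node`
#' itself) exactly once. All strategies are implemented with explicit stacks
#' or queues rather than recursion, so traversal is never bounded by the
#' interpreter's recursion depth — trees with hundreds of thousands of nodes
#' (e.g. the NCBI taxonomy) traverse safely.
#'
#' @param node A `tree_node`; treated as the root of its own subtree.
#' @param strategy One of `"preorder"` (node before its children),
#'   `"postorder"` (children before the node) or `"levelorder"`
#'   (breadth-first).
#' @return A list of `tree_node` objects in visit order.
#' @examples
#' t <- parse_newick("((A,B)X,C)R;")
#' vapply(traverse(t, "postorder"), function(n) n$name, "")
#' @export
traverse <- function(node, strategy = c("preorder", "postorder", "levelorder")) {
  strategy <- match.arg(strategy)
  if (strategy == "levelorder") {
    out <- vector("list", 64L)
    out[[1L]] <- node
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      nd <- out[[head]]
      head <- head + 1L
      ch <- nd$children
      k <- length(ch)
      if (k) {
        if (tail + k > length(out)) length(out) <- 2L * (tail + k)
        for (j in seq_len(k)) {
          tail <- tail + 1L
          out[[tail]] <- ch[[j]]
        }
      }
    }
    return(out[seq_len(tail)])
  }
  # preorder by an explicit stack; postorder is the reverse of a preorder
  # that visits children right-to-left
  rev_children <- strategy == "preorder"
  stack <- vector("list", 64L)
  stack[[1L]] <- node
  top <- 1L
  out <- vector("list", 64L)
  n <- 0L
  while (top > 0L) {
    nd <- stack[[top]]
    top <- top - 1L
    n <- n + 1L
    if (n > length(out)) length(out) <- 2L * n
    out[[n]] <- nd
    ch <- nd$children
    k <- length(ch)
    if (k) {
      if (top + k > length(stack)) length(stack) <- 2L * (top + k)
      if (rev_children) {
        for (j in k:1L) {
          top <- top + 1L
          stack[[top]] <- ch[[j]]
        }
      } else {
        for (j in seq_len(k)) {
          top <- top + 1L
          stack[[top]] <- ch[[j]]
        }
      }
    }
  }
  out <- out[seq_len(n)]
  if (strategy == "postorder") out <- rev(out)
  out
}

#' Leaves of a subtree
#'
#' The childless nodes under `node`, in traversal (preorder) order. The
#' number of leaves defines the size of a tree: `length(tree)` is
#' `length(leaves(tree))`.
#'
#' @param node A `tree_node`.
#' @return A list of leaf `tree_node` objects.
#' @export
leaves <- function(node) {
  all <- traverse(node, "preorder")
  all[vapply(all, is_leaf, logical(1L))]
}

#' Leaf names of a subtree, in traversal order
#' @param node A `tree_node`.
#' @return Character vector of leaf names.
#' @export
leaf_names <- function(node) {
  vapply(leaves(node), function(x) x$name, character(1L))
}
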