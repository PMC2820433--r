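#' Path-length distance between two nodes
#'
#' Sum of branch lengths along the unique path between `a` and `b` through
#' their first common ancestor. With `topology_only`, every edge counts 1
#' regardless of its branch length.
#'
#' @param a,b Nodes of the same tree.
#' @param topology_only Count edges instead of summing branch lengths?
#' @return A non-negative number; 0 iff `a` and `b` are the same node.
#' @examples
#' t <- parse_newick("(A:1,(B:2,C:3):4);")
#' a <- search_nodes(t, name = "A")[[1]]
#' b <- search_nodes(t, name = "B")[[1]]
#' get_distance(a, b)  # 7
#' @export
get_distance <- function(a, b, topology_only = FALSE) {
  pa <- root_path(a)
  pb <- root_path(b)
  ida <- vapply(pa, function(x) x$id, integer(1L))
  idb <- vapply(pb, function(x) x$id, integer(1L))
  ka <- which(ida %in% idb)[1L]
  if (is.na(ka)) stop("nodes do not belong to the same tree")
  kb <- match(ida[ka], idb)
  edge_sum <- function(path, k) {
    if (k <= 1L) return(0)
    nodes <- path[seq_len(k - 1L)]
    if (topology_only) length(nodes)
    else sum(vapply(nodes, function(x) x$dist, numeric(1L)))
  }
  edge_sum(pa, ka) + edge_sum(pb, kb)
}

# distances from `node` to every node reachable in the whole tree (undirected
# walk over child and parent edges); returns list(nodes=, dist=)
all_distances_from <- function(node, topology_only = FALSE,
                               descendants_only = FALSE) {
  stack <- vector("list", 64L)
  dstack <- numeric(64L)
  fstack <- integer(64L)   # id of the vertex we arrived from (0 = start)
  stack[[1L]] <- node
  dstack[1L] <- 0
  fstack[1L] <- 0L
  top <- 1L
  out <- vector("list", 64L)
  dist <- numeric(64L)
  n <- 0L
  while (top > 0L) {
    nd <- stack[[top]]
    d <- dstack[top]
    from <- fstack[top]
    top <- top - 1L
    n <- n + 1L
    if (n > length(out)) { length(out) <- 2L * n; length(dist) <- 2L * n }
    out[[n]] <- nd
    dist[n] <- d
    nb <- nd$children
    if (!descendants_only && !is.null(nd$parent)) nb <- c(nb, list(nd$parent))
    for (x in nb) {
      if (x$id == from) next
      w <- if (topology_only) 1 else if (identical(x, nd$parent)) nd$dist
           else x$dist
      top <- top + 1L
      if (top > length(stack)) {
        length(stack) <- 2L * top
        length(dstack) <- 2L * top
        length(fstack) <- 2L * top
      }
      stack[[top]] <- x
      dstack[top] <- d + w
      fstack[top] <- nd$id
    }
  }
  list(nodes = out[seq_len(n)], dist = dist[seq_len(n)])
}

#' Farthest node from a given node
#'
#' Searches the whole tree by default (walking through the parent as well as
#' the children), or only the subtree under `node` with `descendants_only`.
#' Ties are broken by preorder traversal order of the search domain (first
#' node found at the maximal distance wins).
#'
#' @param node A `tree_node`.
#' @param leaves_only Consider only leaves as candidates?
#' @param topology_only Count edges instead of branch lengths?
#' @param descendants_only Restrict the search to the subtree under `node`?
#' @return A list with elements `node` and `dist`.
#' @export
farthest <- function(node, leaves_only = FALSE, topology_only = FALSE,
                     descendants_only = FALSE) {
  dd <- all_distances_from(node, topology_only, descendants_only)
  ids <- vapply(dd$nodes, function(x) x$id, integer(1L))
  domain <- if (descendants_only) node else get_root(node)
  cands <- traverse(domain, "preorder")
  if (leaves_only) cands <- cands[vapply(cands, is_leaf, logical(1L))]
  if (!length(cands)) stop("no candidate nodes to search")
  m <- match(vapply(cands, function(x) x$id, integer(1L)), ids)
  d <- dd$dist[m]
  best <- which.max(d)  # first maximum = first in traversal order
  list(node = cands[[best]], dist = d[best])
}

#' All pairwise leaf-to-leaf path lengths
#'
#' Computes the full symmetric matrix of leaf distances in one postorder
#' sweep (merging per-subtree depth vectors), rows and columns in leaf
#' traversal order.
#'
#' @param root A `tree_node`.
#' @param topology_only Count edges instead of summing branch lengths?
#' @return A numeric matrix with leaf names as dimnames.
#' @examples
#' leaf_distance_matrix(parse_newick("((A:1,B:2):1,C:3);"))
#' @export
leaf_distance_matrix <- function(root, topology_only = FALSE) {
  lv <- leaves(root)
  n <- length(lv)
  idx <- integer(0)
  idx[as.character(vapply(lv, function(x) x$id, integer(1L)))] <- seq_len(n)
  D <- matrix(0, n, n, dimnames = list(vapply(lv, function(x) x$name, ""),
                                       vapply(lv, function(x) x$name, "")))
  # postorder merge of (leaf index, depth) lists; cross pairs between child
  # subtrees meet exactly once, at their LCA
  acc <- new.env(parent = emptyenv())
  for (nd in traverse(root, "postorder")) {
    key <- as.character(nd$id)
    if (is_leaf(nd)) {
      assign(key, list(i = idx[[key]], d = 0), envir = acc)
      next
    }
    li <- integer(0)
    ld <- numeric(0)
    for (ch in nd$children) {
      ck <- as.character(ch$id)
      cl <- get(ck, envir = acc)
      rm(list = ck, envir = acc)
      w <- if (topology_only) 1 else ch$dist
      cd <- cl$d + w
      if (length(li)) {
        for (u in seq_along(li)) {
          D[li[u], cl$i] <- D[cl$i, li[u]] <- ld[u] + cd
        }
      }
      li <- c(li, cl$i)
      ld <- c(ld, cd)
    }
    assign(key, list(i = li, d = ld), envir = acc)
  }
  D
}

#' Midpoint outgroup of a tree
#'
#' Finds the longest leaf-to-leaf path (the tree diameter) and returns the
#' node whose parent edge contains its midpoint; rooting the tree at that
#' node balances the two deepest leaves. When several leaf pairs attain the
#' diameter, the lexicographically first pair of leaf names is used, for
#' reproducibility. The exact position of the midpoint inside the edge is
#' recorded on the returned node as feature `"outgroup_split"` (distance from
#' the node to the midpoint), which [set_outgroup()] consumes so that the new
#' root lands exactly on the midpoint. When the midpoint coincides with an
#' internal node, that node is returned (split 0); when it coincides with the
#' current root, the diameter-path child of the root is returned with a split
#' placing the new root at the old root's position.
#'
#' @param root The tree root.
#' @return A `tree_node` to be used as outgroup.
#' @export
midpoint_outgroup <- function(root) {
  lv <- leaves(root)
  if (length(lv) < 2L) stop("midpoint rooting needs at least 2 leaves")
  D <- leaf_distance_matrix(root)
  diam <- max(D)
  if (diam <= 0)
    stop("all branch lengths are zero; root by topology instead ",
         "(e.g. set_outgroup on a node chosen with topology_only distances)")
  hits <- which(D == diam, arr.ind = TRUE)
  hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
  nm <- rownames(D)
  pairs <- cbind(pmin(nm[hits[, 1L]], nm[hits[, 2L]]),
                 pmax(nm[hits[, 1L]], nm[hits[, 2L]]))
  ord <- order(pairs[, 1L], pairs[, 2L])
  first <- ord[1L]
  u <- lv[[which(nm == pairs[first, 1L])[1L]]]
  v <- lv[[which(nm == pairs[first, 2L])[1L]]]
  half <- diam / 2
  eps <- max(1e-12, 1e-12 * diam)
  # edges along the path u -> lca -> v, each as (child node, position of the
  # child along the path from u, position of its parent along the path)
  pu <- root_path(u)
  pv <- root_path(v)
  idu <- vapply(pu, function(x) x$id, integer(1L))
  idv <- vapply(pv, function(x) x$id, integer(1L))
  ku <- which(idu %in% idv)[1L]
  kv <- match(idu[ku], idv)
  lca <- pu[[ku]]
  child <- list()
  cpos <- numeric(0)
  ppos <- numeric(0)
  pos <- 0
  if (ku > 1L) for (i in seq_len(ku - 1L)) {
    x <- pu[[i]]
    child <- c(child, list(x))
    cpos <- c(cpos, pos)
    ppos <- c(ppos, pos + x$dist)
    pos <- pos + x$dist
  }
  if (kv > 1L) for (j in (kv - 1L):1L) {
    x <- pv[[j]]
    child <- c(child, list(x))
    ppos <- c(ppos, pos)
    cpos <- c(cpos, pos + x$dist)
    pos <- pos + x$dist
  }
  # midpoint exactly on a path node?
  for (i in seq_along(child)) {
    for (at in c("c", "p")) {
      nodepos <- if (at == "c") cpos[i] else ppos[i]
      hit <- abs(nodepos - half) <= eps
      if (!hit) next
      x <- if (at == "c") child[[i]] else child[[i]]$parent
      if (is.null(x$parent)) {
        # midpoint sits on the current root: keep the root's position by
        # splitting at the far end of the adjacent diameter-path edge
        og <- child[[i]]
        set_feature(og, "outgroup_split", og$dist)
        return(og)
      }
      set_feature(x, "outgroup_split", 0)
      return(x)
    }
  }
  for (i in seq_along(child)) {
    lo <- min(cpos[i], ppos[i])
    hi <- max(cpos[i], ppos[i])
    if (half > lo && half < hi) {
      og <- child[[i]]
      set_feature(og, "outgroup_split", abs(half - cpos[i]))
      return(og)
    }
  }
  stop("internal error: midpoint not located on the diameter path")
}

#' Re-root a tree at an outgroup node
#'
#' Returns a new binary root whose two children are the outgroup's subtree
#' and everything else. The outgroup's parent edge is split between the two
#' root children (`split` = distance from the outgroup to the new root;
#' default half the edge, or the exact midpoint position recorded by
#' [midpoint_outgroup()]), so all pairwise leaf distances are preserved. A
#' former root left with a single child is collapsed, its branch length
#' absorbed. Trees with a multifurcating (unrooted-style) root are supported:
#' the non-outgroup children stay grouped under the old root node.
#'
#' @param root The current tree root.
#' @param outgroup A node of the tree other than the root.
#' @param split Distance from `outgroup` to the new root along its parent
#'   edge, in `[0, outgroup$dist]`; `NULL` uses the recorded
#'   `"outgroup_split"` feature when present, else half the edge.
#' @return The new root `tree_node`.
#' @export
set_outgroup <- function(root, outgroup, split = NULL) {
  if (!identical(get_root(outgroup), root))
    stop("outgroup is not a node of this tree")
  if (identical(outgroup, root)) stop("outgroup cannot be the current root")
  X <- outgroup
  L <- X$dist
  if (is.null(split)) {
    split <- X$features[["outgroup_split"]]
    if (!is.null(split)) X$features[["outgroup_split"]] <- NULL
    else split <- L / 2
  }
  if (!is.numeric(split) || length(split) != 1L || is.na(split) ||
      split < 0 || split > L + 1e-12)
    stop("split must lie within the outgroup's parent edge [0, ", L, "]")
  split <- min(split, L)
  P <- X$parent
  detach(X)
  newroot <- tree_node("", dist = 0)
  X$parent <- newroot
  newroot$children <- list(X)
  X$dist <- split
  prev <- newroot
  prev_edge <- L - split
  prev_support <- X$support
  node <- P
  while (!is.null(node)) {
    nxt <- node$parent
    d_old <- node$dist
    s_old <- node$support
    if (!is.null(nxt)) {
      i <- child_index(node)
      nxt$children[[i]] <- NULL
    }
    node$parent <- prev
    prev$children[[length(prev$children) + 1L]] <- node
    node$dist <- prev_edge
    node$support <- prev_support
    prev <- node
    prev_edge <- d_old
    prev_support <- s_old
    node <- nxt
  }
  # collapse the old root if rerooting left it unary
  if (length(prev$children) == 1L && !identical(prev, newroot)) {
    ch <- prev$children[[1L]]
    par <- prev$parent
    i <- child_index(prev)
    ch$dist <- ch$dist + prev$dist
    ch$parent <- par
    par$children[[i]] <- ch
    prev$parent <- NULL
    prev$children <- list()
  }
  newroot
}
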