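#' Read a numeric profile matrix
#'
#' Tab-delimited format: first line `#NAMES<TAB>col1<TAB>col2...`, then one
#' row per item with the item name in the first column. Empty cells or `NA`
#' are missing values.
#'
#' @param path File path.
#' @return A numeric matrix with row and column names.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1L], "#NAMES"))
    stop("profile matrix must start with a '#NAMES' header line")
  cols <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  rn <- vapply(cells, `[[`, character(1L), 1L)
  vals <- t(vapply(cells, function(x) {
    v <- x[-1L]
    length(v) <- length(cols)
    v[!nzchar(v) | v == "NA"] <- NA
    as.numeric(v)
  }, numeric(length(cols))))
  dimnames(vals) <- list(rn, cols)
  validate_profiles(vals)
  vals
}

validate_profiles <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("profiles must be a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("profile matrix needs unique row names")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("profile matrix needs unique column names")
  empty <- rowSums(!is.na(m)) == 0L
  if (any(empty))
    stop("rows with no non-missing value: ",
         paste(rownames(m)[empty], collapse = ", "))
  invisible(m)
}

#' Link a profile matrix to the leaves of a tree
#'
#' Stores each leaf's matrix row as its `"profile"` feature and the full
#' matrix on the root (feature `"profile_matrix"`), which defines the set of
#' "linked leaves" used by the validation indexes.
#'
#' @param tree A `tree_node` (typically a dendrogram over the matrix rows).
#' @param matrix A numeric matrix with row names matching leaf names.
#' @param strict Error when a leaf has no matrix row (default)? When `FALSE`
#'   unmatched leaves are reported in a warning and left unlinked.
#' @return The tree, invisibly.
#' @export
link_profiles <- function(tree, matrix, strict = TRUE) {
  validate_profiles(matrix)
  lv <- leaves(tree)
  lvn <- vapply(lv, function(x) x$name, character(1L))
  missing <- setdiff(lvn, rownames(matrix))
  if (length(missing) == length(lvn))
    stop("no leaf name matches a matrix row")
  if (length(missing)) {
    msg <- paste("leaves without a profile row:",
                 paste(missing, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  for (lf in lv) {
    if (lf$name %in% rownames(matrix))
      set_feature(lf, "profile", matrix[lf$name, ])
  }
  set_feature(tree, "profile_matrix", matrix)
  invisible(tree)
}

#' Leaves of a subtree that carry a linked profile
#'
#' @param node A `tree_node`.
#' @return A list of leaf nodes having a `"profile"` feature (see
#'   [link_profiles()]).
#' @export
linked_leaves <- function(node) {
  Filter(function(lf) !is.null(lf$features[["profile"]]), leaves(node))
}

#' Distance between two profiles
#'
#' Supported metrics: `"euclidean"`, `"pearson"` (1 - Pearson correlation)
#' and `"spearman"` (1 - Spearman correlation); the correlation
#' dissimilarities range over \[0, 2\]. Missing values are handled by
#' pairwise-complete columns; a pair of profiles sharing no non-missing
#' column is an error.
#'
#' @param x,y Numeric vectors of equal length (possibly with `NA`s).
#' @param metric Metric name.
#' @param xname,yname Labels used in error messages.
#' @return A non-negative number.
#' @export
profile_distance <- function(x, y,
                             metric = c("euclidean", "pearson", "spearman"),
                             xname = "x", yname = "y") {
  metric <- match.arg(metric)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok))
    stop("profiles '", xname, "' and '", yname,
         "' share no non-missing column")
  x <- x[ok]
  y <- y[ok]
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    pearson = 1 - stats::cor(x, y, method = "pearson"),
    spearman = 1 - stats::cor(x, y, method = "spearman")
  )
}

cluster_profiles <- function(node) {
  lv <- linked_leaves(node)
  if (!length(lv))
    stop("node has no linked leaves; run link_profiles() first")
  mat <- do.call(rbind, lapply(lv, function(x) x$features[["profile"]]))
  rownames(mat) <- vapply(lv, function(x) x$name, character(1L))
  mat
}

#' Mean and deviation profile of a node (cluster)
#'
#' The expression profile of an internal node is the column-wise mean of its
#' leaves' profiles; the deviation vector is the column-wise (population)
#' standard deviation. Missing values are skipped per column; a column with
#' no non-missing value across the cluster is `NA` in both outputs.
#'
#' @param node A node with linked leaves.
#' @return A list with numeric vectors `mean` and `deviation`.
#' @export
node_profile <- function(node) {
  mat <- cluster_profiles(node)
  mn <- colMeans(mat, na.rm = TRUE)
  dev <- apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    sqrt(mean((col - mean(col))^2))
  })
  mn[is.nan(mn)] <- NA_real_
  list(mean = mn, deviation = dev)
}

pairwise_dists <- function(mat, metric) {
  n <- nrow(mat)
  d <- numeric(0)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- c(d, profile_distance(mat[i, ], mat[j, ], metric,
                               rownames(mat)[i], rownames(mat)[j]))
  }
  d
}

#' Mean intra-cluster distance of a node
#'
#' Mean pairwise profile distance among the node's linked leaves; 0 for a
#' singleton.
#'
#' @param node A node with linked leaves.
#' @param metric See [profile_distance()].
#' @return A non-negative number.
#' @export
intracluster_distance <- function(node, metric = "euclidean") {
  mat <- cluster_profiles(node)
  if (nrow(mat) < 2L) return(0)
  mean(pairwise_dists(mat, metric))
}

#' Inter-cluster distance between two nodes
#'
#' Aggregates the profile distances over all cross pairs of the two nodes'
#' linked leaves with the chosen linkage (`"mean"` by default; `"min"` is the
#' single linkage used inside the Dunn index).
#'
#' @param a,b Nodes with disjoint linked leaf sets.
#' @param metric See [profile_distance()].
#' @param linkage One of `"mean"`, `"min"`, `"max"`.
#' @return A non-negative number, symmetric in `a` and `b`.
#' @export
intercluster_distance <- function(a, b, metric = "euclidean",
                                  linkage = c("mean", "min", "max")) {
  linkage <- match.arg(linkage)
  ma <- cluster_profiles(a)
  mb <- cluster_profiles(b)
  if (length(intersect(rownames(ma), rownames(mb))))
    stop("clusters overlap: ",
         paste(intersect(rownames(ma), rownames(mb)), collapse = ", "))
  d <- numeric(0)
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
    d <- c(d, profile_distance(ma[i, ], mb[j, ], metric,
                               rownames(ma)[i], rownames(mb)[j]))
  }
  switch(linkage, mean = mean(d), min = min(d), max = max(d))
}

#' Silhouette validation of a tree partition
#'
#' Treats the subtree under `node` as one cluster `C` and all remaining
#' linked leaves of the tree as the outside set. For each leaf `i` in `C`,
#' `a(i)` is its mean distance to the other members of `C` and `b(i)` its
#' mean distance to the outside leaves; `s(i) = (b - a) / max(a, b)`, with
#' `s(i) = 0` for a singleton cluster. The node silhouette is the mean of
#' `s(i)`, always in \[-1, 1\]. The outside reference set is the whole
#' root-complement of the subtree (a dendrogram node has no canonical
#' "nearest other cluster"), which is the natural reading of a per-partition
#' index on a tree.
#'
#' The silhouette is also stored as the node feature `"silhouette"`, which
#' the clustering visualization layout uses.
#'
#' @param node A proper subtree: at least one linked leaf inside and one
#'   outside.
#' @param metric See [profile_distance()].
#' @return An object of class `cluster_validation`: a list with `node`,
#'   `silhouette`, `intra_distance`, `inter_distance` (mean linkage to the
#'   outside set) and `std_deviation` (root mean squared deviation of the
#'   cluster's entries around its mean profile).
#' @export
silhouette_index <- function(node, metric = "euclidean") {
  root <- get_root(node)
  inside <- cluster_profiles(node)
  all_lv <- linked_leaves(root)
  out_lv <- Filter(function(lf) !(lf$name %in% rownames(inside)), all_lv)
  if (!length(out_lv))
    stop("node spans all linked leaves; silhouette needs an outside set")
  outside <- do.call(rbind, lapply(out_lv, function(x) x$features[["profile"]]))
  rownames(outside) <- vapply(out_lv, function(x) x$name, character(1L))
  n <- nrow(inside)
  s <- numeric(n)
  bs <- numeric(n)
  for (i in seq_len(n)) {
    b <- mean(vapply(seq_len(nrow(outside)), function(j) {
      profile_distance(inside[i, ], outside[j, ], metric,
                       rownames(inside)[i], rownames(outside)[j])
    }, numeric(1L)))
    bs[i] <- b
    if (n == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(setdiff(seq_len(n), i), function(j) {
      profile_distance(inside[i, ], inside[j, ], metric,
                       rownames(inside)[i], rownames(inside)[j])
    }, numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  sil <- mean(s)
  dev <- node_profile(node)$deviation
  res <- structure(list(
    node = node,
    silhouette = sil,
    intra_distance = if (n < 2L) 0 else mean(pairwise_dists(inside, metric)),
    inter_distance = mean(bs),
    std_deviation = sqrt(mean(dev[!is.na(dev)]^2))
  ), class = "cluster_validation")
  set_feature(node, "silhouette", sil)
  res
}

#' @export
print.cluster_validation <- function(x, ...) {
  cat(sprintf(
    "<cluster_validation: silhouette %.4f, intra %.4f, inter %.4f, sd %.4f>\n",
    x$silhouette, x$intra_distance, x$inter_distance, x$std_deviation))
  invisible(x)
}

#' Silhouette for every internal partition of a tree
#'
#' Convenience wrapper running [silhouette_index()] on each internal node
#' that is a proper subtree of the linked tree, storing the `"silhouette"`
#' feature on the nodes (used by [cluster_layout()]).
#'
#' @param tree The linked tree root.
#' @param metric See [profile_distance()].
#' @return A data.frame with one row per evaluated node: `node_id`, `n_leaves`,
#'   `silhouette`, `intra_distance`, `inter_distance`, `std_deviation`.
#' @export
validate_clusters <- function(tree, metric = "euclidean") {
  total <- length(linked_leaves(tree))
  rows <- list()
  for (nd in traverse(tree, "preorder")) {
    if (is_leaf(nd) || identical(nd, tree)) next
    k <- length(linked_leaves(nd))
    if (k == 0L || k == total) next
    v <- silhouette_index(nd, metric)
    rows[[length(rows) + 1L]] <- data.frame(
      node_id = nd$id, n_leaves = k, silhouette = v$silhouette,
      intra_distance = v$intra_distance, inter_distance = v$inter_distance,
      std_deviation = v$std_deviation)
  }
  if (!length(rows))
    return(data.frame(node_id = integer(0), n_leaves = integer(0),
                      silhouette = numeric(0), intra_distance = numeric(0),
                      inter_distance = numeric(0), std_deviation = numeric(0)))
  do.call(rbind, rows)
}

#' Dunn index of a partition
#'
#' The minimum single-linkage distance between any two clusters divided by
#' the maximum cluster diameter (maximum intra-cluster pairwise distance).
#' Higher values indicate compact, well-separated clusters. A partition in
#' which every cluster has zero diameter is degenerate and raises an error.
#'
#' @param clusters A list of at least two nodes with pairwise-disjoint
#'   linked leaf sets.
#' @param metric See [profile_distance()].
#' @return A non-negative number.
#' @export
dunn_index <- function(clusters, metric = "euclidean") {
  if (length(clusters) < 2L) stop("need at least two clusters")
  mats <- lapply(clusters, cluster_profiles)
  nm <- unlist(lapply(mats, rownames))
  if (anyDuplicated(nm))
    stop("clusters overlap: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  diam <- max(vapply(mats, function(m) {
    if (nrow(m) < 2L) 0 else max(pairwise_dists(m, metric))
  }, numeric(1L)))
  if (diam == 0)
    stop("all cluster diameters are zero; Dunn index is undefined ",
         "for this degenerate partition")
  inter <- Inf
  k <- length(clusters)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    inter <- min(inter, intercluster_distance(clusters[[i]], clusters[[j]],
                                              metric, linkage = "min"))
  }
  inter / diam
}

#' Generate a synthetic clustered profile matrix with its dendrogram
#'
#' Draws `n_clusters` cluster centers spaced `separation` apart (along the
#' first profile dimension, so the Euclidean distance between adjacent
#' centers is exactly `separation`) and `items_per_cluster` items per cluster
#' as center + Gaussian noise with standard deviation `noise_sd`. Also builds
#' the ground-truth dendrogram: one caterpillar subtree per cluster (its root
#' carries feature `cluster = k`), clusters joined into a caterpillar
#' backbone. The matrix is linked to the tree.
#'
#' @param n_clusters,items_per_cluster,n_cols Counts (>= 1).
#' @param separation Distance between adjacent cluster centers.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return A list with `matrix`, `tree` (linked root) and `clusters` (the
#'   list of ground-truth cluster nodes).
#' @export
generate_profiles <- function(n_clusters, items_per_cluster, n_cols,
                              separation = 10, noise_sd = 1, seed = NULL) {
  stopifnot(n_clusters >= 1, items_per_cluster >= 1, n_cols >= 1,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_clusters * items_per_cluster
  m <- matrix(stats::rnorm(n * n_cols, sd = noise_sd), nrow = n, ncol = n_cols)
  rn <- character(n)
  cluster_of <- rep(seq_len(n_clusters), each = items_per_cluster)
  m[, 1L] <- m[, 1L] + (cluster_of - 1L) * separation
  for (k in seq_len(n_clusters)) {
    idx <- which(cluster_of == k)
    rn[idx] <- paste0("c", k, "_i", seq_along(idx))
  }
  rownames(m) <- rn
  colnames(m) <- paste0("cond", seq_len(n_cols))

  caterpillar <- function(names) {
    node <- tree_node(names[[1L]])
    if (length(names) == 1L) return(node)
    for (nm in names[-1L]) {
      p <- tree_node("")
      attach_child(p, node)
      attach_child(p, tree_node(nm))
      node <- p
    }
    node
  }
  subtrees <- lapply(seq_len(n_clusters), function(k) {
    st <- caterpillar(rn[cluster_of == k])
    set_feature(st, "cluster", k)
    st
  })
  tree <- subtrees[[1L]]
  if (n_clusters > 1L) {
    for (k in 2:n_clusters) {
      p <- tree_node("")
      attach_child(p, tree)
      attach_child(p, subtrees[[k]])
      tree <- p
    }
  }
  link_profiles(tree, m)
  list(matrix = m, tree = tree, clusters = subtrees)
}
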