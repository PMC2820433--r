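# shared fixtures and independent brute-force oracles

# random binary tree with random branch lengths/supports, seeded.
# Supports are randomized on internal nodes only: the serialization dialects
# carry support in the internal-label slot, so leaf supports are not a
# round-trippable quantity.
random_weighted_tree <- function(n, seed, max_dist = 5,
                                 internal_supports = TRUE) {
  t <- populate_random(n, seed = seed)
  set.seed(seed + 77777L)
  for (nd in traverse(t)) {
    nd$dist <- stats::runif(1) * max_dist
    if (internal_supports && !is_leaf(nd)) nd$support <- stats::runif(1)
  }
  t
}

# oracle: LCA by walking root paths pointer-by-pointer
oracle_lca <- function(a, b) {
  anc <- list()
  x <- a
  while (!is.null(x)) {
    anc[[length(anc) + 1L]] <- x
    x <- x$parent
  }
  y <- b
  while (!is.null(y)) {
    for (x in anc) if (identical(x, y)) return(y)
    y <- y$parent
  }
  NULL
}

# oracle: path-length distance via explicit walks to the LCA
oracle_distance <- function(a, b, topology_only = FALSE) {
  l <- oracle_lca(a, b)
  walk <- function(x) {
    d <- 0
    while (!identical(x, l)) {
      d <- d + if (topology_only) 1 else x$dist
      x <- x$parent
    }
    d
  }
  walk(a) + walk(b)
}

# oracle: all-pairs leaf distance matrix via oracle_distance
oracle_leaf_dists <- function(tree) {
  lv <- leaves(tree)
  n <- length(lv)
  nm <- leaf_names(tree)
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- oracle_distance(lv[[i]], lv[[j]])
  }
  D
}

# topology isomorphism preserving child order, comparing names/dist/support
# and selected features
expect_same_tree <- function(a, b, features = character(0), tol = 1e-9) {
  na <- traverse(a, "preorder")
  nb <- traverse(b, "preorder")
  expect_equal(length(na), length(nb))
  for (i in seq_along(na)) {
    x <- na[[i]]
    y <- nb[[i]]
    expect_equal(length(x$children), length(y$children))
    expect_identical(x$name, y$name)
    expect_lt(abs(x$dist - y$dist), tol)
    if (!is_leaf(x)) expect_lt(abs(x$support - y$support), tol)
    for (f in features)
      expect_identical(x$features[[f]], y$features[[f]])
  }
  invisible(TRUE)
}

# independent cluster-index oracles built on stats::dist / stats::cor
oracle_dist_matrix <- function(m, metric = "euclidean") {
  if (metric == "euclidean") return(as.matrix(stats::dist(m)))
  meth <- if (metric == "pearson") "pearson" else "spearman"
  1 - stats::cor(t(m), method = meth)
}

oracle_silhouette <- function(m, members, metric = "euclidean") {
  D <- oracle_dist_matrix(m, metric)
  inside <- which(rownames(m) %in% members)
  outside <- setdiff(seq_len(nrow(m)), inside)
  s <- vapply(inside, function(i) {
    b <- mean(D[i, outside])
    if (length(inside) == 1L) return(0)
    a <- mean(D[i, setdiff(inside, i)])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

oracle_dunn <- function(m, groups, metric = "euclidean") {
  D <- oracle_dist_matrix(m, metric)
  idx <- lapply(groups, function(g) which(rownames(m) %in% g))
  diam <- max(vapply(idx, function(ii) {
    if (length(ii) < 2L) 0 else max(D[ii, ii])
  }, numeric(1L)))
  inter <- Inf
  k <- length(idx)
  for (i in 1:(k - 1L)) for (j in (i + 1L):k)
    inter <- min(inter, min(D[idx[[i]], idx[[j]]]))
  inter / diam
}

oracle_intra <- function(m, members, metric = "euclidean") {
  D <- oracle_dist_matrix(m, metric)
  ii <- which(rownames(m) %in% members)
  if (length(ii) < 2L) return(0)
  mean(D[ii, ii][upper.tri(diag(length(ii)))])
}

oracle_inter <- function(m, ga, gb, metric = "euclidean", linkage = "mean") {
  D <- oracle_dist_matrix(m, metric)
  ia <- which(rownames(m) %in% ga)
  ib <- which(rownames(m) %in% gb)
  v <- as.vector(D[ia, ib, drop = FALSE])
  switch(linkage, mean = mean(v), min = min(v), max = max(v))
}
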