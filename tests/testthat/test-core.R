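test_that("traversal strategies visit every node in the documented order", {
  t <- parse_newick("((A,B)ab,(C,D)cd)r;")
  nm <- function(nodes) vapply(nodes, function(x) x$name, character(1L))
  expect_identical(nm(traverse(t, "preorder")),
                   c("r", "ab", "A", "B", "cd", "C", "D"))
  expect_identical(nm(traverse(t, "postorder")),
                   c("A", "B", "ab", "C", "D", "cd", "r"))
  expect_identical(nm(traverse(t, "levelorder")),
                   c("r", "ab", "cd", "A", "B", "C", "D"))
  single <- tree_node("only")
  expect_length(traverse(single), 1L)
  expect_identical(leaf_names(single), "only")
})

test_that("traversal is stack-safe on a deep caterpillar", {
  # built bottom-up so each attach happens under a fresh root
  node <- tree_node("L1")
  for (i in 2:50000) {
    p <- tree_node("")
    attach_child(p, node)
    attach_child(p, tree_node(paste0("L", i)))
    node <- p
  }
  root <- node
  expect_equal(length(traverse(root, "postorder")), 2L * 50000L - 1L)
  expect_equal(length(leaves(root)), 50000L)
})

test_that("features are typed, persistent and protected from shadowing", {
  t <- parse_newick("(A:1,B:2);")
  a <- search_nodes(t, name = "A")[[1]]
  set_feature(a, "vector", c(1.5, 2.5))
  set_feature(a, "flag", TRUE)
  expect_identical(get_feature(a, "vector"), c(1.5, 2.5))
  expect_true(get_feature(a, "flag"))
  expect_null(get_feature(a, "absent"))
  expect_error(set_feature(a, "dist", 3), "dist")
  expect_error(set_feature(a, "children", list()), "children")
})

test_that("search_nodes matches attributes and features like a linear scan", {
  t <- random_weighted_tree(30, 11)
  set_feature(search_nodes(t, name = "t5")[[1]], "mark", "x")
  set_feature(search_nodes(t, name = "t9")[[1]], "mark", "x")
  hits <- search_nodes(t, mark = "x")
  expect_setequal(vapply(hits, function(x) x$name, ""), c("t5", "t9"))
  # oracle: plain filter over all nodes
  all <- traverse(t, "preorder")
  oracle <- Filter(function(nd) identical(nd$features[["mark"]], "x"), all)
  expect_equal(length(hits), length(oracle))
  expect_error(search_nodes(t, "unnamed"), "named")
  expect_length(search_nodes(t, name = "no_such_leaf"), 0L)
})

test_that("attach/detach implement cut & paste preserving content", {
  t <- random_weighted_tree(20, 3)
  before <- sort(leaf_names(t))
  deep <- Filter(function(lf) !is_root(lf$parent) && !is_root(lf$parent$parent),
                 leaves(t))
  sub <- deep[[1]]$parent
  moved <- sort(leaf_names(sub))
  detach(sub)
  expect_true(is.null(sub$parent))
  expect_identical(sort(c(leaf_names(t), moved)), before)
  attach_child(t, sub, dist = 0.25)
  expect_identical(sort(leaf_names(t)), before)
  expect_equal(sub$dist, 0.25)
  expect_error(attach_child(sub, t), "cycle|descendant")
  expect_error(detach(t), "root")
})

test_that("delete_node splices children and preserves path lengths", {
  t <- parse_newick("((A:1,B:2)x:3,C:4);")
  a <- search_nodes(t, name = "A")[[1]]
  c_ <- search_nodes(t, name = "C")[[1]]
  d_before <- get_distance(a, c_)
  delete_node(search_nodes(t, name = "x")[[1]])
  expect_identical(leaf_names(t), c("A", "B", "C"))
  expect_equal(search_nodes(t, name = "A")[[1]]$dist, 4)
  expect_equal(get_distance(a, c_), d_before)
})

test_that("prune keeps exactly the requested leaves and their distances", {
  t <- parse_newick("(((A:1,B:1):1,(C:1,D:1):2):1,E:5);")
  a <- search_nodes(t, name = "A")[[1]]
  e <- search_nodes(t, name = "E")[[1]]
  d <- get_distance(a, e)
  t2 <- prune(t, c("A", "E"))
  expect_setequal(leaf_names(t2), c("A", "E"))
  expect_equal(get_distance(a, e), d)
  # no unary internal nodes remain
  for (nd in traverse(t2)) expect_true(length(nd$children) != 1L)
  expect_error(prune(t2, "Z"), "Z")
})

test_that("common_ancestor and get_distance match the brute-force oracle", {
  for (seed in 1:10) {
    t <- random_weighted_tree(sample(3:25, 1), seed + 40)
    nodes <- traverse(t, "preorder")
    pick <- sample(length(nodes), min(12L, length(nodes)))
    for (i in pick) for (j in pick) {
      a <- nodes[[i]]
      b <- nodes[[j]]
      expect_identical(common_ancestor(list(a, b))$id, oracle_lca(a, b)$id)
      expect_lt(abs(get_distance(a, b) - oracle_distance(a, b)), 1e-9)
      expect_equal(get_distance(a, b, topology_only = TRUE),
                   oracle_distance(a, b, topology_only = TRUE))
    }
  }
  # a single node is its own ancestor; distance to self is 0
  t <- parse_newick("((A,B),C);")
  a <- search_nodes(t, name = "A")[[1]]
  expect_identical(common_ancestor(list(a))$id, a$id)
  expect_equal(get_distance(a, a), 0)
})

test_that("farthest finds the maximum-distance node, ties by traversal order", {
  t <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  a <- search_nodes(t, name = "A")[[1]]
  f <- farthest(a, leaves_only = TRUE)
  expect_equal(f$dist, 4)
  expect_identical(f$node$name, "C")  # C ties D, C first in preorder
  t2 <- parse_newick("((A:3,(B:1,C:1):1):1,D:1);")
  f2 <- farthest(t2, leaves_only = TRUE, descendants_only = TRUE)
  expect_identical(f2$node$name, "A")
  expect_equal(f2$dist, 4)
})

test_that("leaf_distance_matrix equals the pairwise oracle", {
  for (seed in 1:6) {
    t <- random_weighted_tree(sample(3:25, 1), seed + 90)
    D <- leaf_distance_matrix(t)
    O <- oracle_leaf_dists(t)
    expect_lt(max(abs(D - O[rownames(D), colnames(D)])), 1e-9)
  }
})

test_that("set_outgroup reroots correctly and preserves leaf distances", {
  t <- parse_newick("((A:1,B:2)ab:1,C:3)r;")
  c_ <- search_nodes(t, name = "C")[[1]]
  r2 <- set_outgroup(t, c_)
  expect_true(is_root(r2))
  expect_equal(length(r2$children), 2L)
  expect_setequal(leaf_names(r2), c("A", "B", "C"))
  # distances are invariant under rerooting
  for (seed in 1:8) {
    t <- random_weighted_tree(sample(4:25, 1), seed + 200)
    D1 <- leaf_distance_matrix(t)
    og <- leaves(t)[[sample(length(leaves(t)), 1)]]
    r <- set_outgroup(t, og)
    D2 <- leaf_distance_matrix(r)
    expect_lt(max(abs(D1 - D2[rownames(D1), colnames(D1)])), 1e-9)
  }
})

test_that("midpoint rooting balances the two deepest leaves", {
  t <- parse_newick("((A:6,B:1):1,C:1);")
  og <- midpoint_outgroup(t)
  r <- set_outgroup(t, og)
  depths <- vapply(leaves(r), function(lf) get_distance(r, lf), numeric(1L))
  # diameter is A..C = 8; both sides of the root must reach 4
  side_max <- vapply(r$children, function(ch)
    ch$dist + max(c(0, vapply(leaves(ch), function(lf)
      get_distance(ch, lf), numeric(1L)))), numeric(1L))
  expect_lt(abs(side_max[1] - side_max[2]), 1e-6)
  expect_equal(max(depths), 4, tolerance = 1e-6)
})

test_that("populate_random is seeded, sized correctly and varied", {
  t <- populate_random(50, seed = 7)
  expect_equal(length(leaves(t)), 50L)
  expect_equal(length(traverse(t)), 99L)  # 2n - 1 nodes, binary
  expect_identical(sort(leaf_names(t)), sort(paste0("t", 1:50)))
  expect_identical(write_newick(populate_random(50, seed = 7)),
                   write_newick(t))
  diff <- 0L
  for (s in 1:20) {
    a <- write_newick(populate_random(10, seed = s), "TOPOLOGY_ONLY")
    b <- write_newick(populate_random(10, seed = s + 1000L), "TOPOLOGY_ONLY")
    if (!identical(a, b)) diff <- diff + 1L
  }
  expect_gt(diff, 0L)
  nm <- c("x", "y", "z")
  expect_setequal(leaf_names(populate_random(3, names = nm, seed = 1)), nm)
})

test_that("ascii_art draws each leaf on its own line", {
  t <- parse_newick("((A,B)ab,C)r;")
  art <- ascii_art(t)
  lines <- strsplit(art, "\n")[[1]]
  for (lf in c("A", "B", "C"))
    expect_equal(sum(grepl(lf, lines, fixed = TRUE)), 1L)
  expect_true(any(grepl("ab", lines, fixed = TRUE)))
  expect_false(grepl("ab", ascii_art(t, show_internal = FALSE), fixed = TRUE))
  # print method uses it
  expect_output(print(t), "A")
})

test_that("clone_node copies structure and features independently", {
  t <- random_weighted_tree(15, 5)
  set_feature(leaves(t)[[1]], "tag", "orig")
  cp <- clone_node(t)
  expect_same_tree(t, cp, features = "tag")
  set_feature(leaves(cp)[[1]], "tag", "changed")
  expect_identical(get_feature(leaves(t)[[1]], "tag"), "orig")
  # ids are fresh so both trees can be searched independently
  expect_false(cp$id == t$id)
})
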