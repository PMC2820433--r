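#' Generate a random binary tree
#'
#' Grows a tree by Yule-like splitting: starting from a single node, a
#' uniformly random current leaf is repeatedly replaced by a cherry until the
#' requested number of leaves is reached. The result is binary with `n`
#' leaves and `2n - 1` nodes; all branch lengths and supports take the
#' defaults of [tree_defaults()]. With the same `seed` the generated tree
#' (topology and names) is identical across calls.
#'
#' @param n Number of leaves (>= 1).
#' @param names Optional character vector of leaf names (length >= `n`);
#'   assigned to leaves in traversal order. When `NULL`, leaves are named
#'   `t1 ... tn`.
#' @param seed Optional integer seed for the split sequence.
#' @return The root `tree_node`.
#' @examples
#' t <- populate_random(5, seed = 42)
#' length(t)
#' @export
populate_random <- function(n, names = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  if (!is.null(names) && length(names) < n)
    stop("names has ", length(names), " entries but ", n, " leaves requested")
  if (!is.null(seed)) set.seed(seed)
  root <- tree_node()
  lv <- vector("list", n)
  lv[[1L]] <- root
  nl <- 1L
  while (nl < n) {
    i <- sample.int(nl, 1L)
    nd <- lv[[i]]
    c1 <- tree_node()
    c2 <- tree_node()
    c1$parent <- nd
    c2$parent <- nd
    nd$children <- list(c1, c2)
    lv[[i]] <- c1
    nl <- nl + 1L
    lv[[nl]] <- c2
  }
  out <- leaves(root)
  if (is.null(names)) names <- paste0("t", seq_len(n))
  for (i in seq_len(n)) out[[i]]$name <- names[[i]]
  root
}
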