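#' Text-mode tree visualization
#'
#' Draws the subtree as a multi-line ASCII dendrogram using '/', '\\', '|'
#' and '-' characters. Each leaf name appears on exactly one line; deeper
#' nodes are indented further right. Built iteratively (postorder assembly of
#' line blocks), so it is not limited by recursion depth.
#'
#' @param root A `tree_node`.
#' @param show_internal Write internal node names onto their stems?
#' @return A single string with embedded newlines.
#' @examples
#' cat(ascii_art(parse_newick("((A,B),C);")))
#' @export
ascii_art <- function(root, show_internal = TRUE) {
  blocks <- new.env(parent = emptyenv())  # id -> list(lines=, mid=) mid 1-based
  for (nd in traverse(root, "postorder")) {
    key <- as.character(nd$id)
    if (is_leaf(nd)) {
      # stem starts with a placeholder '-'; the parent overwrites it
      assign(key, list(lines = paste0("--", nd$name), mid = 1L), envir = blocks)
      next
    }
    k <- length(nd$children)
    label <- if (show_internal && nzchar(nd$name)) nd$name else ""
    len <- max(3L, nchar(label) + 2L)
    pad <- strrep(" ", len)
    bar <- paste0(strrep(" ", len - 1L), "|")
    lines <- character(0)
    mids <- integer(0)
    for (j in seq_len(k)) {
      ch <- nd$children[[j]]
      ck <- as.character(ch$id)
      b <- get(ck, envir = blocks)
      rm(list = ck, envir = blocks)
      char2 <- if (k == 1L || j == 1L) "/" else if (j == k) "\\" else "-"
      clines <- b$lines
      substr(clines[b$mid], 1L, 1L) <- char2
      mids <- c(mids, b$mid + length(lines))
      lines <- c(lines, clines)
    }
    lo <- mids[1L]
    hi <- mids[k]
    end <- length(lines)
    prefixes <- c(rep(pad, lo), rep(bar, max(0L, hi - lo - 1L)),
                  rep(pad, end - hi + 1L))
    mid <- as.integer((lo + hi) %/% 2L)
    stem_tail <- substr(prefixes[mid], len, len)
    stem <- paste0("-", label, strrep("-", len - 2L - nchar(label)), stem_tail)
    prefixes[mid] <- stem
    assign(key, list(lines = paste0(prefixes[seq_len(end)], lines), mid = mid),
           envir = blocks)
  }
  b <- get(as.character(root$id), envir = blocks)
  paste0(paste(b$lines, collapse = "\n"), "\n")
}
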