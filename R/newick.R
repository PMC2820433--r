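#' Newick dialect registry
#'
#' Newick files in the wild differ in which fields they carry. A dialect
#' declares which fields are written (and expected when parsing strictly):
#' leaf names, internal node names, branch lengths and support values, plus
#' where supports live (`"internal-name-slot"` puts a bare number in the
#' internal label position, the common convention). Four dialects are
#' registered, addressable by id or by name:
#'
#' * `FULL` (id 0): leaf and internal names, branch lengths, supports;
#'   an internal node's label slot holds its name when non-empty, else its
#'   support value. Strict.
#' * `LEAF_NAMES_LENGTHS` (id 1): leaf names and branch lengths only. Strict.
#' * `TOPOLOGY_ONLY` (id 2): leaf names only. Strict.
#' * `FLEXIBLE` (id 3): same fields as `FULL` but non-strict — malformed or
#'   absent numeric fields fall back to [tree_defaults()] instead of
#'   erroring.
#'
#' @return `newick_dialects()`: the list of registered dialects.
#' @export
newick_dialects <- function() .newick_registry

new_dialect <- function(id, name, leaf_names, internal_names, lengths,
                        support, strict) {
  stopifnot(leaf_names || lengths)
  structure(list(
    id = id, name = name,
    writes_leaf_names = leaf_names,
    writes_internal_names = internal_names,
    writes_branch_lengths = lengths,
    writes_support = support,
    support_position = if (support) "internal-name-slot" else "bracket-none",
    strict = strict
  ), class = "newick_dialect")
}

.newick_registry <- list(
  FULL = new_dialect(0L, "FULL", TRUE, TRUE, TRUE, TRUE, TRUE),
  LEAF_NAMES_LENGTHS = new_dialect(1L, "LEAF_NAMES_LENGTHS",
                                   TRUE, FALSE, TRUE, FALSE, TRUE),
  TOPOLOGY_ONLY = new_dialect(2L, "TOPOLOGY_ONLY",
                              TRUE, FALSE, FALSE, FALSE, TRUE),
  FLEXIBLE = new_dialect(3L, "FLEXIBLE", TRUE, TRUE, TRUE, TRUE, FALSE)
)

#' @rdname newick_dialects
#' @param dialect A dialect object, a registered dialect name, or an id.
#' @export
get_dialect <- function(dialect) {
  if (inherits(dialect, "newick_dialect")) return(dialect)
  if (is.numeric(dialect)) {
    ids <- vapply(.newick_registry, `[[`, integer(1L), "id")
    i <- match(as.integer(dialect), ids)
    if (is.na(i)) stop("no newick dialect with id ", dialect)
    return(.newick_registry[[i]])
  }
  if (is.character(dialect)) {
    d <- .newick_registry[[toupper(dialect)]]
    if (is.null(d)) stop("no newick dialect named '", dialect, "'")
    return(d)
  }
  stop("dialect must be a dialect object, name or id")
}

.nhx_key_bad <- "[:=\\[\\]]"
.nhx_val_bad <- "[:\\[\\]]"

#' Decode an NHX comment into an annotation map
#'
#' NHX (New Hampshire eXtended) embeds per-node annotations in newick
#' comments of the form `[&&NHX:key=value:key=value]`. `decode_nhx` takes the
#' comment body (without the square brackets) and returns the entries as an
#' ordered named character vector. When a key occurs more than once, the last
#' occurrence wins and a warning is emitted.
#'
#' @param comment Comment body beginning with `"&&NHX"`.
#' @return A named character vector (possibly empty), in entry order.
#' @examples
#' decode_nhx("&&NHX:S=Hsa:D=Y")
#' @export
decode_nhx <- function(comment) {
  if (!startsWith(comment, "&&NHX"))
    stop("not an NHX comment: ", comment)
  body <- substr(comment, 6L, nchar(comment))
  out <- stats::setNames(character(0), character(0))
  if (!nzchar(body)) return(out)
  if (!startsWith(body, ":"))
    stop("malformed NHX comment: expected ':' after '&&NHX' in ", comment)
  parts <- strsplit(substr(body, 2L, nchar(body)), ":", fixed = TRUE)[[1L]]
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 1L)
      stop("malformed NHX pair (no '='): '", p, "'")
    k <- substr(p, 1L, eq - 1L)
    v <- substr(p, eq + 1L, nchar(p))
    if (!nzchar(k)) stop("malformed NHX pair (empty key): '", p, "'")
    if (k %in% names(out)) {
      warning("duplicate NHX key '", k, "'; last occurrence wins")
      out <- out[names(out) != k]
    }
    out[[k]] <- v
  }
  out
}

#' Encode an annotation map as an NHX block
#'
#' The inverse of [decode_nhx()]: returns `"[&&NHX:k1=v1:...]"` with keys in
#' the input order, or `""` for an empty annotation (no block emitted). Keys
#' may not contain `:`, `=`, `[`, `]`; values may not contain `:`, `[`, `]`.
#'
#' @param annotation A named character vector (or coercible list).
#' @return A character scalar.
#' @export
encode_nhx <- function(annotation) {
  if (length(annotation) == 0L) return("")
  keys <- names(annotation)
  vals <- vapply(annotation, as.character, character(1L))
  if (is.null(keys) || any(!nzchar(keys)))
    stop("all NHX entries must be named")
  bad_k <- grepl(.nhx_key_bad, keys, perl = TRUE)
  if (any(bad_k))
    stop("illegal character in NHX key(s): ",
         paste(keys[bad_k], collapse = ", "))
  bad_v <- grepl(.nhx_val_bad, vals, perl = TRUE)
  if (any(bad_v))
    stop("illegal character in NHX value(s) for key(s): ",
         paste(keys[bad_v], collapse = ", "))
  paste0("[&&NHX:", paste0(keys, "=", vals, collapse = ":"), "]")
}

# tokenizer shared by the parser; returns matches and their offsets
newick_tokens <- function(text) {
  m <- gregexpr("'(?:[^']|'')*'|\\[[^]]*\\]|[(),;]|[^(),;\\[\\]']+",
                text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(list(tok = character(0), pos = integer(0)))
  list(tok = regmatches(text, list(m))[[1L]], pos = as.integer(m))
}

# "name" / "name:dist" / ":dist" / "" -> list(label=, dist= or NULL)
split_label_dist <- function(s) {
  i <- regexpr(":", s, fixed = TRUE)
  if (i < 1L) return(list(label = trimws(s), dist = NULL))
  list(label = trimws(substr(s, 1L, i - 1L)),
       dist = trimws(substr(s, i + 1L, nchar(s))))
}

#' Parse a newick / NHX statement
#'
#' Reads a single `';'`-terminated newick statement into a tree of
#' [tree_node()] objects. NHX comment blocks attach their entries (as
#' character values) to the node's feature map. Multifurcations are
#' preserved. Absent branch lengths and supports take the defaults of
#' [tree_defaults()]. Under a strict dialect a non-numeric branch length is a
#' parse error reporting the character offset; under `FLEXIBLE` it falls back
#' to the default. Following common practice, a bare number in an internal
#' node's label slot is read as a support value when the dialect declares
#' `writes_support`, and as a name otherwise. Quoted labels (`'...'`, with
#' `''` escaping a quote) are supported; whitespace outside quoted labels is
#' ignored.
#'
#' @param text A newick statement.
#' @param dialect Dialect object, name or id (see [newick_dialects()]);
#'   default `"FLEXIBLE"`.
#' @return The root `tree_node`.
#' @examples
#' t <- parse_newick("(A:1,(B:2,C:3)0.9:4)root;")
#' leaf_names(t)
#' @export
parse_newick <- function(text, dialect = "FLEXIBLE") {
  d <- get_dialect(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  tk <- newick_tokens(text)
  toks <- tk$tok
  poss <- tk$pos
  perr <- function(msg, pos) {
    stop("newick parse error at character ", pos, ": ", msg)
  }
  parse_num <- function(s, pos, what) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      if (d$strict) perr(paste0("non-numeric ", what, " '", s, "'"), pos)
      return(NULL)  # caller keeps the default
    }
    v
  }
  root <- tree_node()
  cur <- root
  fresh <- TRUE
  done <- FALSE
  depth <- 0L
  for (ti in seq_along(toks)) {
    tok <- toks[[ti]]
    pos <- poss[[ti]]
    if (done) {
      if (!nzchar(trimws(tok)))
        next
      perr("content after ';'", pos)
    }
    c1 <- substr(tok, 1L, 1L)
    if (c1 == "(") {
      depth <- depth + 1L
      ch <- tree_node()
      ch$parent <- cur
      cur$children[[length(cur$children) + 1L]] <- ch
      cur <- ch
      fresh <- TRUE
    } else if (c1 == ",") {
      if (fresh) perr("dangling comma (empty node)", pos)
      p <- cur$parent
      if (is.null(p) || depth == 0L)
        perr("comma outside parentheses", pos)
      ch <- tree_node()
      ch$parent <- p
      p$children[[length(p$children) + 1L]] <- ch
      cur <- ch
      fresh <- TRUE
    } else if (c1 == ")") {
      if (fresh) perr("dangling comma or empty group", pos)
      if (depth == 0L || is.null(cur$parent))
        perr("unbalanced parentheses: unexpected ')'", pos)
      depth <- depth - 1L
      cur <- cur$parent
      fresh <- FALSE
    } else if (c1 == ";") {
      if (depth != 0L)
        perr("unbalanced parentheses: unclosed '('", pos)
      if (fresh && length(cur$children) == 0L && !nzchar(cur$name))
        perr("empty newick statement", pos)
      done <- TRUE
    } else if (c1 == "'") {
      nm <- substr(tok, 2L, nchar(tok) - 1L)
      cur$name <- gsub("''", "'", nm, fixed = TRUE)
      fresh <- FALSE
    } else if (c1 == "[") {
      body <- substr(tok, 2L, nchar(tok) - 1L)
      if (startsWith(body, "&&NHX")) {
        ann <- decode_nhx(body)
        for (k in names(ann)) cur$features[[k]] <- ann[[k]]
      }
      fresh <- FALSE
    } else {
      if (!nzchar(trimws(tok))) next
      ld <- split_label_dist(tok)
      if (nzchar(ld$label)) {
        num <- suppressWarnings(as.numeric(ld$label))
        is_internal <- length(cur$children) > 0L
        if (is_internal && !is.na(num) && d$writes_support) {
          cur$support <- num
        } else {
          cur$name <- ld$label
        }
      }
      if (!is.null(ld$dist) && nzchar(ld$dist)) {
        v <- parse_num(ld$dist, pos, "branch length")
        if (!is.null(v)) cur$dist <- v
      }
      fresh <- FALSE
    }
  }
  if (!done) stop("newick parse error: missing terminating ';'")
  root
}

.newick_reserved <- "[(),:;\\[\\]]"

newick_label <- function(name, auto_quote) {
  if (!nzchar(name)) return("")
  if (grepl(.newick_reserved, name, perl = TRUE) || grepl("\\s", name)) {
    if (!auto_quote)
      stop("node name '", name, "' contains newick-reserved characters; ",
           "rename it or write with auto_quote = TRUE")
    return(paste0("'", gsub("'", "''", name, fixed = TRUE), "'"))
  }
  name
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a tree as a newick / NHX string
#'
#' Serializes the subtree under `root` as a `';'`-terminated newick
#' statement. Which fields appear is controlled by the dialect (see
#' [newick_dialects()]). Under a support-writing dialect, an internal node's
#' label slot carries its name when non-empty, else its support value. Nodes
#' holding any feature listed in `include_features` gain an NHX block. Names
#' containing newick-reserved characters (`'(),:;[]'` or whitespace) raise an
#' error unless `auto_quote = TRUE`, in which case they are single-quoted.
#' `parse_newick(write_newick(t))` reproduces `t`: topology, names, numeric
#' fields and exported features.
#'
#' The writer is iterative (explicit stack), so very large trees serialize
#' without recursion-depth limits.
#'
#' @param root A `tree_node`.
#' @param dialect Dialect object, name or id; default `"FULL"`.
#' @param include_features Character vector of feature names to export as
#'   NHX annotations.
#' @param auto_quote Quote names containing reserved characters instead of
#'   raising?
#' @return A character scalar ending in `";"`.
#' @examples
#' t <- parse_newick("(A:1,B:2)R:0;")
#' write_newick(t, dialect = "LEAF_NAMES_LENGTHS")
#' @export
write_newick <- function(root, dialect = "FULL",
                         include_features = character(0),
                         auto_quote = FALSE) {
  d <- get_dialect(dialect)
  nhx_for <- function(nd) {
    if (!length(include_features)) return("")
    present <- include_features[include_features %in% names(nd$features)]
    if (!length(present)) return("")
    vals <- vapply(nd$features[present], function(v) as.character(v)[1L],
                   character(1L))
    encode_nhx(stats::setNames(vals, present))
  }
  node_suffix <- function(nd) {
    is_int <- length(nd$children) > 0L
    label <- if (is_int) {
      if (d$writes_internal_names && nzchar(nd$name))
        newick_label(nd$name, auto_quote)
      else if (d$writes_support) fmt_num(nd$support)
      else if (d$writes_internal_names) ""
      else ""
    } else {
      if (d$writes_leaf_names) newick_label(nd$name, auto_quote) else ""
    }
    out <- label
    if (d$writes_branch_lengths) out <- paste0(out, ":", fmt_num(nd$dist))
    paste0(out, nhx_for(nd))
  }
  cap <- 1024L
  out <- character(cap)
  oi <- 0L
  ns <- vector("list", 64L)
  ci <- integer(64L)
  ns[[1L]] <- root
  ci[1L] <- 0L
  top <- 1L
  while (top > 0L) {
    nd <- ns[[top]]
    i <- ci[top]
    ch <- nd$children
    k <- length(ch)
    if (i < k) {
      oi <- oi + 1L
      if (oi > cap) { cap <- cap * 2L; length(out) <- cap }
      out[oi] <- if (i == 0L) "(" else ","
      ci[top] <- i + 1L
      top <- top + 1L
      if (top > length(ns)) { length(ns) <- 2L * top; length(ci) <- 2L * top }
      ns[[top]] <- ch[[i + 1L]]
      ci[top] <- 0L
    } else {
      oi <- oi + 1L
      if (oi > cap) { cap <- cap * 2L; length(out) <- cap }
      out[oi] <- if (k > 0L) paste0(")", node_suffix(nd)) else node_suffix(nd)
      top <- top - 1L
    }
  }
  paste0(paste0(out[seq_len(oi)], collapse = ""), ";")
}

#' Read trees from a newick file
#'
#' A file may hold several `';'`-terminated statements (one tree each).
#'
#' @param path File path.
#' @param dialect Dialect for parsing (default `"FLEXIBLE"`).
#' @return A single `tree_node` when the file holds one tree, else a list.
#' @export
read_tree <- function(path, dialect = "FLEXIBLE") {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # split into statements on ';' that lie outside quotes/comments
  tk <- newick_tokens(text)
  ends <- which(tk$tok == ";")
  if (!length(ends)) stop("no ';'-terminated newick statement in ", path)
  starts <- c(1L, tk$pos[ends[-length(ends)]] + 1L)
  trees <- lapply(seq_along(ends), function(i) {
    parse_newick(substr(text, starts[i], tk$pos[ends[i]]), dialect)
  })
  if (length(trees) == 1L) trees[[1L]] else trees
}

#' Write a tree to a newick file
#'
#' @inheritParams write_newick
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_tree <- function(root, path, dialect = "FULL",
                       include_features = character(0), auto_quote = FALSE) {
  writeLines(write_newick(root, dialect, include_features, auto_quote), path)
  invisible(path)
}
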